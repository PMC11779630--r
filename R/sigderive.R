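#' Derive orthogonal organotropism and subtype gene signatures
#'
#' From a two-factor DE result, selects genes up in the liver-like group
#' passing the organ-factor FDR gate and removes any gene falling in the
#' top half of genes ranked by the subtype factor (and vice versa for the
#' subtype signature), yielding a pair of mutually orthogonalized sets.
#'
#' "Top half" is the first `ceiling(N/2)` of the N-gene universe ranked
#' by the other factor's unadjusted Wald p ascending; ties at the median
#' rank are conservatively included in the top half.
#'
#' @param de a `de_result` covering both factors on one gene universe.
#' @param fdr_org FDR gate for the organ factor (default 0.2).
#' @param fdr_sub FDR gate for the subtype factor (default 1e-4).
#' @param rank_by ranking statistic behind the top-half exclusion:
#'   unadjusted `"p"` (default), `"fdr"`, or absolute Wald `"stat"`.
#' @return object of class `signature_pair`: list with `porg_like` and
#'   `psub_like` (character vectors of gene ids) and `provenance`
#'   (thresholds, direction, and the genes excluded by each top-half
#'   rule). Empty signatures produce a warning, not an error.
#' @export
derive_signatures <- function(de, fdr_org = 0.2, fdr_sub = 1e-4,
                              rank_by = c("p", "fdr", "stat")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(de, "de_result"))
  org <- de_table(de, "organ")
  sub <- de_table(de, "subtype")
  stopifnot(identical(org$gene, sub$gene))
  top_half <- function(tab) {
    key <- switch(rank_by, p = tab$p, fdr = tab$fdr, stat = -abs(tab$stat))
    thr <- sort(key)[ceiling(length(key) / 2)]
    tab$gene[key <= thr]
  }
  th_sub <- top_half(sub)
  th_org <- top_half(org)
  cand_org <- org$gene[org$fdr < fdr_org & org$log2fc > 0]
  cand_sub <- sub$gene[sub$fdr < fdr_sub & sub$log2fc > 0]
  porg <- setdiff(cand_org, th_sub)
  psub <- setdiff(cand_sub, th_org)
  if (length(porg) == 0)
    warning("organ signature is empty after gating/exclusion")
  if (length(psub) == 0)
    warning("subtype signature is empty after gating/exclusion")
  structure(list(
    porg_like = porg,
    psub_like = psub,
    provenance = list(fdr_org = fdr_org, fdr_sub = fdr_sub,
                      direction = "up only", rank_by = rank_by,
                      excluded_org = intersect(cand_org, th_sub),
                      excluded_sub = intersect(cand_sub, th_org))),
    class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat("signature_pair: organ-like", length(x$porg_like),
      "genes, subtype-like", length(x$psub_like), "genes\n")
  cat("  gates: organ FDR <", x$provenance$fdr_org, "| subtype FDR <",
      x$provenance$fdr_sub, "| ranked by", x$provenance$rank_by, "\n")
  invisible(x)
}

#' Write a signature pair as GMT plus provenance JSON
#'
#' @param sig a `signature_pair`
#' @param gmt_path GMT destination (sets named pORG_like / pSUB_like)
#' @param provenance_path optional JSON sidecar destination
#' @return `gmt_path`, invisibly
#' @export
write_signatures <- function(sig, gmt_path, provenance_path = NULL) {
  sets <- list()
  if (length(sig$porg_like)) sets <- c(sets, list(gene_set("pORG_like", sig$porg_like)))
  if (length(sig$psub_like)) sets <- c(sets, list(gene_set("pSUB_like", sig$psub_like)))
  write_gmt(sets, gmt_path)
  if (!is.null(provenance_path))
    jsonlite::write_json(sig$provenance, provenance_path, auto_unbox = TRUE)
  invisible(gmt_path)
}

#' Leave-one-out cross-validation of the signature derivation
#'
#' Repeats the full derivation (dispersion estimation, two-factor fit,
#' gating and top-half exclusion) with each sample left out, scores all
#' samples with the per-fold signatures, and keeps only each left-out
#' sample's score. The combined cross-validated score vectors are tested
#' for association with the organ and subtype labels by two-sided
#' two-sample t-tests, alongside the over-fit in-sample scores for
#' comparison.
#'
#' @param cm a [counts_matrix()] whose `samples` carry `organ_factor`
#'   and `subtype_factor`.
#' @param fdr_org,fdr_sub FDR gates passed to [derive_signatures()].
#' @param tau GSVA weighting exponent passed to [gsva_scores()].
#' @return list with `cv_scores` (data.frame: sample_id, porg, psub),
#'   `insample_scores` (same shape), and `association` (data.frame:
#'   factor, p_cv, p_insample). Folds whose reduced design loses a
#'   factor level, or whose signature comes back empty, contribute a
#'   missing score with a warning.
#' @export
loo_crossvalidate <- function(cm, fdr_org = 0.2, fdr_sub = 1e-4, tau = 1) {
  stopifnot(inherits(cm, "counts_matrix"))
  n <- ncol(cm$counts)
  if (n < 9)
    stop("leave-one-out needs >= 9 samples so every fold keeps >= 8; got ",
         n)
  samples <- cm$samples
  expr <- tmm_log_cpm(cm)
  score_with <- function(sig) {
    out <- c(porg = NA_real_, psub = NA_real_)
    sets <- list()
    if (length(sig$porg_like))
      sets$pORG_like <- gene_set("pORG_like", sig$porg_like)
    if (length(sig$psub_like))
      sets$pSUB_like <- gene_set("pSUB_like", sig$psub_like)
    if (length(sets) == 0) return(NULL)
    gsva_scores(expr, sets, tau = tau)
  }
  cv <- data.frame(sample_id = samples$sample_id,
                   porg = NA_real_, psub = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sub_cm <- cm[, -i]
    des <- tryCatch(two_factor_design(sub_cm$samples),
                    error = function(e) NULL)
    if (is.null(des)) {
      warning("fold ", samples$sample_id[i],
              ": single-level factor, fold skipped")
      next
    }
    de <- fit_two_factor(sub_cm, des)
    sig <- suppressWarnings(derive_signatures(de, fdr_org, fdr_sub))
    sc <- score_with(sig)
    if (is.null(sc)) {
      warning("fold ", samples$sample_id[i],
              ": empty signature, score missing")
      next
    }
    if ("pORG_like" %in% rownames(sc)) cv$porg[i] <- sc["pORG_like", i]
    if ("pSUB_like" %in% rownames(sc)) cv$psub[i] <- sc["pSUB_like", i]
  }
  de_full <- fit_two_factor(cm, two_factor_design(samples))
  sig_full <- suppressWarnings(derive_signatures(de_full, fdr_org, fdr_sub))
  sc_full <- score_with(sig_full)
  ins <- data.frame(sample_id = samples$sample_id,
                    porg = NA_real_, psub = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(sc_full)) {
    if ("pORG_like" %in% rownames(sc_full)) ins$porg <- sc_full["pORG_like", ]
    if ("pSUB_like" %in% rownames(sc_full)) ins$psub <- sc_full["pSUB_like", ]
  }
  assoc_p <- function(score, label) {
    if (sum(!is.na(score)) < 4 || length(unique(label[!is.na(score)])) < 2)
      return(NA_real_)
    stats::t.test(score ~ label)$p.value
  }
  association <- data.frame(
    factor = c("organ", "subtype"),
    p_cv = c(assoc_p(cv$porg, samples$organ_factor),
             assoc_p(cv$psub, samples$subtype_factor)),
    p_insample = c(assoc_p(ins$porg, samples$organ_factor),
                   assoc_p(ins$psub, samples$subtype_factor)),
    stringsAsFactors = FALSE)
  list(cv_scores = cv, insample_scores = ins, association = association)
}
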