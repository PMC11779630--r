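#' Transcripts-per-million normalization
#'
#' Per sample, counts are converted to length-normalized rates
#' `count / length` and rescaled so each column sums to one million.
#'
#' @param cm a [counts_matrix()] with gene lengths.
#' @return an [expression_matrix()] with `transform_tag = "tpm"`. Samples
#'   with zero total counts get an all-zero column with a warning.
#' @export
compute_tpm <- function(cm) {
  stopifnot(inherits(cm, "counts_matrix"))
  if (is.null(cm$gene_lengths))
    stop("gene lengths are required for TPM")
  rate <- cm$counts / cm$gene_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("zero-count sample(s): ",
            paste(colnames(cm$counts)[zero], collapse = ", "),
            "; TPM column set to zero")
    tot[zero] <- 1
  }
  expression_matrix(sweep(rate, 2, tot, "/") * 1e6, "tpm")
}

#' Filter genes by mean TPM across the dataset
#'
#' A gene is retained when its mean TPM over all samples is at least
#' `cutoff`; genes with mean strictly below the cutoff are removed.
#'
#' @param tpm an [expression_matrix()] with `transform_tag = "tpm"`.
#' @param cutoff minimum mean TPM (default 0.25).
#' @return character vector of retained gene ids, in input order.
#' @export
mean_tpm_filter <- function(tpm, cutoff = 0.25) {
  stopifnot(inherits(tpm, "expression_matrix"))
  if (tpm$transform_tag != "tpm")
    stop("mean_tpm_filter expects TPM values, got ", tpm$transform_tag)
  m <- rowMeans(tpm$values)
  rownames(tpm$values)[m >= cutoff]
}

#' TMM-normalized log2 counts-per-million
#'
#' Library scale factors are computed with the trimmed mean of M-values
#' method (reference sample chosen by upper-quartile fraction closest to
#' the mean; 30% trim on M, 5% on A; pairwise-complete over non-zero
#' genes; factors normalized to geometric mean one), then expression is
#' `log2(count * 1e6 / (libsize * factor) + prior)`.
#'
#' @param cm a [counts_matrix()] with at least two samples.
#' @param prior prior count added inside the log (default 0.5).
#' @return an [expression_matrix()] with `transform_tag = "log_cpm_tmm"`
#'   and the scale factors in attribute `"tmm_factors"`.
#' @export
tmm_log_cpm <- function(cm, prior = 0.5) {
  stopifnot(inherits(cm, "counts_matrix"))
  if (ncol(cm$counts) < 2)
    stop("TMM normalization needs at least 2 samples")
  libsize <- colSums(cm$counts)
  if (any(libsize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[libsize == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(edgeR::DGEList(counts = cm$counts),
                              method = "TMM")$samples$norm.factors
  eff <- libsize * f
  out <- expression_matrix(log2(sweep(cm$counts, 2, eff, "/") * 1e6 + prior),
                           "log_cpm_tmm")
  attr(out, "tmm_factors") <- stats::setNames(f, colnames(cm$counts))
  out
}

#' Variance-flattening log transform
#'
#' A monotone `log2(CPM + prior)` transform with a large prior count,
#' used where a variance-stabilized scale is wanted without a fitted
#' mean-variance model. Labeled `vst_like` in all outputs.
#'
#' @param cm a [counts_matrix()]
#' @param prior prior count (default 8)
#' @return an [expression_matrix()] with `transform_tag = "vst_like"`
#' @export
vst_like <- function(cm, prior = 8) {
  stopifnot(inherits(cm, "counts_matrix"))
  libsize <- colSums(cm$counts)
  if (any(libsize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[libsize == 0], collapse = ", "))
  expression_matrix(log2(sweep(cm$counts, 2, libsize, "/") * 1e6 + prior),
                    "vst_like")
}
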