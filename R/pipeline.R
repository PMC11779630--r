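#' Pipeline configuration
#'
#' Centralizes every numeric constant of the analysis alongside the
#' input paths. Thresholds default to the values used throughout the
#' package: TPM filter 0.25, organ-factor FDR gate 0.2, subtype-factor
#' gate 1e-4, repertoire QC at 100 productive templates, tumor-distinct
#' universe at 10 combined templates, dominance rank 50, shared-clone
#' prevalence 0.25, survival horizon 545 days and early-death exclusion
#' at 30 days.
#'
#' @param out_dir output directory
#' @param seed integer seed for any stochastic stage
#' @param counts,lengths,samples input paths (counts TSV, gene-length
#'   TSV, sample CSV)
#' @param gene_sets optional GMT of extra sets to score
#' @param tcr_manifest optional CSV linking clonotype TSVs to
#'   patient/compartment/tissue/input_ng
#' @param reference_cdr3 optional plain-text reference CDR3 list
#' @param tsp_model optional TSP classifier JSON
#' @param thresholds named list overriding individual defaults
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1, counts = NULL,
                            lengths = NULL, samples = NULL,
                            gene_sets = NULL, tcr_manifest = NULL,
                            reference_cdr3 = NULL, tsp_model = NULL,
                            thresholds = list()) {
  defaults <- list(tpm_cutoff = 0.25, fdr_org = 0.2, fdr_sub = 1e-4,
                   min_templates = 100, distinct_min = 10, top_n = 50,
                   prevalence = 0.25, horizon = 545, early_death = 30)
  thresholds <- utils::modifyList(defaults, thresholds)
  if (any(unlist(thresholds) <= 0))
    stop("all thresholds must be positive")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 counts = counts, lengths = lengths, samples = samples,
                 gene_sets = gene_sets, tcr_manifest = tcr_manifest,
                 reference_cdr3 = reference_cdr3, tsp_model = tsp_model,
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Write a complete synthetic study to disk
#'
#' Generates the expression study, survival fields and repertoire
#' cohort from the package's synthetic-truth defaults and writes every
#' file [run_pipeline()] reads, plus a `truth.json` sidecar recording
#' the planted structure.
#'
#' @param config a [pipeline_config()]; its `out_dir` receives the
#'   files and its `seed` drives all generation
#' @param n_patients repertoire pairs to generate (default 12)
#' @param expr_truth,surv_truth,rep_truth optional truth objects
#'   overriding the defaults
#' @param force overwrite an existing non-empty output directory
#' @return an updated `pipeline_config` pointing at the written files
#' @export
simulate_study <- function(config, n_patients = 12, expr_truth = NULL,
                           surv_truth = NULL, rep_truth = NULL,
                           force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    stop("output directory ", out, " exists; use force = TRUE")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (is.null(expr_truth)) expr_truth <- expression_truth()
  if (is.null(surv_truth)) surv_truth <- survival_truth()
  if (is.null(rep_truth)) rep_truth <- repertoire_truth()
  study <- generate_expression_study(expr_truth, config$seed)
  # survival linked to the planted organ factor as a crude score
  score <- as.numeric(study$cm$samples$organ_factor == "liver-like")
  surv <- generate_survival(study$cm$samples, score, surv_truth,
                            config$seed + 1L)
  p <- function(f) file.path(out, f)
  write_counts_tsv(study$cm, p("counts.tsv"), p("lengths.tsv"))
  utils::write.csv(surv, p("samples.csv"), row.names = FALSE)
  cohort <- generate_repertoire_cohort(n_patients, rep_truth,
                                       config$seed + 2L)
  manifest <- do.call(rbind, lapply(cohort, function(pr) {
    rows <- lapply(list(pr$blood, pr$tumor), function(r) {
      f <- paste0(r$sample_id, ".tsv")
      write_immunoseq(r, p(f))
      data.frame(file = f, sample_id = r$sample_id,
                 patient_id = r$patient_id, compartment = r$compartment,
                 tissue = r$tissue, input_ng = r$input_ng,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (!is.null(manifest))
    utils::write.csv(manifest, p("tcr_manifest.csv"), row.names = FALSE)
  truth <- list(
    organ_genes = expr_truth$organ_genes,
    subtype_genes = expr_truth$subtype_genes,
    overlap_genes = expr_truth$overlap_genes,
    log2fc_org = expr_truth$log2fc_org,
    log2fc_sub = expr_truth$log2fc_sub,
    beta_score = surv_truth$beta_score,
    repertoire = attr(cohort, "truth"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE)
  pipeline_config(out_dir = out, seed = config$seed,
                  counts = p("counts.tsv"), lengths = p("lengths.tsv"),
                  samples = p("samples.csv"),
                  tcr_manifest = if (!is.null(manifest))
                    p("tcr_manifest.csv"),
                  reference_cdr3 = config$reference_cdr3,
                  tsp_model = config$tsp_model,
                  thresholds = config$thresholds)
}

#' Run the end-to-end analysis
#'
#' Executes normalize -> filter -> two-factor DE -> signature
#' derivation -> enrichment scoring -> quartile cohorts -> survival
#' statistics, plus the TCR analytics when a manifest is supplied.
#' Stages whose inputs are absent are skipped with a note in the run
#' manifest. Per-stage tables are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()] with at least `counts`,
#'   `lengths` and `samples` set
#' @return (invisibly) the report bundle: a list with per-stage results
#'   and the run manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  report <- list()
  skipped <- character(0)
  cm <- read_counts_tsv(config$counts, config$lengths, config$samples)

  keep <- mean_tpm_filter(compute_tpm(cm), thr$tpm_cutoff)
  cmf <- cm[keep, ]
  expr <- tmm_log_cpm(cmf)
  utils::write.table(
    data.frame(gene_id = rownames(expr$values), expr$values,
               check.names = FALSE),
    p("expression_logcpm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$normalize <- list(genes_in = nrow(cm$counts),
                           genes_kept = length(keep))

  have_factors <- all(c("organ_factor", "subtype_factor") %in%
                        names(cmf$samples))
  if (have_factors) {
    design <- two_factor_design(cmf$samples)
    de <- fit_two_factor(cmf, design)
    for (f in de$factors)
      utils::write.table(de_table(de, f), p(paste0("de_", f, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- suppressWarnings(
      derive_signatures(de, thr$fdr_org, thr$fdr_sub))
    write_signatures(sig, p("signatures.gmt"), p("provenance.json"))
    report$derive <- list(n_porg = length(sig$porg_like),
                          n_psub = length(sig$psub_like))
    sets <- list()
    if (length(sig$porg_like))
      sets$pORG_like <- gene_set("pORG_like", sig$porg_like)
    if (length(sig$psub_like))
      sets$pSUB_like <- gene_set("pSUB_like", sig$psub_like)
    if (!is.null(config$gene_sets))
      sets <- c(sets, read_gmt(config$gene_sets))
    if (length(sets)) {
      scores <- gsva_scores(expr, sets)
      utils::write.table(
        data.frame(set = rownames(scores), scores, check.names = FALSE),
        p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      report$scores <- scores
      if ("pORG_like" %in% rownames(scores)) {
        report$quartiles <- quartile_cohorts(scores["pORG_like", ])
        surv_ok <- all(c("time", "event") %in% names(cmf$samples))
        if (surv_ok) {
          rec <- cmf$samples
          rec <- thirty_day_filter(rec, thr$early_death)
          sc <- scores["pORG_like", rec$sample_id]
          cut <- tryCatch(youden_cutoff(sc, rec, thr$horizon),
                          error = function(e) NULL)
          if (!is.null(cut)) {
            rec$group <- ifelse(sc >= cut$cutoff, "high", "low")
            report$survival <- list(
              cutoff = cut,
              logrank = if (length(unique(rec$group)) == 2)
                logrank_test(rec),
              cox = cox_fit(transform(rec, score = sc), "score"))
            jsonlite::write_json(
              list(cutoff = cut$cutoff,
                   cox_hr = report$survival$cox$table$hr),
              p("survival.json"), auto_unbox = TRUE)
          }
        } else skipped <- c(skipped, "survival: no time/event columns")
      }
    }
  } else skipped <- c(skipped, "de/derive/score: no factor columns")

  if (!is.null(config$tcr_manifest) && file.exists(config$tcr_manifest)) {
    man <- utils::read.csv(config$tcr_manifest, stringsAsFactors = FALSE)
    reps <- lapply(seq_len(nrow(man)), function(i)
      read_immunoseq(file.path(dirname(config$tcr_manifest),
                               man$file[i]),
                     sample_id = man$sample_id[i],
                     patient_id = man$patient_id[i],
                     compartment = man$compartment[i],
                     tissue = man$tissue[i],
                     input_ng = man$input_ng[i]))
    reps <- qc_filter(reps, thr$min_templates)
    metrics <- do.call(rbind, lapply(reps, diversity_metrics))
    utils::write.table(metrics, p("tcr_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tumors <- Filter(function(r) r$compartment == "tumor", reps)
    bloods <- Filter(function(r) r$compartment == "blood", reps)
    pair_of <- function(pid) {
      b <- Filter(function(r) r$patient_id == pid, bloods)
      t <- Filter(function(r) r$patient_id == pid, tumors)
      if (length(b) && length(t)) repertoire_pair(b[[1]], t[[1]])
    }
    pids <- unique(vapply(reps, `[[`, "", "patient_id"))
    pairs <- Filter(Negate(is.null), lapply(pids, pair_of))
    td <- vapply(pairs, tumor_distinct_percent,
                 0, min_templates = thr$distinct_min)
    shared <- if (length(tumors))
      shared_dominant_clones(tumors, thr$top_n, thr$prevalence)
    else character(0)
    report$tcr <- list(
      metrics = metrics,
      tumor_distinct = stats::setNames(
        td, vapply(pairs, `[[`, "", "patient_id")),
      shared_dominant = shared,
      expanded = if (length(tumors)) expanded_clones(tumors),
      reference_matches = if (!is.null(config$reference_cdr3))
        vapply(tumors, function(r)
          match_reference_cdr3(
            r, read_reference_cdr3(config$reference_cdr3))$n_matched,
          0L))
    jsonlite::write_json(
      report$tcr[c("tumor_distinct", "shared_dominant")],
      p("tcr_summary.json"), auto_unbox = TRUE)
  } else skipped <- c(skipped, "tcr: no manifest")

  truth_path <- file.path(dirname(config$counts), "truth.json")
  if (file.exists(truth_path) && !is.null(report$derive)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    sig <- read_gmt(p("signatures.gmt"))
    if ("pORG_like" %in% names(sig)) {
      hits <- sig$pORG_like$genes %in% truth$organ_genes
      report$planted_precision <- mean(hits)
    }
  }
  report$manifest <- list(seed = config$seed,
                          thresholds = thr,
                          skipped = skipped,
                          n_samples = ncol(cm$counts),
                          timestamp = format(Sys.time()))
  jsonlite::write_json(report$manifest, p("run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
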