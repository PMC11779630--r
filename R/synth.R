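#' Ground truth for a synthetic two-factor expression study
#'
#' Defines the planted structure the generator embeds: a set of genes up
#' in the liver-like organotropism group, a set up in the basal-like
#' subtype group, a planted overlap between the two, negative-binomial
#' noise (variance mu + alpha * mu^2) and library-size bounds. The
#' defaults describe the study conditions used throughout the package's
#' validation: 2,000 genes, 80 samples (40 per organ arm, crossed with a
#' balanced subtype factor), log2 fold change 1.5 and dispersion 0.05.
#'
#' @param n_genes,n_samples matrix dimensions
#' @param n_organ,n_subtype,n_overlap planted set sizes (`n_overlap`
#'   genes belong to both sets)
#' @param log2fc_org,log2fc_sub planted effect sizes (log2 units)
#' @param dispersion NB dispersion alpha (> 0), scalar or per-gene
#' @param libsize_range lower/upper bounds for total counts per sample
#' @param group_labels optional data.frame with `organ_factor` and
#'   `subtype_factor` per sample; defaults to a balanced crossed design
#' @return object of class `expression_truth`
#' @export
expression_truth <- function(n_genes = 2000, n_samples = 80,
                             n_organ = 100, n_subtype = 100,
                             n_overlap = 20, log2fc_org = 1.5,
                             log2fc_sub = 1.5, dispersion = 0.05,
                             libsize_range = c(5e5, 2e6),
                             group_labels = NULL) {
  stopifnot(n_overlap <= min(n_organ, n_subtype),
            is.finite(log2fc_org), is.finite(log2fc_sub),
            all(dispersion > 0), length(libsize_range) == 2)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  n_distinct <- n_organ + n_subtype - n_overlap
  if (n_genes < n_distinct)
    stop("n_genes must cover the planted organ/subtype gene union")
  organ_genes <- gene_ids[seq_len(n_organ)]
  subtype_genes <- gene_ids[seq(n_organ - n_overlap + 1,
                                length.out = n_subtype)]
  if (is.null(group_labels) && n_samples > 0) {
    org <- rep(c("liver-like", "lung-like"), length.out = n_samples)
    sub <- rep(c("basal-like", "basal-like", "classical-like",
                 "classical-like"), length.out = n_samples)
    group_labels <- data.frame(organ_factor = org, subtype_factor = sub,
                               stringsAsFactors = FALSE)
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 gene_ids = gene_ids, organ_genes = organ_genes,
                 subtype_genes = subtype_genes,
                 overlap_genes = intersect(organ_genes, subtype_genes),
                 log2fc_org = log2fc_org, log2fc_sub = log2fc_sub,
                 dispersion = dispersion, libsize_range = libsize_range,
                 group_labels = group_labels),
            class = "expression_truth")
}

#' Generate a synthetic expression study with planted effects
#'
#' Draws NB counts with per-cell means
#' `mu_ij = libsize_j * q_i * 2^(x_org_j * log2fc_org * [i in organ set]
#' + x_sub_j * log2fc_sub * [i in subtype set])`, where `q` is a
#' log-normal relative-abundance profile normalized to sum 1 and
#' `x_org`/`x_sub` indicate liver-like and basal-like samples. The same
#' seed always reproduces the same study.
#'
#' @param truth an [expression_truth()]
#' @param seed integer seed (all randomness is local to this call)
#' @return list with `cm` (a [counts_matrix()] whose `samples` carry
#'   both factor labels) and `truth`
#' @export
generate_expression_study <- function(truth, seed) {
  stopifnot(inherits(truth, "expression_truth"))
  n <- truth$n_samples
  G <- truth$n_genes
  if (n == 0) {
    cm <- counts_matrix(matrix(integer(0), G, 0,
                               dimnames = list(truth$gene_ids, NULL)),
                        stats::setNames(rep(1000, G), truth$gene_ids),
                        data.frame(sample_id = character(0),
                                   organ_factor = character(0),
                                   subtype_factor = character(0)))
    return(list(cm = cm, truth = truth))
  }
  labs <- truth$group_labels
  if (length(unique(labs$organ_factor)) < 2 ||
      length(unique(labs$subtype_factor)) < 2)
    stop("degenerate design: a planted factor has a single level")
  withr::with_seed(seed, {
    q <- exp(stats::rnorm(G, 0, 1.5))
    q <- q / sum(q)
    libsize <- stats::runif(n, truth$libsize_range[1],
                            truth$libsize_range[2])
    x_org <- as.integer(labs$organ_factor == "liver-like")
    x_sub <- as.integer(labs$subtype_factor == "basal-like")
    in_org <- truth$gene_ids %in% truth$organ_genes
    in_sub <- truth$gene_ids %in% truth$subtype_genes
    lfc <- outer(in_org, x_org) * truth$log2fc_org +
      outer(in_sub, x_sub) * truth$log2fc_sub
    mu <- (q %o% libsize) * 2^lfc
    alpha <- rep_len(truth$dispersion, G)
    counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                    size = rep(1 / alpha, n)),
                     G, n)
    gene_lengths <- stats::setNames(
      round(stats::runif(G, 300, 5000)), truth$gene_ids)
  })
  dimnames(counts) <- list(truth$gene_ids,
                           sprintf("sample%03d", seq_len(n)))
  samples <- data.frame(sample_id = colnames(counts),
                        organ_factor = labs$organ_factor,
                        subtype_factor = labs$subtype_factor,
                        stringsAsFactors = FALSE)
  list(cm = counts_matrix(counts, gene_lengths, samples), truth = truth)
}

#' Ground truth for synthetic survival
#'
#' @param beta_score log-hazard per unit of signature score
#' @param baseline_rate baseline event hazard (events/day)
#' @param censor_rate independent censoring hazard (events/day)
#' @param admin_horizon administrative censoring time (days)
#' @return object of class `survival_truth`
#' @export
survival_truth <- function(beta_score = 0.7, baseline_rate = 1 / 500,
                           censor_rate = 1 / 3000,
                           admin_horizon = 3000) {
  stopifnot(baseline_rate > 0, censor_rate > 0, admin_horizon >= 0)
  structure(list(beta_score = beta_score, baseline_rate = baseline_rate,
                 censor_rate = censor_rate,
                 admin_horizon = admin_horizon),
            class = "survival_truth")
}

#' Generate proportional-hazards survival linked to a score
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(beta_score * score)`; censoring is an
#' independent exponential truncated by the administrative horizon. The
#' observed time is the minimum of the three, with the event indicator
#' set accordingly.
#'
#' @param samples data.frame with one row per subject (a `sample_id`
#'   column is preserved if present)
#' @param scores finite numeric vector, one per subject
#' @param truth a [survival_truth()]
#' @param seed integer seed
#' @return `samples` with `time`, `event` and `score` columns appended
#' @export
generate_survival <- function(samples, scores, truth, seed) {
  stopifnot(inherits(truth, "survival_truth"),
            nrow(samples) == length(scores))
  if (any(!is.finite(scores))) stop("non-finite scores rejected")
  n <- length(scores)
  withr::with_seed(seed, {
    ev <- stats::rexp(n, truth$baseline_rate *
                        exp(truth$beta_score * scores))
    cs <- stats::rexp(n, truth$censor_rate)
  })
  time <- pmin(ev, cs, truth$admin_horizon)
  samples$time <- time
  samples$event <- as.integer(ev <= cs & ev <= truth$admin_horizon)
  samples$score <- scores
  samples
}

#' Ground truth for synthetic TCR repertoire cohorts
#'
#' Clone frequencies follow a discretized power law (Zipf, default
#' exponent 1.5) over a per-patient clone pool, the heavy-tailed shape
#' typical of real repertoire sequencing. Shared-pool clones are
#' injected across patients at the top of the frequency ranking so they
#' are dominantly clonal where present; tumor-restricted expanded
#' clones are planted in tumors only at 10+ templates.
#'
#' @param clone_exponent Zipf exponent (> 0)
#' @param clone_pool_size private background clones per patient
#' @param n_shared size of the cross-patient shared clone pool
#' @param n_tumor_distinct planted tumor-only clones per patient
#' @param reference optional reference CDR3 list to plant matches from
#' @param n_reference_hits reference clones planted per tumor
#' @param blood_templates,tumor_templates template totals drawn per
#'   compartment
#' @param input_ng_range DNA input mass bounds (ng)
#' @return object of class `repertoire_truth`
#' @export
repertoire_truth <- function(clone_exponent = 1.5,
                             clone_pool_size = 2000, n_shared = 30,
                             n_tumor_distinct = 5,
                             reference = character(0),
                             n_reference_hits = 2,
                             blood_templates = 5000,
                             tumor_templates = 2500,
                             input_ng_range = c(200, 2000)) {
  structure(list(clone_exponent = clone_exponent,
                 clone_pool_size = clone_pool_size, n_shared = n_shared,
                 n_tumor_distinct = n_tumor_distinct,
                 reference = reference,
                 n_reference_hits = n_reference_hits,
                 blood_templates = blood_templates,
                 tumor_templates = tumor_templates,
                 input_ng_range = input_ng_range),
            class = "repertoire_truth")
}

# random CDR3 amino-acid strings: CASS + 7-13 random residues + F,
# total length 12-18; collision probability is negligible
random_cdr3 <- function(n) {
  mid <- sample(7:13, n, replace = TRUE)
  vapply(mid, function(k)
    paste0("CASS", paste(sample(AA_ALPHABET, k, replace = TRUE),
                         collapse = ""), "F"), "")
}

#' Generate a cohort of matched blood-tumor repertoire pairs
#'
#' Each patient receives a clone pool of private background clones plus
#' any shared-pool clones assigned to them (every shared clone reaches
#' at least 25% of patients). Template counts for blood and tumor are
#' multinomial over Zipf clone probabilities; planted tumor-distinct
#' clones are then added to the tumor only, at 10-30 templates each,
#' and reference-list clones (when supplied) are planted in tumors.
#'
#' @param n_patients number of patients (>= 0)
#' @param truth a [repertoire_truth()]
#' @param seed integer seed
#' @return list of [repertoire_pair()]; the planted structure is
#'   attached as attribute `"truth"` (per-patient tumor-distinct
#'   clones, the shared pool, reference hits)
#' @export
generate_repertoire_cohort <- function(n_patients, truth, seed) {
  stopifnot(inherits(truth, "repertoire_truth"), n_patients >= 0)
  if (truth$clone_exponent <= 0)
    stop("clone-law exponent must be positive")
  if (n_patients == 0) return(structure(list(), truth = list()))
  withr::with_seed(seed, {
    shared_pool <- random_cdr3(truth$n_shared)
    min_carr <- ceiling(0.25 * n_patients)
    carriers <- lapply(seq_len(truth$n_shared), function(i) {
      k <- sample(min_carr:n_patients, 1)
      sample(seq_len(n_patients), k)
    })
    pairs <- vector("list", n_patients)
    planted <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      pid <- sprintf("PT%03d", p)
      my_shared <- shared_pool[vapply(carriers, function(cr) p %in% cr,
                                      TRUE)]
      private <- random_cdr3(truth$clone_pool_size)
      private <- setdiff(private, shared_pool)
      pool <- c(my_shared, private)
      prob <- seq_along(pool)^(-truth$clone_exponent)
      prob <- prob / sum(prob)
      draw <- function(total) {
        tpl <- as.integer(stats::rmultinom(1, total, prob))
        keep <- tpl > 0
        data.frame(cdr3_aa = pool[keep], templates = tpl[keep],
                   stringsAsFactors = FALSE)
      }
      blood_ct <- draw(truth$blood_templates)
      tumor_ct <- draw(truth$tumor_templates)
      td <- character(0)
      if (truth$n_tumor_distinct > 0) {
        repeat {
          td <- random_cdr3(truth$n_tumor_distinct)
          if (!any(td %in% c(pool, blood_ct$cdr3_aa))) break
        }
        tumor_ct <- rbind(tumor_ct, data.frame(
          cdr3_aa = td,
          templates = sample(10:30, truth$n_tumor_distinct,
                             replace = TRUE),
          stringsAsFactors = FALSE))
      }
      ref_hits <- character(0)
      if (length(truth$reference) > 0 && truth$n_reference_hits > 0) {
        ref_hits <- sample(setdiff(unique(truth$reference),
                                   tumor_ct$cdr3_aa),
                           min(truth$n_reference_hits,
                               length(unique(truth$reference))))
        tumor_ct <- rbind(tumor_ct, data.frame(
          cdr3_aa = ref_hits,
          templates = sample(3:8, length(ref_hits), replace = TRUE),
          stringsAsFactors = FALSE))
      }
      ng <- stats::runif(2, truth$input_ng_range[1],
                         truth$input_ng_range[2])
      blood <- repertoire(paste0(pid, "_blood"), blood_ct, pid,
                          "blood", "blood", ng[1])
      tumor <- repertoire(paste0(pid, "_tumor"), tumor_ct, pid,
                          "tumor", "primary", ng[2])
      pairs[[p]] <- repertoire_pair(blood, tumor, "primary_associated")
      planted[[p]] <- list(tumor_distinct = td, shared = my_shared,
                           reference_hits = ref_hits)
    }
  })
  names(planted) <- vapply(pairs, `[[`, "", "patient_id")
  structure(pairs,
            truth = list(shared_pool = shared_pool, planted = planted))
}
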