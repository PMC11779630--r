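AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' TCR-beta repertoire container
#'
#' One sample's productive clonotype table. Clonotype identity is the
#' CDR3 amino-acid sequence alone; V/J annotations, if present in the
#' source file, are carried but ignored for identity.
#'
#' @param sample_id sample identifier
#' @param clonotypes data.frame with columns `cdr3_aa`, `templates`
#'   (non-negative integers) and optionally `productive_frequency`
#'   (recomputed from templates when absent).
#' @param patient_id patient identifier (optional)
#' @param compartment `"blood"` or `"tumor"`
#' @param tissue `"primary"`, `"metastasis"` or `"blood"`
#' @param input_ng DNA mass sequenced, in ng (optional; enables
#'   templates-per-ng reporting)
#' @return object of class `repertoire`
#' @export
repertoire <- function(sample_id, clonotypes, patient_id = NA_character_,
                       compartment = c("blood", "tumor"),
                       tissue = c("blood", "primary", "metastasis"),
                       input_ng = NA_real_) {
  compartment <- match.arg(compartment)
  tissue <- match.arg(tissue)
  clonotypes <- as.data.frame(clonotypes)
  stopifnot(all(c("cdr3_aa", "templates") %in% names(clonotypes)))
  cd <- as.character(clonotypes$cdr3_aa)
  if (nrow(clonotypes) > 0) {
    if (any(!nzchar(cd))) stop("empty CDR3 sequence")
    if (anyDuplicated(cd)) stop("duplicate CDR3 keys in clonotype table")
    bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), cd)
    if (any(bad))
      stop("non-canonical amino-acid letters in CDR3: ",
           paste(utils::head(cd[bad], 3), collapse = ", "))
  }
  tpl <- clonotypes$templates
  if (any(tpl < 0) || any(tpl != round(tpl)))
    stop("templates must be non-negative integers")
  total <- sum(tpl)
  if (is.null(clonotypes$productive_frequency)) {
    clonotypes$productive_frequency <-
      if (total > 0) tpl / total else rep(0, length(tpl))
  } else if (total > 0 &&
             abs(sum(clonotypes$productive_frequency) - 1) > 1e-6) {
    stop("productive frequencies must sum to 1 (got ",
         signif(sum(clonotypes$productive_frequency), 8), ")")
  }
  clonotypes$cdr3_aa <- cd
  rownames(clonotypes) <- NULL
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 compartment = compartment, tissue = tissue,
                 clonotypes = clonotypes, input_ng = input_ng,
                 total_productive_templates = total),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("repertoire ", x$sample_id, " (", x$compartment, "/", x$tissue,
      "): ", nrow(x$clonotypes), " clonotypes, ",
      x$total_productive_templates, " productive templates\n", sep = "")
  invisible(x)
}

#' Matched blood-tumor repertoire pair
#'
#' @param blood,tumor [repertoire()] objects from the same patient
#' @param blood_class `"primary_associated"`, `"metastasis_associated"`
#'   or `"uncharacterized"` (see [classify_blood_sample()])
#' @return object of class `repertoire_pair`
#' @export
repertoire_pair <- function(blood, tumor,
                            blood_class = "uncharacterized") {
  stopifnot(inherits(blood, "repertoire"), inherits(tumor, "repertoire"))
  if (!identical(blood$patient_id, tumor$patient_id))
    stop("blood and tumor repertoires belong to different patients")
  blood_class <- match.arg(blood_class,
                           c("primary_associated", "metastasis_associated",
                             "uncharacterized"))
  structure(list(patient_id = blood$patient_id, blood = blood,
                 tumor = tumor, blood_class = blood_class),
            class = "repertoire_pair")
}

#' Read an immunoSEQ-style clonotype export
#'
#' Expects a TSV with at least `cdr3_aa` and `templates` columns
#' (optional `productive_frequency`, `frame`, `v_gene`, `j_gene`).
#' Non-productive rows (CDR3 containing a stop codon `*` or a `frame`
#' flag other than "In") are dropped with the count reported, and
#' frequencies are renormalized over the remaining productive templates.
#'
#' @param path TSV file
#' @inheritParams repertoire
#' @return a [repertoire()]
#' @export
read_immunoseq <- function(path, sample_id = NULL,
                           patient_id = NA_character_,
                           compartment = "blood", tissue = "blood",
                           input_ng = NA_real_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty clonotype file: ", path)
  need <- c("cdr3_aa", "templates")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("clonotype file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  nonprod <- grepl("*", tab$cdr3_aa, fixed = TRUE)
  if (!is.null(tab$frame)) nonprod <- nonprod | tolower(tab$frame) != "in"
  if (any(nonprod))
    message("dropped ", sum(nonprod), " non-productive row(s) from ", path)
  tab <- tab[!nonprod, , drop = FALSE]
  if (nrow(tab) == 0) stop("no productive clonotypes in ", path)
  tab$productive_frequency <- tab$templates / sum(tab$templates)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  repertoire(sample_id,
             tab[, c("cdr3_aa", "templates", "productive_frequency")],
             patient_id, compartment, tissue, input_ng)
}

#' Write a repertoire as a clonotype TSV
#'
#' @param rep a [repertoire()]
#' @param path destination
#' @return `path`, invisibly
#' @export
write_immunoseq <- function(rep, path) {
  utils::write.table(rep$clonotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exclude low-depth repertoires
#'
#' @param reps list of [repertoire()] objects
#' @param min_templates minimum productive templates (default 100);
#'   samples strictly below are excluded.
#' @return the retained list
#' @export
qc_filter <- function(reps, min_templates = 100) {
  Filter(function(r) r$total_productive_templates >= min_templates, reps)
}

#' Repertoire diversity, evenness and clonality metrics
#'
#' All metrics are computed from amino-acid CDR3 productive frequencies:
#' richness R (unique productive CDR3s), Shannon entropy H in nats,
#' Pielou evenness H/ln R, clonality 1 - H/ln R, Simpson's d (sum p^2),
#' Simpson's diversity 1 - d, Simpson's evenness (1/d)/R, and templates
#' per ng of input DNA. A monoclonal repertoire (R = 1) takes the
#' convention clonality = 1, Pielou = 0.
#'
#' @param rep a [repertoire()] with at least one template
#' @return one-row data.frame of the metrics plus sample metadata
#' @export
diversity_metrics <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (rep$total_productive_templates == 0)
    stop("repertoire ", rep$sample_id, " has zero productive templates")
  p <- rep$clonotypes$productive_frequency
  p <- p[p > 0] / sum(p[p > 0])
  R <- length(p)
  H <- -sum(p * log(p))
  pielou <- if (R > 1) H / log(R) else 0
  d <- sum(p^2)
  data.frame(sample_id = rep$sample_id, patient_id = rep$patient_id,
             compartment = rep$compartment, tissue = rep$tissue,
             richness = R, shannon = H, pielou = pielou,
             clonality = 1 - pielou, simpson_d = d,
             simpson_diversity = 1 - d, simpson_evenness = (1 / d) / R,
             templates_per_ng =
               rep$total_productive_templates / rep$input_ng,
             stringsAsFactors = FALSE)
}

#' Public overlap and Jaccard index between two repertoires
#'
#' Overlap is computed on the sets of productive CDR3 amino-acid keys:
#' `public` is the intersection size, `jaccard` the intersection over
#' the union. Both are symmetric in their arguments.
#'
#' @param a,b [repertoire()] objects
#' @return list with `public` (integer) and `jaccard` (in \[0, 1\];
#'   defined 0 with a warning when both repertoires are empty)
#' @export
repertoire_overlap <- function(a, b) {
  A <- a$clonotypes$cdr3_aa[a$clonotypes$templates > 0]
  B <- b$clonotypes$cdr3_aa[b$clonotypes$templates > 0]
  u <- length(union(A, B))
  i <- length(intersect(A, B))
  if (u == 0) {
    warning("both repertoires empty; Jaccard defined as 0")
    return(list(public = 0L, jaccard = 0))
  }
  list(public = i, jaccard = i / u)
}

#' Mean pairwise overlap of one repertoire against a cohort
#'
#' The per-sample summary of shared T cell responses: each sample's
#' public overlap and Jaccard index with every other sample, averaged.
#' Any log10 transform happens at the reporting layer, not here.
#'
#' @param rep a [repertoire()]
#' @param others non-empty list of comparison repertoires; the caller
#'   is responsible for leaving the query sample out of the cohort
#' @return list with `mean_public` and `mean_jaccard`
#' @export
mean_pairwise_overlap <- function(rep, others) {
  if (length(others) == 0) stop("no comparison repertoires supplied")
  ov <- lapply(others, repertoire_overlap, a = rep)
  list(mean_public = mean(vapply(ov, `[[`, 0, "public")),
       mean_jaccard = mean(vapply(ov, `[[`, 0, "jaccard")))
}

#' Percent tumor-distinct clones in a matched pair
#'
#' The universe is every CDR3 whose combined blood-plus-tumor template
#' count reaches `min_templates`; a clone is tumor-distinct when it is
#' found in the tumor but absent from the matched blood. Returns the
#' percentage of the universe that is tumor-distinct.
#'
#' @param pair a [repertoire_pair()]
#' @param min_templates combined-template threshold (default 10)
#' @return percent in \[0, 100\]; `NA` with a warning when no clone
#'   reaches the threshold
#' @export
tumor_distinct_percent <- function(pair, min_templates = 10) {
  stopifnot(inherits(pair, "repertoire_pair"))
  bl <- stats::setNames(pair$blood$clonotypes$templates,
                        pair$blood$clonotypes$cdr3_aa)
  tu <- stats::setNames(pair$tumor$clonotypes$templates,
                        pair$tumor$clonotypes$cdr3_aa)
  all_cd <- union(names(bl), names(tu))
  comb <- ifelse(is.na(bl[all_cd]), 0, bl[all_cd]) +
    ifelse(is.na(tu[all_cd]), 0, tu[all_cd])
  U <- all_cd[comb >= min_templates]
  if (length(U) == 0) {
    warning("no clone reaches ", min_templates,
            " combined templates for patient ", pair$patient_id)
    return(NA_real_)
  }
  distinct <- vapply(U, function(cd) {
    (!is.na(tu[cd]) && tu[cd] > 0) && (is.na(bl[cd]) || bl[cd] == 0)
  }, TRUE)
  100 * sum(distinct) / length(U)
}

#' Shared, dominantly clonal CDR3 sequences in a cohort
#'
#' Compiles each sample's top `top_n` clonotypes by productive frequency
#' (ties at the boundary rank are all included), then keeps the
#' candidates present at any frequency in at least
#' `ceiling(min_prevalence * n)` of the cohort's samples.
#'
#' @param cohort non-empty list of [repertoire()] objects
#' @param top_n dominance rank cutoff (default 50)
#' @param min_prevalence minimum fraction of samples carrying the clone
#'   (default 0.25, boundary inclusive)
#' @return character vector of shared dominant CDR3 sequences
#' @export
shared_dominant_clones <- function(cohort, top_n = 50,
                                   min_prevalence = 0.25) {
  if (length(cohort) == 0) stop("empty cohort")
  top_of <- function(r) {
    ct <- r$clonotypes
    if (nrow(ct) == 0) return(character(0))
    f <- sort(ct$productive_frequency, decreasing = TRUE)
    thr <- f[min(top_n, length(f))]
    ct$cdr3_aa[ct$productive_frequency >= thr]
  }
  candidates <- unique(unlist(lapply(cohort, top_of)))
  if (length(candidates) == 0) return(character(0))
  presence <- vapply(candidates, function(cd) {
    sum(vapply(cohort,
               function(r) cd %in%
                 r$clonotypes$cdr3_aa[r$clonotypes$templates > 0],
               TRUE))
  }, 0L)
  need <- ceiling(min_prevalence * length(cohort))
  sort(candidates[presence >= need])
}

#' Per-patient burden of shared dominant clones
#'
#' @param patient_reps list of [repertoire()] objects from one patient
#' @param shared character vector from [shared_dominant_clones()]
#' @return list with `count` (distinct shared clones present in the
#'   patient's repertoires) and `total_freq` (their productive-frequency
#'   sum within each sample, averaged across the patient's samples)
#' @export
per_patient_shared_stats <- function(patient_reps, shared) {
  if (length(shared) == 0 || length(patient_reps) == 0)
    return(list(count = 0L, total_freq = 0))
  present <- unique(unlist(lapply(patient_reps, function(r)
    intersect(shared, r$clonotypes$cdr3_aa))))
  per_sample <- vapply(patient_reps, function(r) {
    hit <- r$clonotypes$cdr3_aa %in% shared
    sum(r$clonotypes$productive_frequency[hit])
  }, 0)
  list(count = length(present), total_freq = mean(per_sample))
}

#' Expanded clones across a tumor set
#'
#' A clone is expanded when its template total across the tumors exceeds
#' one per patient on average (strictly more than one template per
#' patient).
#'
#' @param tumors non-empty list of tumor [repertoire()] objects
#' @return character vector of expanded CDR3 sequences
#' @export
expanded_clones <- function(tumors) {
  if (length(tumors) == 0) stop("empty tumor set")
  pts <- unique(vapply(tumors, `[[`, "", "patient_id"))
  n_pat <- if (all(is.na(pts))) length(tumors) else length(pts)
  tot <- tapply(
    unlist(lapply(tumors, function(r) r$clonotypes$templates)),
    unlist(lapply(tumors, function(r) r$clonotypes$cdr3_aa)),
    sum)
  sort(names(tot)[tot / n_pat > 1])
}

#' Match a repertoire against a reference CDR3 list
#'
#' Exact string matching of CDR3 amino-acid sequences against a
#' supplied reference list (for example, published sequences reported
#' as specific for driver-mutation epitopes). Duplicate reference
#' entries are deduplicated.
#'
#' @param rep a [repertoire()]
#' @param reference non-empty character vector of CDR3 sequences
#' @return list with `n_matched` (distinct reference clones present)
#'   and `matched_freqs` (their productive frequencies, named)
#' @export
match_reference_cdr3 <- function(rep, reference) {
  if (length(reference) == 0) stop("empty reference CDR3 list")
  reference <- unique(as.character(reference))
  ct <- rep$clonotypes
  hit <- ct$cdr3_aa %in% reference
  list(n_matched = sum(hit),
       matched_freqs = stats::setNames(ct$productive_frequency[hit],
                                       ct$cdr3_aa[hit]))
}

#' Read a reference CDR3 list (one sequence per line)
#'
#' @param path plain-text file
#' @return character vector of sequences
#' @export
read_reference_cdr3 <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) stop("empty reference CDR3 list: ", path)
  x
}

#' Classify a blood sample relative to disease course
#'
#' Resected patients: blood collected on or before the day of primary
#' resection is primary-associated; after a recurrence,
#' metastasis-associated; between resection and recurrence,
#' uncharacterized. Non-resected patients: blood collected within 180
#' days before the latest confirmed metastasis-free date is
#' primary-associated; blood collected after metastasis detection, or
#' within 30 days before it, is metastasis-associated; anything else is
#' uncharacterized.
#'
#' @param collection_day day the blood was drawn (per-patient clock)
#' @param resection_day,recurrence_day,last_met_free_day,met_detected_day
#'   event day offsets on the same clock; `NA` when the event did not
#'   occur or is unknown
#' @param resected logical, whether the patient was treated by resection
#' @return one of `"primary_associated"`, `"metastasis_associated"`,
#'   `"uncharacterized"`
#' @export
classify_blood_sample <- function(collection_day, resection_day = NA,
                                  recurrence_day = NA,
                                  last_met_free_day = NA,
                                  met_detected_day = NA, resected) {
  if (resected) {
    if (is.na(resection_day))
      stop("resected patient without a resection day")
    if (!is.na(recurrence_day) && recurrence_day < resection_day)
      stop("recurrence before resection: contradictory day offsets")
    if (collection_day <= resection_day) return("primary_associated")
    if (!is.na(recurrence_day) && collection_day > recurrence_day)
      return("metastasis_associated")
    return("uncharacterized")
  }
  if (!is.na(met_detected_day) &&
      (collection_day > met_detected_day ||
       (met_detected_day - collection_day) <= 30))
    return("metastasis_associated")
  if (!is.na(last_met_free_day) &&
      collection_day <= last_met_free_day &&
      (last_met_free_day - collection_day) <= 180)
    return("primary_associated")
  "uncharacterized"
}
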