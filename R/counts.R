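#' Gene-by-sample count container
#'
#' Bundles an integer count matrix with per-gene lengths and a sample
#' annotation table, the raw input to normalization and differential
#' expression. Modeled on the light-weight list containers of the
#' expression-analysis packages (a `DGEList`-style object).
#'
#' @param counts numeric matrix, genes in rows, samples in columns; all
#'   entries finite and non-negative. Dimnames are required and must be
#'   unique: rownames are gene ids, colnames sample ids.
#' @param gene_lengths positive numeric vector of gene lengths in base
#'   pairs, one per gene (recycled names checked against rownames).
#' @param samples optional data.frame of per-sample annotations with one
#'   row per sample; a `sample_id` column is added from colnames if absent.
#'
#' @return An object of class `counts_matrix`: a list with elements
#'   `counts`, `gene_lengths`, `samples`.
#' @export
counts_matrix <- function(counts, gene_lengths = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0) {
    if (is.null(rownames(counts)))
      stop("counts must have gene rownames")
    if (anyDuplicated(rownames(counts)))
      stop("duplicate gene ids in counts")
  }
  if (ncol(counts) > 0) {
    if (is.null(colnames(counts)))
      stop("counts must have sample colnames")
    if (anyDuplicated(colnames(counts)))
      stop("duplicate sample ids in counts")
  }
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != nrow(counts))
      stop("gene_lengths must have one entry per gene")
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive and finite")
    if (!is.null(names(gene_lengths)) &&
        !identical(names(gene_lengths), rownames(counts)))
      gene_lengths <- gene_lengths[rownames(counts)]
    names(gene_lengths) <- rownames(counts)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts) %||% character(0),
                          stringsAsFactors = FALSE)
  } else {
    samples <- as.data.frame(samples)
    if (nrow(samples) != ncol(counts))
      stop("samples must have one row per sample column")
    if (is.null(samples$sample_id))
      samples$sample_id <- colnames(counts) %||% character(0)
    if (ncol(counts) > 0 &&
        !identical(as.character(samples$sample_id), colnames(counts)))
      stop("samples$sample_id must match counts colnames in order")
  }
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 samples = samples),
            class = "counts_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.counts_matrix <- function(x, ...) {
  cat("counts_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  if (!is.null(x$gene_lengths)) cat("  gene lengths present\n")
  cat("  sample annotations:", paste(names(x$samples), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' Subset a counts_matrix by gene and/or sample
#'
#' @param x a `counts_matrix`
#' @param i gene index (ids, logical or integer)
#' @param j sample index
#' @param ... unused
#' @return a `counts_matrix` restricted to the selected genes/samples
#' @export
`[.counts_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts_matrix(x$counts[i, j, drop = FALSE],
                if (!is.null(x$gene_lengths)) x$gene_lengths[i],
                x$samples[match(colnames(x$counts[, j, drop = FALSE]),
                                x$samples$sample_id), , drop = FALSE])
}

#' Real-valued expression matrix with a transform tag
#'
#' @param values numeric matrix (genes x samples) of finite values.
#' @param transform_tag one of `"tpm"`, `"log_cpm_tmm"`, `"vst_like"` —
#'   recorded so downstream outputs are labeled with the scale they were
#'   computed on.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              transform_tag = c("tpm", "log_cpm_tmm",
                                                "vst_like")) {
  transform_tag <- match.arg(transform_tag)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, transform_tag = transform_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$transform_tag, "]: ", nrow(x$values),
      " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read a genes-by-samples counts TSV
#'
#' First column holds gene ids, header holds sample ids.
#'
#' @param path counts TSV path
#' @param lengths_path optional two-column TSV (gene id, length in bp)
#' @param samples_path optional sample annotation CSV with a `sample_id`
#'   column
#' @return a [counts_matrix()]
#' @export
read_counts_tsv <- function(path, lengths_path = NULL, samples_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, header = TRUE,
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(lt[[2]], lt[[1]])[rownames(counts)]
  }
  samples <- NULL
  if (!is.null(samples_path)) {
    samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
    samples <- samples[match(colnames(counts), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  counts_matrix(counts, lengths, samples)
}

#' Write a counts_matrix to TSV (plus optional lengths/sample sidecars)
#'
#' @param cm a [counts_matrix()]
#' @param path counts TSV destination
#' @param lengths_path,samples_path optional sidecar destinations
#' @return `path`, invisibly
#' @export
write_counts_tsv <- function(cm, path, lengths_path = NULL,
                             samples_path = NULL) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(cm$gene_lengths))
    utils::write.table(
      data.frame(gene_id = names(cm$gene_lengths), length = cm$gene_lengths),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.csv(cm$samples, samples_path, row.names = FALSE)
  invisible(path)
}
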