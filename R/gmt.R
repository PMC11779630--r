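#' Gene set constructor
#'
#' @param name set name
#' @param genes character vector of gene ids; duplicates are removed with
#'   a warning, an empty set is an error.
#' @return an object of class `gene_set` (list with `name`, `genes`).
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("duplicate genes in set '", name, "' deduplicated")
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path
#' @return a named list of [gene_set()] objects
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line ", i, " ('", parts[1], "') has no genes")
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects
#' @param path destination
#' @param descriptions optional character vector of per-set descriptions
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    paste(c(s$name, descriptions[i], s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
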