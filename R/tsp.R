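#' Load a top-scoring-pairs classifier model
#'
#' The model ships as data (JSON), not code: gene pairs, per-pair
#' logistic weights, an intercept and a calling threshold, in the layout
#' of the published single-sample subtype classifiers.
#'
#' @param path JSON file with fields `pairs` (list of 2-gene arrays),
#'   `weights`, `intercept`, `threshold`.
#' @return object of class `tsp_model`.
#' @export
read_tsp_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pairs", "weights", "intercept", "threshold")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("TSP model file lacks field(s): ", paste(miss, collapse = ", "))
  pairs <- m$pairs
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.list(pairs) && !is.matrix(pairs))
    pairs <- do.call(rbind, pairs)
  if (ncol(pairs) != 2 || nrow(pairs) != length(m$weights))
    stop("TSP model: pairs must be K x 2 with one weight per pair")
  if (any(pairs[, 1] == pairs[, 2]))
    stop("TSP model: a pair references the same gene twice")
  if (any(!is.finite(m$weights)) || !is.finite(m$intercept))
    stop("TSP model: weights and intercept must be finite")
  structure(list(pairs = pairs, weights = as.numeric(m$weights),
                 intercept = as.numeric(m$intercept),
                 threshold = as.numeric(m$threshold)),
            class = "tsp_model")
}

#' Top-scoring-pairs subtype score and call
#'
#' For each sample, each pair contributes an indicator
#' `I = 1 if expr(a) > expr(b) else 0` (ties give 0); the subtype score
#' is `logistic(intercept + sum(weights * I))` and the call is
#' basal-like when the score exceeds the model threshold. Because only
#' within-sample comparisons enter, the call is invariant to any
#' monotone per-sample transformation of the expression values.
#'
#' @param expr an [expression_matrix()] containing every model gene
#'   (missing genes are an error listing them).
#' @param model a `tsp_model` from [read_tsp_model()].
#' @return data.frame with `sample_id`, `score` (in (0, 1)) and `call`
#'   (`"basal-like"` / `"classical"`).
#' @export
tsp_score <- function(expr, model) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(model, "tsp_model"))
  X <- expr$values
  miss <- setdiff(unique(as.vector(model$pairs)), rownames(X))
  if (length(miss))
    stop("model genes missing from expression matrix: ",
         paste(miss, collapse = ", "))
  ind <- (X[model$pairs[, 1], , drop = FALSE] >
            X[model$pairs[, 2], , drop = FALSE]) + 0
  score <- stats::plogis(model$intercept +
                           as.numeric(crossprod(ind, model$weights)))
  data.frame(sample_id = colnames(X), score = score,
             call = ifelse(score > model$threshold, "basal-like",
                           "classical"),
             stringsAsFactors = FALSE)
}
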