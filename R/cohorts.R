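#' Top/bottom quartile cohort assignment
#'
#' Labels each sample `high` (score at or above the 75th percentile),
#' `low` (at or below the 25th), or `mid`. Percentiles use linear
#' interpolation (quantile type 7). The sample universe over which the
#' quartiles are computed (all primaries, all metastases, all tumors) is
#' whatever the caller passes in.
#'
#' @param scores named numeric vector of per-sample scores (>= 4 values).
#' @return character vector of labels, named like `scores`. If all
#'   scores are equal every sample is `mid`, with a warning.
#' @export
quartile_cohorts <- function(scores) {
  if (length(scores) < 4)
    stop("quartile cohorts need at least 4 samples")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) == 1) {
    warning("all scores equal; every sample labeled 'mid'")
    return(stats::setNames(rep("mid", length(scores)), names(scores)))
  }
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  lab <- rep("mid", length(scores))
  lab[scores >= q[2]] <- "high"
  lab[scores <= q[1]] <- "low"
  both <- scores >= q[2] & scores <= q[1]
  if (any(both)) {
    warning("degenerate quartiles: ", sum(both),
            " sample(s) in both tails labeled 'mid'")
    lab[both] <- "mid"
  }
  stats::setNames(lab, names(scores))
}
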