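#' Two-factor design matrix for organotropism x subtype
#'
#' Builds the design used throughout the pipeline: an intercept, an
#' organotropism indicator (1 = liver-like) and a subtype indicator
#' (1 = basal-like).
#'
#' @param samples data.frame with `organ_factor` and `subtype_factor`
#'   columns (character or factor; liver-like/basal-like are the coded
#'   levels).
#' @param organ_level,subtype_level values coded as 1 in each column.
#' @return numeric matrix with columns `intercept`, `organ`, `subtype`
#'   and sample ids as rownames; errors if either factor is single-level
#'   or the matrix is rank-deficient.
#' @export
two_factor_design <- function(samples, organ_level = "liver-like",
                              subtype_level = "basal-like") {
  for (col in c("organ_factor", "subtype_factor"))
    if (is.null(samples[[col]])) stop("samples lacks column ", col)
  org <- as.integer(as.character(samples$organ_factor) == organ_level)
  sub <- as.integer(as.character(samples$subtype_factor) == subtype_level)
  if (length(unique(org)) < 2)
    stop("degenerate design: organ factor has a single level")
  if (length(unique(sub)) < 2)
    stop("degenerate design: subtype factor has a single level")
  X <- cbind(intercept = 1, organ = org, subtype = sub)
  rownames(X) <- samples$sample_id
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (confounded factors)")
  X
}

# TMM-scaled effective library sizes, normalized to geometric mean 1,
# used as NB size factors throughout the DE fits.
size_factors <- function(cm) {
  libsize <- colSums(cm$counts)
  if (any(libsize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[libsize == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(edgeR::DGEList(counts = cm$counts),
                              method = "TMM")$samples$norm.factors
  eff <- libsize * f
  eff / exp(mean(log(eff)))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimator from group-wise residual variance of
#' size-factor-normalized counts (groups = distinct design rows), under
#' the NB parameterization `var = mu + alpha * mu^2`, floored at 1e-8,
#' then shrunk on the log scale toward a local-regression trend of
#' dispersion on mean expression.
#'
#' @param cm a [counts_matrix()] (low-expression genes filtered upstream).
#' @param design design matrix from [two_factor_design()].
#' @param shrink weight given to the per-gene estimate (default 0.5;
#'   the complement goes to the fitted trend).
#' @return named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(cm, design, shrink = 0.5) {
  stopifnot(inherits(cm, "counts_matrix"))
  n <- ncol(cm$counts)
  grp <- apply(design, 1, paste, collapse = "/")
  ngrp <- length(unique(grp))
  if (n - ngrp < 2)
    stop("fewer than 2 residual degrees of freedom (n = ", n,
         ", groups = ", ngrp, ")")
  s <- size_factors(cm)
  y <- sweep(cm$counts, 2, s, "/")
  mean_inv_s <- mean(1 / s)
  groups <- split(seq_len(n), grp)
  # pooled within-group variance and grand mean per gene
  ss <- matrix(0, nrow(y), 1)
  df <- 0
  for (idx in groups) {
    if (length(idx) < 2) next
    gm <- rowMeans(y[, idx, drop = FALSE])
    ss <- ss + rowSums((y[, idx, drop = FALSE] - gm)^2)
    df <- df + length(idx) - 1
  }
  v <- as.numeric(ss) / df
  mu <- rowMeans(y)
  raw <- (v - mu * mean_inv_s) / mu^2
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, 1e-8)
  # log-log local-regression trend, fitted on expressed genes
  use <- mu > 0
  alpha <- raw
  if (sum(use) >= 10 && length(unique(mu[use])) > 2) {
    lo <- stats::lowess(log(mu[use]), log(raw[use]), f = 0.5)
    trend <- exp(stats::approx(lo$x, lo$y, xout = log(mu[use]),
                               rule = 2)$y)
    alpha[use] <- exp(shrink * log(raw[use]) + (1 - shrink) * log(trend))
  }
  alpha <- pmax(alpha, 1e-8)
  stats::setNames(alpha, rownames(cm$counts))
}

#' Two-factor negative-binomial differential expression
#'
#' Per gene, fits an NB log-link GLM with the two-factor design and
#' TMM-scaled library-size offsets by iteratively reweighted least
#' squares, and reports per-coefficient Wald tests with BH-adjusted FDR
#' computed within each factor.
#'
#' @param cm a [counts_matrix()] (filtered; all-zero genes are dropped
#'   with a message).
#' @param design design matrix from [two_factor_design()].
#' @param dispersion optional per-gene dispersions; estimated with
#'   [estimate_dispersion()] when missing.
#' @return object of class `de_result`: list with `table` (per-gene
#'   baseMean, dispersion, and log2fc/se/stat/p/fdr per factor),
#'   `factors`, and `n_dropped`. Non-converged fits are flagged and
#'   assigned p = 1.
#' @export
fit_two_factor <- function(cm, design, dispersion = NULL) {
  stopifnot(inherits(cm, "counts_matrix"))
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient")
  keep <- rowSums(cm$counts) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " all-zero gene(s) before fitting")
    cm <- cm[keep, ]
    if (!is.null(dispersion)) dispersion <- dispersion[keep]
  }
  if (is.null(dispersion)) dispersion <- estimate_dispersion(cm, design)
  # offset = log TMM-scaled effective library size, geometric mean 1,
  # so the intercept stays on the counts scale
  s <- size_factors(cm)
  off <- log(s)
  G <- nrow(cm$counts)
  coefs <- c("organ", "subtype")
  out <- data.frame(gene = rownames(cm$counts),
                    baseMean = rowMeans(sweep(cm$counts, 2, s, "/")),
                    dispersion = as.numeric(dispersion),
                    converged = TRUE, stringsAsFactors = FALSE)
  for (cf in coefs)
    for (fld in c("log2fc", "se", "stat", "p"))
      out[[paste(fld, cf, sep = "_")]] <- NA_real_
  jorg <- match("organ", colnames(design))
  jsub <- match("subtype", colnames(design))
  for (g in seq_len(G)) {
    y <- cm$counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / max(dispersion[g], 1e-8))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(design, y, family = fam,
                                      offset = off)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged && all(is.finite(fit$coefficients))
    if (!ok) {
      out$converged[g] <- FALSE
      for (cf in coefs) {
        out[[paste0("log2fc_", cf)]][g] <- 0
        out[[paste0("se_", cf)]][g] <- NA_real_
        out[[paste0("stat_", cf)]][g] <- 0
        out[[paste0("p_", cf)]][g] <- 1
      }
      next
    }
    R <- qr.R(fit$qr)
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    se <- if (is.null(cov)) rep(NA_real_, ncol(design)) else
      sqrt(pmax(diag(cov), 0))[order(fit$qr$pivot)]
    for (cf in coefs) {
      j <- if (cf == "organ") jorg else jsub
      b <- fit$coefficients[j]
      out[[paste0("log2fc_", cf)]][g] <- b / log(2)
      out[[paste0("se_", cf)]][g] <- se[j] / log(2)
      z <- if (is.finite(se[j]) && se[j] > 0) b / se[j] else 0
      out[[paste0("stat_", cf)]][g] <- z
      out[[paste0("p_", cf)]][g] <- 2 * stats::pnorm(-abs(z))
    }
  }
  for (cf in coefs)
    out[[paste0("fdr_", cf)]] <- bh_adjust(out[[paste0("p_", cf)]])
  structure(list(table = out, factors = coefs, n_dropped = n_dropped),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$table), "genes, factors:",
      paste(x$factors, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one factor's DE table
#'
#' @param de a `de_result`
#' @param factor `"organ"` or `"subtype"`
#' @return data.frame with columns gene, baseMean, log2fc, se, stat, p, fdr
#' @export
de_table <- function(de, factor = c("organ", "subtype")) {
  factor <- match.arg(factor)
  t <- de$table
  data.frame(gene = t$gene, baseMean = t$baseMean,
             log2fc = t[[paste0("log2fc_", factor)]],
             se = t[[paste0("se_", factor)]],
             stat = t[[paste0("stat_", factor)]],
             p = t[[paste0("p_", factor)]],
             fdr = t[[paste0("fdr_", factor)]],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, returned in the
#' input order. NaN entries propagate as NaN with a warning and do not
#' enter the adjustment.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NaN allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  bad <- is.nan(p)
  if (any(bad)) warning(sum(bad), " NaN p-value(s) propagated")
  if (any(p[!bad] < 0 | p[!bad] > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NaN, length(p))
  out[!bad] <- stats::p.adjust(p[!bad], method = "BH")
  out
}
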