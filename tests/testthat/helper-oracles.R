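# Independent reference implementations used as oracles. These are
# deliberately written as plain loops, separate from the package code
# paths they check.

# Textbook TMM: doubly trimmed, precision-weighted mean of M-values,
# reference = sample whose upper-quartile fraction is closest to the mean.
tmm_oracle <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib[j]
    refd <- counts[, ref] / lib[ref]
    keep <- obs > 0 & refd > 0
    M <- log2(obs[keep] / refd[keep])
    A <- 0.5 * log2(obs[keep] * refd[keep])
    w <- (1 - counts[keep, j] / lib[j]) / counts[keep, j] +
      (1 - counts[keep, ref] / lib[ref]) / counts[keep, ref]
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1;      hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k] / w[k]) / sum(1 / w[k]))
  })
  f / exp(mean(log(f)))
}

# Step-by-step kernel-CDF enrichment scorer: explicit loops, no shared
# code with gsva_scores().
gsva_oracle <- function(X, set_genes, tau = 1, variant = "max_diff") {
  N <- nrow(X); n <- ncol(X)
  z <- matrix(0, N, n)
  for (i in seq_len(N)) {
    h <- max(stats::sd(X[i, ]), 1e-8) / 4
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + stats::pnorm((X[i, j] - X[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  inset <- rownames(X) %in% set_genes
  m <- sum(inset)
  out <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rnk <- integer(N); rnk[ord] <- seq_len(N)
    r <- abs(N / 2 - rnk)
    denom <- sum(r[inset]^tau)
    v <- 0; vmax <- 0; vmin <- 0; vabs <- 0; varg <- 0
    for (pos in seq_len(N)) {
      g <- ord[pos]
      v <- v + if (inset[g]) r[g]^tau / denom else -1 / (N - m)
      if (v > vmax) vmax <- v
      if (v < vmin) vmin <- v
      if (abs(v) > vabs) { vabs <- abs(v); varg <- v }
    }
    out[j] <- if (variant == "max_diff") vmax + vmin else varg
  }
  out
}

# Exhaustive two-sided Fisher p: enumerate every table with the observed
# margins and sum the probabilities at most as likely as observed.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Youden scan over the rule "score >= t predicts short",
# evaluated at every observed score value.
youden_oracle <- function(scores, short) {
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[short] >= t)
    spec <- mean(scores[!short] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, youden = best_j)
}

# Build a de_result object from explicit per-factor statistics, for
# tests that exercise derivation logic on constructed tables.
make_de_result <- function(genes, lfc_org, p_org, lfc_sub, p_sub) {
  tab <- data.frame(gene = genes, baseMean = 100, dispersion = 0.1,
                    converged = TRUE,
                    log2fc_organ = lfc_org, se_organ = 0.1,
                    stat_organ = lfc_org / 0.1, p_organ = p_org,
                    log2fc_subtype = lfc_sub, se_subtype = 0.1,
                    stat_subtype = lfc_sub / 0.1, p_subtype = p_sub,
                    stringsAsFactors = FALSE)
  tab$fdr_organ <- bh_adjust(tab$p_organ)
  tab$fdr_subtype <- bh_adjust(tab$p_subtype)
  structure(list(table = tab, factors = c("organ", "subtype"),
                 n_dropped = 0L), class = "de_result")
}

# Minimal repertoire builder for hand-constructed clone tables.
make_rep <- function(id, cdr3, templates, patient = "PT1",
                     compartment = "blood", tissue = "blood",
                     input_ng = NA_real_) {
  repertoire(id, data.frame(cdr3_aa = cdr3, templates = templates,
                            stringsAsFactors = FALSE),
             patient, compartment, tissue, input_ng)
}

# Valid CDR3-like strings for fixtures (deterministic, distinct).
fixture_cdr3 <- function(n, prefix = "CASS") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  g <- expand.grid(a = aa, b = aa, c = aa, stringsAsFactors = FALSE)
  stopifnot(n <= nrow(g))
  paste0(prefix, g$a[seq_len(n)], g$b[seq_len(n)], g$c[seq_len(n)], "F")
}
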