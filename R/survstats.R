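#' Exclude early post-surgical deaths
#'
#' Removes resected patients who died fewer than 30 days after surgery,
#' so that deaths from surgical complications do not enter survival
#' analyses. Non-resected patients (missing `resection_to_death_days`)
#' pass through.
#'
#' @param records data.frame of survival records with an optional
#'   `resection_to_death_days` column
#' @param min_days minimum post-surgical survival (default 30; day 30
#'   itself is retained)
#' @return the filtered data.frame
#' @export
thirty_day_filter <- function(records, min_days = 30) {
  if (is.null(records$resection_to_death_days)) return(records)
  drop <- !is.na(records$resection_to_death_days) &
    records$resection_to_death_days < min_days
  records[!drop, , drop = FALSE]
}

#' Kaplan-Meier curve with median survival
#'
#' Product-limit estimator with Greenwood confidence bands. The median
#' is the earliest time at which the survival function falls to 0.5 or
#' below, and is missing when the curve never reaches it.
#'
#' @param records data.frame with `time` (days) and `event` (0/1)
#' @param conf_level confidence level for the bands (default 0.95)
#' @return list with `curve` (data.frame: time, n_risk, n_event,
#'   surv, se, lower, upper) and `median`
#' @export
km_curve <- function(records, conf_level = 0.95) {
  stopifnot(nrow(records) >= 1, all(records$time >= 0),
            all(records$event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.int = conf_level,
                           conf.type = "log")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      se = fit$std.err * fit$surv,
                      lower = fit$lower, upper = fit$upper)
  med <- curve$time[curve$surv <= 0.5]
  list(curve = curve,
       median = if (length(med)) min(med) else NA_real_)
}

#' Log-rank test between survival groups
#'
#' @param records data.frame with `time`, `event` and a grouping column
#' @param group name of the grouping column (default `"group"`)
#' @return list with `chi2`, `df`, `p`
#' @export
logrank_test <- function(records, group = "group") {
  g <- records[[group]]
  if (is.null(g)) stop("grouping column '", group, "' not found")
  tab <- table(g)
  if (length(tab) < 2) stop("log-rank needs at least 2 groups")
  if (any(tab == 0)) stop("empty group in log-rank test")
  if (sum(records$event) < 1) stop("log-rank needs at least one event")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = records$time, event = records$event, g = g))
  df <- length(tab) - 1
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Newton-Raphson, as implemented in the
#' `survival` package) with Efron or Breslow ties handling; reports per
#' covariate the log-hazard coefficient, hazard ratio, standard error,
#' Wald p and a 95% CI. Complete cases only.
#'
#' @param records data.frame with `time`, `event` and covariate columns
#' @param covariates character vector of covariate column names
#' @param ties `"efron"` (default) or `"breslow"`
#' @return object of class `cox_fit`: list with `table` (term, beta,
#'   hr, se, p, ci_lower, ci_upper), `n`, `ties`, `converged`
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  keep <- stats::complete.cases(records[, c("time", "event", covariates),
                                        drop = FALSE])
  records <- records[keep, , drop = FALSE]
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v)) < 2)
      stop("covariate '", cv, "' is constant across records")
  }
  if (sum(records$event) < length(covariates))
    stop("fewer events than covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  s <- summary(fit, conf.int = 0.95)
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    warning("possible separation/monotone likelihood: ",
            "a coefficient is infinite or extreme")
  structure(list(
    table = data.frame(term = names(beta), beta = as.numeric(beta),
                       hr = as.numeric(exp(beta)),
                       se = s$coefficients[, "se(coef)"],
                       p = s$coefficients[, "Pr(>|z|)"],
                       ci_lower = s$conf.int[, "lower .95"],
                       ci_upper = s$conf.int[, "upper .95"],
                       row.names = NULL, stringsAsFactors = FALSE),
    n = fit$n, ties = ties,
    converged = fit$iter < 50), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit (", x$ties, " ties, n = ", x$n, ")\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' ROC / Youden-index score cutoff for survival dichotomization
#'
#' Labels patients as short-term survivors (death before
#' `horizon_days`) or long-term survivors (observed beyond it,
#' regardless of event status); patients censored before the horizon
#' have an unknowable class and are excluded (their count is reported).
#' All midpoints between adjacent sorted unique scores are scanned and
#' the cutoff maximizing Youden's J = sensitivity + specificity - 1
#' for the rule "score >= cutoff predicts short-term" is returned, with
#' ties resolved to the lowest cutoff.
#'
#' @param scores numeric vector, one per record
#' @param records data.frame with `time` and `event`
#' @param horizon_days the survival horizon (default 545)
#' @return list with `cutoff`, `youden`, `n_short`, `n_long`,
#'   `n_excluded`
#' @export
youden_cutoff <- function(scores, records, horizon_days = 545) {
  stopifnot(length(scores) == nrow(records))
  short <- records$event == 1 & records$time < horizon_days
  long <- records$time > horizon_days
  usable <- short | long
  if (!any(short)) stop("no short-term survivors before the horizon")
  if (!any(long)) stop("no long-term survivors beyond the horizon")
  sc <- scores[usable]
  y <- short[usable]
  u <- sort(unique(sc))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  J <- vapply(cand, function(ct) {
    sens <- mean(sc[y] >= ct)
    spec <- mean(sc[!y] < ct)
    sens + spec - 1
  }, 0)
  best <- min(cand[J == max(J)])
  list(cutoff = best, youden = max(J), n_short = sum(y),
       n_long = sum(!y), n_excluded = sum(!usable))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return two-sided p-value (sum of hypergeometric probabilities of
#'   all tables with fixed margins at most as probable as the observed
#'   one, with a small relative slack for floating-point ties)
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero contingency table")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Correlation coefficient with two-sided p
#'
#' Pearson for Gaussian data, Spearman for non-Gaussian, Kendall's tau
#' for censored/ordinal data.
#'
#' @param x,y numeric vectors of equal length >= 3, finite,
#'   non-constant
#' @param method `"pearson"`, `"spearman"` or `"kendall"`
#' @return list with `estimate` and `p`
#' @export
correlate <- function(x, y, method = c("pearson", "spearman",
                                       "kendall")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in correlation input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value)
}

#' Two-group and multi-group comparisons
#'
#' Two-sided t-test for two Gaussian groups, one-way ANOVA for more
#' than two, Kruskal-Wallis for non-Gaussian data.
#'
#' @param values numeric vector
#' @param labels group labels, same length
#' @param test `"t"`, `"anova"` or `"kruskal"`
#' @return p-value
#' @export
group_compare <- function(values, labels, test = c("t", "anova",
                                                   "kruskal")) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("group comparison needs at least 2 groups")
  if (test %in% c("t", "anova") && any(tab < 2))
    stop("each group needs at least 2 values for ", test)
  if (test == "t" && length(tab) != 2)
    stop("t-test compares exactly 2 groups")
  switch(test,
         t = stats::t.test(values ~ labels)$p.value,
         anova = summary(stats::aov(values ~ labels))[[1]][["Pr(>F)"]][1],
         kruskal = stats::kruskal.test(values, labels)$p.value)
}
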