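test_that("early post-surgical deaths are excluded at the 30-day boundary", {
  rec <- data.frame(patient_id = paste0("p", 1:4),
                    time = c(29, 30, 400, 500), event = c(1, 1, 0, 1),
                    resection_to_death_days = c(29, 30, NA, 45))
  out <- thirty_day_filter(rec)
  expect_setequal(out$patient_id, c("p2", "p3", "p4"))
  # records without the column pass through untouched
  rec2 <- rec[, 1:3]
  expect_equal(thirty_day_filter(rec2), rec2)
})

test_that("Kaplan-Meier estimator matches hand product-limit arithmetic", {
  rec <- data.frame(time = 1:5, event = 1)
  km <- km_curve(rec)
  expect_equal(km$curve$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  cens <- data.frame(time = c(10, 20, 30), event = 0)
  km2 <- km_curve(cens)
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))

  one <- km_curve(data.frame(time = 7, event = 1))
  expect_equal(one$curve$surv[one$curve$time == 7], 0)

  # with no censoring the KM curve equals the empirical survival
  set.seed(51)
  t <- round(rexp(40, 1 / 100), 3)
  km3 <- km_curve(data.frame(time = t, event = 1))
  emp <- vapply(km3$curve$time, function(x) mean(t > x), 0)
  expect_equal(km3$curve$surv, emp, tolerance = 1e-12)
})

test_that("log-rank agrees with the Cox score test and handles nulls", {
  set.seed(52)
  rec <- data.frame(time = rexp(60, 1 / 100),
                    event = rbinom(60, 1, 0.8),
                    group = rep(c("a", "b"), 30))
  lr <- logrank_test(rec)
  sc <- summary(survival::coxph(
    survival::Surv(time, event) ~ group, data = rec))$sctest[["test"]]
  expect_equal(lr$chi2, sc, tolerance = 1e-6)

  # two identical groups: statistic collapses to zero
  twin <- data.frame(time = rep(c(5, 10, 15), 2),
                     event = 1, group = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(twin)
  expect_lt(lr2$chi2, 1e-10)
  expect_gt(lr2$p, 0.99)
  expect_error(logrank_test(data.frame(time = 1:3, event = 1,
                                       group = "a")), "2 groups")
  expect_error(logrank_test(data.frame(time = 1:4, event = 0,
                                       group = rep(c("a", "b"), 2))),
               "one event")
})

test_that("Cox fit matches a closed-form partial-likelihood optimum", {
  # four subjects, two events, continuous covariate; the oracle
  # maximizes the hand-written Efron/Breslow-free partial likelihood
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                    x = c(0.5, -0.2, 1.0, -1.0))
  # no ties: partial likelihood has two event terms
  nll <- function(b) {
    risk1 <- exp(b * rec$x) # all four at risk at t = 1
    risk2 <- exp(b * rec$x[2:4]) # three at risk at t = 2
    -(b * rec$x[1] - log(sum(risk1)) + b * rec$x[2] - log(sum(risk2)))
  }
  opt <- stats::optimize(nll, c(-10, 10), tol = 1e-12)
  fit <- cox_fit(rec, "x")
  expect_equal(fit$table$beta, opt$minimum, tolerance = 1e-6)
  expect_equal(fit$table$hr, exp(opt$minimum), tolerance = 1e-6)
  expect_true(fit$table$ci_lower < fit$table$hr &
                fit$table$hr < fit$table$ci_upper)
  expect_error(cox_fit(transform(rec, x = 1), "x"), "constant")
})

test_that("null data give a hazard ratio near one", {
  set.seed(53)
  rec <- data.frame(time = rexp(500, 1 / 300), event = 1,
                    score = rnorm(500))
  fit <- cox_fit(rec, "score")
  expect_gt(fit$table$hr, 0.85)
  expect_lt(fit$table$hr, 1.18)
})

test_that("Youden cutoff equals the brute-force scan", {
  # perfectly separating scores
  rec <- data.frame(time = c(rep(100, 5), rep(900, 5)),
                    event = c(rep(1, 5), rep(0, 5)))
  sc <- c(rep(2, 5), rep(-2, 5))
  yc <- youden_cutoff(sc, rec)
  expect_equal(yc$youden, 1)
  expect_true(yc$cutoff > -2 && yc$cutoff <= 2)

  set.seed(54)
  n <- 80
  rec2 <- data.frame(time = sample(c(100, 300, 700, 1200), n, TRUE),
                     event = rbinom(n, 1, 0.7))
  sc2 <- rnorm(n)
  ok <- (rec2$event == 1 & rec2$time < 545) | rec2$time > 545
  yc2 <- youden_cutoff(sc2, rec2)
  orc <- youden_oracle(sc2[ok],
                       (rec2$event == 1 & rec2$time < 545)[ok])
  expect_equal(yc2$youden, orc$youden, tolerance = 1e-12)
  # the midpoint cutoff induces the same partition as the oracle value
  expect_equal(sc2[ok] >= yc2$cutoff, sc2[ok] >= orc$threshold)
  expect_equal(yc2$n_excluded, sum(!ok))

  # everyone censored before the horizon: no usable classes
  allc <- data.frame(time = rep(100, 6), event = 0)
  expect_error(youden_cutoff(rnorm(6), allc), "short-term")
})

test_that("Fisher's exact matches exhaustive enumeration", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(55)
  for (i in 1:60) {
    N <- sample(4:30, 1)
    a_ <- sample(0:N, 1); r1 <- sample(a_:N, 1)
    c1 <- sample(a_:(N - (r1 - a_)), 1)
    tab <- matrix(c(a_, r1 - a_, c1 - a_, N - r1 - c1 + a_), 2,
                  byrow = TRUE)
    if (any(tab < 0) || sum(tab) == 0) next
    expect_equal(fisher_exact(tab), fisher_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("correlations match closed forms and rank oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x, "pearson")$estimate, 1)
  # monotone transform: spearman stays 1, pearson drops below
  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  set.seed(56)
  a <- rnorm(20); b <- rnorm(20)
  # brute-force rank computation oracle
  manual <- stats::cor(rank(a), rank(b))
  expect_equal(correlate(a, b, "spearman")$estimate, manual,
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("group comparisons dispatch the right tests", {
  set.seed(57)
  # identical groups: t statistic is exactly zero
  v0 <- rep(c(1.2, 3.4, 2.2), 2)
  expect_equal(group_compare(v0, rep(c("a", "b"), each = 3), "t"), 1)
  g1 <- rnorm(30); g2 <- rnorm(30) + 2
  expect_lt(group_compare(c(g1, g2), rep(c("a", "b"), each = 30), "t"),
            0.01)
  expect_lt(group_compare(c(g1, g2, rnorm(30) + 1),
                          rep(c("a", "b", "c"), each = 30), "anova"),
            0.01)
  # kruskal is invariant under monotone transforms
  v <- c(g1, g2)
  lb <- rep(c("a", "b"), each = 30)
  expect_equal(group_compare(v, lb, "kruskal"),
               group_compare(exp(v), lb, "kruskal"))
  expect_error(group_compare(g1, rep("a", 30)), "2 groups")
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b"), "t"),
               "at least 2 values")
})
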