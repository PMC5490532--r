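# Method-agreement battery.

test_that("Lin's CCC matches direct moment arithmetic and its bounds", {
  x <- c(10, 12, 14, 16, 20); y <- c(11, 12.5, 13, 17, 19.5)
  cc <- lin_ccc(x, y)
  expect_equal(cc$ccc, oracle_ccc(x, y), tolerance = 1e-12)
  expect_equal(cc$ccc, 0.9679193, tolerance = 1e-6)   # frozen hand value
  expect_true(cc$lower < cc$ccc && cc$ccc < cc$upper)
  # perfect agreement and perfect reversal
  expect_equal(lin_ccc(x, x)$ccc, 1)
  z <- c(-2, -1, 0, 1, 2)
  expect_equal(lin_ccc(z, -z)$ccc, -1)
  # CCC <= |pearson r| on random inputs, equality iff matched moments
  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(20, 10, 3); b <- 0.6 * a + rnorm(20, i %% 5, 2)
    cc <- lin_ccc(a, b)
    expect_lte(cc$ccc, abs(cc$pearson_r) + 1e-12)
  }
  expect_error(lin_ccc(rep(1, 5), 1:5), "variance")
})

test_that("Bland-Altman reports mean difference with multiplier-SD limits", {
  x <- c(4, 9, 13, 28)
  ba <- bland_altman(x, x)
  expect_equal(c(ba$mean_diff, ba$lower, ba$upper), c(0, 0, 0))
  ba5 <- bland_altman(x + 5, x)
  expect_equal(c(ba5$mean_diff, ba5$lower, ba5$upper), c(5, 5, 5))
  set.seed(32)
  d <- rnorm(2000, 1, 3)
  ba2 <- bland_altman(100 + d, rep(100, 2000), multiplier = 2.5)
  expect_equal(ba2$upper - ba2$lower, 2 * 2.5 * sd(d))
  # limits contain ~95% of Gaussian differences at the default 1.96
  m <- rep(60, 1e5)
  p <- m + rnorm(1e5, 0, 7)
  ba3 <- bland_altman(p, m)
  inside <- mean(p - m >= ba3$lower & p - m <= ba3$upper)
  expect_equal(inside, 0.95, tolerance = 0.02)
})

test_that("mean prediction error is the RMS difference and dominates the bias", {
  x <- c(30, 50, 70)
  expect_equal(mean_prediction_error(x, x), 0)
  expect_equal(mean_prediction_error(x + 4, x), 4)
  expect_equal(mean_prediction_error(x - 4, x), 4)
  d <- c(-3, 1, 7)
  expect_equal(mean_prediction_error(x + d, x), sqrt(mean(d^2)))
  expect_equal(mean_prediction_error(x + d, x, type = "mae"), mean(abs(d)))
  # RMSE >= |Bland-Altman mean difference| always
  set.seed(33)
  for (i in 1:20) {
    a <- runif(15, 20, 90); b <- a + rnorm(15, i - 10, 5)
    expect_gte(mean_prediction_error(a, b),
               abs(bland_altman(a, b)$mean_diff) - 1e-12)
  }
  # differences N(0, sigma^2) at large n give MPE ~ sigma
  e <- rnorm(5e4, 0, 8.9)
  expect_equal(mean_prediction_error(50 + e, rep(50, 5e4)), 8.9,
               tolerance = 0.02)
})

test_that("percent-within matches exhaustive enumeration", {
  x <- c(100, 100, 100, 100)
  expect_equal(pct_within(x, x, 0.15), 1)
  expect_equal(pct_within(c(100, 100, 100, 150), x, 0.30), 0.75)
  set.seed(34)
  m <- runif(200, 30, 120)
  p <- m * runif(200, 0.6, 1.4)
  for (thr in c(0.15, 0.30))
    expect_equal(pct_within(p, m, thr),
                 sum(abs(p - m) / m <= thr) / length(m))
  expect_error(pct_within(c(1, 2, 0.5), c(1, 2, 0), 0.3), "positive")
})

test_that("ROC analysis equals exhaustive concordant-pair counting", {
  set.seed(35)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    cond <- rep(FALSE, n)
    cond[sample(n, sample(2:(n - 2), 1))] <- TRUE
    # half the cases with heavy ties to exercise the midpoint convention
    scores <- if (i %% 2) round(runif(n, 0, 10)) else runif(n, 0, 100)
    scores[cond] <- scores[cond] - i %% 4          # impaired score lower
    r <- roc_analysis(scores, cond)
    expect_equal(r$auc, oracle_auc(scores, cond), tolerance = 1e-12)
  }
})

test_that("ROC extremes: perfect separation and uninformative scores", {
  cond <- rep(c(TRUE, FALSE), each = 20)
  scores <- c(runif(20, 0, 10), runif(20, 20, 30))
  r <- roc_analysis(scores, cond)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  set.seed(36)
  r0 <- roc_analysis(rnorm(4000), rbinom(4000, 1, 0.4) == 1)
  expect_equal(r0$auc, 0.5, tolerance = 0.03)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "classes")
})

test_that("paired DeLong AUC comparison behaves at the boundaries", {
  set.seed(37)
  cond <- rbinom(400, 1, 0.5) == 1
  s1 <- rnorm(400) - 2 * cond          # informative
  s2 <- rnorm(400)                     # random
  ra <- roc_analysis(s1, cond); rb <- roc_analysis(s2, cond)
  expect_equal(compare_auc(ra, ra), 1)
  expect_lt(compare_auc(ra, rb), 1e-4)
  # symmetric in its arguments
  expect_equal(compare_auc(ra, rb), compare_auc(rb, ra))
})

test_that("Hotelling-Williams dependent-correlation test", {
  # equal correlations -> statistic 0, p = 1
  hw0 <- compare_dependent_correlations(0.6, 0.6, 0.5, 100)
  expect_equal(hw0$t, 0)
  expect_equal(hw0$p, 1)
  # symmetry under swapping the two compared correlations
  a <- compare_dependent_correlations(0.77, 0.63, 0.8, 165)
  b <- compare_dependent_correlations(0.63, 0.77, 0.8, 165)
  expect_equal(a$p, b$p)
  expect_equal(a$t, -b$t)
  # UCr~BCM vs UCr~weight comparison scale: r 0.7723 vs sqrt(0.4010),
  # predictors correlated ~0.8, n = 165 -> clearly significant
  hw <- compare_dependent_correlations(0.7723, sqrt(0.4010), 0.8, 165)
  expect_lt(hw$p, 0.005)
  expect_error(compare_dependent_correlations(1, 0.5, 0.5, 50), "\\(-1, 1\\)")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3), "exceed 3")
})

test_that("the aggregated agreement report equals its component statistics", {
  set.seed(38)
  m <- runif(60, 20, 100)
  p <- m + rnorm(60, 0, 6)
  rep_ <- agreement_report(p, m, unit = "mL/min/1.73m2")
  expect_equal(rep_$ccc, lin_ccc(p, m)$ccc)
  ba <- bland_altman(p, m)
  expect_equal(c(rep_$mean_diff, rep_$ba_lower, rep_$ba_upper),
               c(ba$mean_diff, ba$lower, ba$upper))
  expect_equal(rep_$mpe, mean_prediction_error(p, m))
  expect_equal(rep_$pct_within_15, pct_within(p, m, 0.15))
  expect_equal(rep_$pct_within_30, pct_within(p, m, 0.30))
  # identical series give the all-perfect report
  perfect <- agreement_report(m, m + 0, unit = "mg")
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$mean_diff, 0)
  expect_equal(perfect$mpe, 0)
  expect_equal(perfect$pct_within_15, 1)
  # flat serialization round-trips all values
  df <- as.data.frame(rep_)
  expect_equal(df$ccc, rep_$ccc)
  expect_equal(df$mpe, rep_$mpe)
  expect_equal(nrow(df), 1)
})

test_that("agreement statistics are invariant to pair order", {
  set.seed(39)
  m <- runif(40, 10, 90); p <- m + rnorm(40, 1, 5)
  o <- sample(40)
  expect_equal(lin_ccc(p, m)$ccc, lin_ccc(p[o], m[o])$ccc)
  expect_equal(bland_altman(p, m)$upper, bland_altman(p[o], m[o])$upper)
  expect_equal(mean_prediction_error(p, m),
               mean_prediction_error(p[o], m[o]))
  expect_equal(pct_within(p, m, 0.3), pct_within(p[o], m[o], 0.3))
  cond <- m < 50
  expect_equal(roc_analysis(p, cond)$auc,
               roc_analysis(p[o], cond[o])$auc)
})
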