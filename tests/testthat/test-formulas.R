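# Closed-form prediction and normalization formulas.

test_that("body surface area and BMI match direct evaluation and cohort medians", {
  # Du Bois at the cohort's sex-stratified median anthropometrics
  expect_equal(bsa(170, 74.9), 0.007184 * 170^0.725 * 74.9^0.425)
  expect_equal(bsa(170, 74.9), 1.84, tolerance = 0.02)   # male median BSA
  expect_equal(bsa(154, 62.0), 1.59, tolerance = 0.01)   # female median BSA
  expect_equal(bsa(180, 72, formula = "mosteller"), sqrt(180 * 72 / 3600))
  # power-law identity: height scaled by k^(1/0.725) multiplies BSA by k
  k <- 1.37
  expect_equal(bsa(160 * k^(1 / 0.725), 70), k * bsa(160, 70))

  expect_equal(bmi(200, 80), 20)
  expect_equal(bmi(154, 62.0), 26.1, tolerance = 0.005)  # female median BMI
  expect_equal(bmi(160, 2 * 70), 2 * bmi(160, 70))
  expect_error(bsa(-1, 70), "positive")
  expect_error(bmi(160, 0), "positive")
})

test_that("urinary creatinine excretion and measured clearance follow the standard formulas", {
  expect_equal(ucr_24h(100, 1000), 1000)
  expect_equal(ucr_24h(0, 1500), 0)
  expect_equal(ucr_24h(74.6, 1440), 1074.24)
  expect_error(ucr_24h(-1, 100), "non-negative")

  expect_equal(measured_ccr(100, 1440, 1), 100)
  expect_equal(measured_ccr(60, 2000, 2.5), 60 * (2000 / 1440) / 2.5)
  # conc == scr cancels: clearance is exactly the urine flow V/1440
  for (v in c(700, 1440, 2600))
    expect_equal(measured_ccr(3.2, v, 3.2), v / 1440)
  expect_error(measured_ccr(60, 1000, 0), "positive")
})

test_that("the UCr regression equation is the published affine form", {
  # hand evaluation at the cohort medians
  expect_equal(mr_predicted_ucr(24.4, 57, 1.29, 69.8, 1),
               522 + 14.99 * 24.4 - 7.56 * 57 - 31.76 * 1.29 +
                 8.54 * 69.8 + 169.91)
  expect_equal(mr_predicted_ucr(24.4, 57, 1.29, 69.8, 1), 1181.87,
               tolerance = 1e-5)
  # linearity: +10 years lowers UCr by 75.6 mg
  expect_equal(mr_predicted_ucr(20, 60, 2, 70, 0) -
                 mr_predicted_ucr(20, 50, 2, 70, 0), -75.6,
               tolerance = 1e-12)
  # affine identity against the coefficient vector
  cf <- ucr_model_coefficients()
  x1 <- c(30, 44, 1.1, 82, 1); x2 <- c(16, 71, 6.3, 55, 0)
  expect_equal(
    mr_predicted_ucr(x1[1], x1[2], x1[3], x1[4], x1[5]) -
      mr_predicted_ucr(x2[1], x2[2], x2[3], x2[4], x2[5]),
    sum(cf[-1] * (x1 - x2)), tolerance = 1e-12)
  expect_warning(mr_predicted_ucr(12.2, 81, 14.4, 40, 0), "negative")
})

test_that("clearance from predicted UCr uses the mg/dL to mg/mL unit bridge", {
  expect_equal(mr_bcm_ccr(1440, 1), 100)                 # 1440/(0.01*1440)
  expect_equal(mr_bcm_ccr(1074, 2), 1074 / (0.02 * 1440))
  # linear in UCr, inverse in SCr
  expect_equal(mr_bcm_ccr(2 * 900, 1.7), 2 * mr_bcm_ccr(900, 1.7))
  expect_equal(mr_bcm_ccr(900, 2 * 1.7), mr_bcm_ccr(900, 1.7) / 2)
})

test_that("Cockcroft-Gault and MDRD-4 match their published definitions", {
  expect_equal(cockcroft_gault(40, 72, 1, 1), 100)
  expect_equal(cockcroft_gault(40, 72, 1, 0), 85)
  expect_equal(cockcroft_gault(65, 62, 1.19, 0),
               (140 - 65) * 62 / (72 * 1.19) * 0.85)  # = 46.13
  expect_error(cockcroft_gault(150, 70, 1, 1), "140")

  expect_equal(mdrd_gfr(1, 1, 1), 175)
  expect_equal(mdrd_gfr(1.29, 57, 1), 175 * 1.29^-1.154 * 57^-0.203)
  # female factor is exactly 0.742 at any scr/age
  expect_equal(mdrd_gfr(2.3, 44, 0), 0.742 * mdrd_gfr(2.3, 44, 1))
  expect_equal(mdrd_gfr(1, 1, 1, constant = 186), 186)
  expect_error(mdrd_gfr(0, 50, 1), "positive")
})

test_that("BCM GFR follows the -5.1 + 3.3 BCM/SCr line with zero clamping", {
  expect_equal(as.numeric(bcm_gfr(24.4, 1.29)), -5.1 + 3.3 * 24.4 / 1.29)
  # root of the line
  expect_equal(as.numeric(bcm_gfr(5.1 / 3.3, 1)), 0)
  # cohort extreme: negative raw value clamps to 0 and is flagged
  g <- bcm_gfr(12.2, 14.4)
  expect_equal(as.numeric(g), 0)
  expect_true(attr(g, "clamped"))
  expect_lt(as.numeric(bcm_gfr(12.2, 14.4, clamp = FALSE)), 0)
  # strict monotonicity pre-clamp: increasing in BCM, decreasing in SCr
  bcmv <- seq(13, 45, by = 0.5)
  expect_true(all(diff(bcm_gfr(bcmv, 2, clamp = FALSE)) > 0))
  scrv <- seq(0.6, 14, by = 0.2)
  expect_true(all(diff(bcm_gfr(20, scrv, clamp = FALSE)) < 0))
})

test_that("BSA normalization is the 1.73/BSA scaling and invertible", {
  expect_equal(normalize_bsa(100, 1.73), 100)
  expect_equal(normalize_bsa(100, 2.0), 86.5)
  set.seed(4)
  v <- runif(50, 5, 120); b <- runif(50, 1.3, 2.4)
  expect_equal(denormalize_bsa(normalize_bsa(v, b), b), v,
               tolerance = 1e-12)
  expect_error(normalize_bsa(50, 0), "positive")
})

test_that("KDOQI staging partitions the non-negative axis with lower-closed bounds", {
  expect_equal(as.character(ckd_stage(c(95, 60, 59.999, 45, 44.9, 30, 15, 14.9, 0))),
               c("1", "2", "3a", "3a", "3b", "3b", "4", "5", "5"))
  # every non-negative value maps to exactly one stage
  set.seed(5)
  g <- c(runif(500, 0, 150), c(15, 30, 45, 60, 90))
  st <- ckd_stage(g)
  expect_false(any(is.na(st)))
  expect_equal(levels(st), c("1", "2", "3a", "3b", "4", "5"))
  expect_error(ckd_stage(-1), "non-negative")
})

test_that("the impedance surrogate is monotone in height and plausible at cohort inputs", {
  # typical male / female BIA readings give BCM inside the cohort range
  m <- bcm_from_impedance(430, 45, 170, 74.9, 1)
  f <- bcm_from_impedance(480, 45, 154, 62.0, 0)
  expect_true(m > 12.2 && m < 45.2)
  expect_true(f > 12.2 && f < 45.2)
  expect_gt(m, f)
  # fixed electrical values, increasing height -> non-decreasing BCM
  h <- seq(145, 190, by = 5)
  expect_true(all(diff(bcm_from_impedance(450, 40, h, 70, 1)) >= 0))
  # hand evaluation of the documented surrogate (Kyle FFM x fraction)
  ffm <- -4.104 + 0.518 * 170^2 / 430 + 0.231 * 74.9 + 0.130 * 45 + 4.229
  expect_equal(m, 0.47 * ffm)
  expect_error(bcm_from_impedance(0, 45, 170, 70, 1), "positive")
})
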