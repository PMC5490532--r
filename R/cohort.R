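# Synthetic CKD cohort generator. Emulates the joint structure of an adult
# CKD population spanning stages 1-5: sex-stratified anthropometrics and body
# composition, log-normal serum creatinine, 24-h urinary creatinine generated
# from the published linear model, and measured GFR generated from the
# published GFR ~ BCM/SCr line with noise calibrated to the published
# correlation.

#' Cohort generation specification
#'
#' All location/scale parameters default to the sex-stratified medians and
#' IQR-derived SDs of the 165-patient derivation cohort (72 women, 93 men).
#' Gaussian covariates are truncated to the observed cohort ranges by
#' rejection sampling (redraw, so no boundary atoms); serum creatinine is
#' log-normal with a truncation-aware median calibration. Body cell mass is
#' built from a documented correlation scaffold (sex intercept + weight +
#' height + age decline with Gaussian residual); serum creatinine is drawn
#' independently of anthropometrics (disease-driven).
#'
#' @param n cohort size (default 165, the derivation cohort).
#' @param seed optional default seed used by [generate_cohort()] when none is
#'   given there.
#' @param sex_fraction_female probability a patient is female (default 72/165).
#' @param age,height,weight lists with `female`/`male` = c(mean, sd) and a
#'   `bounds` range; defaults from the cohort table.
#' @param bcm list with `intercept` (female, male), `weight_slope`,
#'   `height_slope`, `age_slope`, `sd` (female, male) and `bounds`.
#' @param fat,ecw lists with `intercept` (female, male), `weight_slope`,
#'   `sd`, `bounds`.
#' @param scr list with `median` (female, male), `sdlog`, `bounds` (mg/dL).
#' @param ucr_residual_sd Gaussian SD (mg) added to the linear-model UCr;
#'   default 175, the published prediction error.
#' @param gfr_target_r target Pearson correlation between measured GFR and
#'   BCM/SCr; the GFR residual SD is calibrated from the drawn ratios to hit
#'   it (default 0.9102). Ignored when `gfr_residual_sd` is given.
#' @param gfr_residual_sd fixed Gaussian SD (mL/min) for the GFR noise;
#'   `NULL` (default) means calibrate from `gfr_target_r`.
#' @param uvol list with `meanlog`, `sdlog`, `bounds` for the 24-h urine
#'   volume (mL); default log-normal around 1500 mL.
#' @param reactance c(mean, sd) of the simulated 50 kHz reactance (ohm).
#' @param height_weight_corr correlation between height and weight (0.5).
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n = 165,
                        seed = NULL,
                        sex_fraction_female = 72 / 165,
                        age = list(female = c(58.5, 8.9),
                                   male = c(53, 18.2),
                                   bounds = c(17, 81)),
                        height = list(female = c(154, 5.9),
                                      male = c(170, 8.2),
                                      bounds = c(143, 188)),
                        weight = list(female = c(62, 10.5),
                                      male = c(74.9, 11.2),
                                      bounds = c(44.4, 120.3)),
                        bcm = list(intercept = c(female = 18.7, male = 28.4),
                                   weight_slope = 0.25,
                                   height_slope = 0.15,
                                   age_slope = -0.10,
                                   sd = c(female = 2.5, male = 3.4),
                                   bounds = c(12.2, 45.2)),
                        fat = list(intercept = c(female = 21.4, male = 17.8),
                                   weight_slope = 0.5,
                                   sd = 3,
                                   bounds = c(3.2, 61.2)),
                        ecw = list(intercept = c(female = 12.9, male = 16.6),
                                   weight_slope = 0.1,
                                   sd = 1.5,
                                   bounds = c(8.7, 46.3)),
                        scr = list(median = c(female = 1.19, male = 1.48),
                                   sdlog = 0.85,
                                   bounds = c(0.57, 14.4)),
                        ucr_residual_sd = 175,
                        gfr_target_r = 0.9102,
                        gfr_residual_sd = NULL,
                        uvol = list(meanlog = log(1500), sdlog = 0.25,
                                    bounds = c(400, 4000)),
                        reactance = c(45, 8),
                        height_weight_corr = 0.5) {
  spec <- list(n = n, seed = seed,
               sex_fraction_female = sex_fraction_female,
               age = age, height = height, weight = weight, bcm = bcm,
               fat = fat, ecw = ecw, scr = scr,
               ucr_residual_sd = ucr_residual_sd,
               gfr_target_r = gfr_target_r,
               gfr_residual_sd = gfr_residual_sd,
               uvol = uvol, reactance = reactance,
               height_weight_corr = height_weight_corr)
  .validate_spec(spec)
  structure(spec, class = "cohort_spec")
}

.validate_spec <- function(spec) {
  if (spec$n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (spec$sex_fraction_female < 0 || spec$sex_fraction_female > 1)
    stop("`sex_fraction_female` must be a proportion", call. = FALSE)
  for (nm in c("age", "height", "weight")) {
    p <- spec[[nm]]
    if (p$female[2] <= 0 || p$male[2] <= 0)
      stop("`", nm, "` scale must be positive", call. = FALSE)
    if (diff(p$bounds) <= 0)
      stop("`", nm, "` bounds must be ordered", call. = FALSE)
    # both sex means must be reachable inside the bounds
    if (any(c(p$female[1], p$male[1]) < p$bounds[1]) ||
        any(c(p$female[1], p$male[1]) > p$bounds[2]))
      stop("`", nm, "` means fall outside the clamp bounds", call. = FALSE)
  }
  if (any(spec$bcm$sd <= 0) || diff(spec$bcm$bounds) <= 0)
    stop("invalid `bcm` parameters", call. = FALSE)
  if (spec$scr$sdlog <= 0 || diff(spec$scr$bounds) <= 0)
    stop("invalid `scr` parameters", call. = FALSE)
  if (spec$ucr_residual_sd < 0) stop("`ucr_residual_sd` must be >= 0",
                                     call. = FALSE)
  if (!is.null(spec$gfr_residual_sd) && spec$gfr_residual_sd < 0)
    stop("`gfr_residual_sd` must be >= 0", call. = FALSE)
  if (is.null(spec$gfr_residual_sd) &&
      (spec$gfr_target_r <= 0 || spec$gfr_target_r >= 1))
    stop("`gfr_target_r` must lie in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

#' Default cohort specification
#'
#' [cohort_spec()] with all defaults: the calibrated emulation of the
#' 165-patient derivation cohort. Large cohorts generated from it reproduce
#' the sex-stratified anthropometric medians, corr(UCr, BCM) ~ 0.77 and
#' corr(GFR, BCM/SCr) ~ 0.91.
#'
#' @param n cohort size (default 165).
#' @param ... overrides passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
default_spec <- function(n = 165, ...) cohort_spec(n = n, ...)

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic CKD cohort spec: n =", x$n,
      sprintf("(%.0f%% female)", 100 * x$sex_fraction_female), "\n")
  cat("  UCr residual SD:", x$ucr_residual_sd, "mg;",
      if (is.null(x$gfr_residual_sd))
        sprintf("GFR noise calibrated to r = %.4f", x$gfr_target_r)
      else sprintf("GFR residual SD = %g mL/min", x$gfr_residual_sd), "\n")
  invisible(x)
}

# truncated-normal draw by rejection (no boundary atoms)
.rtnorm <- function(mu, sd, lo, hi) {
  n <- length(mu)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mu, sd)
  bad <- x < lo | x > hi
  guard <- 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mu[bad], sd[bad])
    bad <- x < lo | x > hi
    guard <- guard + 1
    if (guard > 10000) stop("clamp bounds infeasible for the given mean/sd",
                            call. = FALSE)
  }
  x
}

.rtlnorm <- function(meanlog, sdlog, lo, hi) {
  n <- length(meanlog)
  x <- rlnorm(n, meanlog, sdlog)
  bad <- x < lo | x > hi
  guard <- 0
  while (any(bad)) {
    x[bad] <- rlnorm(sum(bad), meanlog[bad], sdlog)
    bad <- x < lo | x > hi
    guard <- guard + 1
    if (guard > 10000) stop("clamp bounds infeasible", call. = FALSE)
  }
  x
}

# meanlog such that the truncated log-normal median equals `target`
.cal_meanlog <- function(target, sdlog, lo, hi) {
  f <- function(m) {
    qlo <- pnorm((log(lo) - m) / sdlog)
    qhi <- pnorm((log(hi) - m) / sdlog)
    exp(m + sdlog * qnorm((qlo + qhi) / 2)) - target
  }
  uniroot(f, c(log(target) - 3, log(target) + 2))$root
}

#' Generate a synthetic CKD cohort
#'
#' Draws a cohort per the spec and returns it in the standard cohort schema
#' (see [read_cohort()]), with the latent noise-free values attached as the
#' `"truth"` attribute (excluded from the standard CSV export; see
#' [write_cohort()]). Raw BIA resistance values are back-computed from the
#' generated BCM through the published surrogate chain so the electrical and
#' body-composition columns are mutually consistent.
#'
#' Generative structure: covariates sex-stratified as documented in
#' [cohort_spec()]; 24-h UCr = published linear model + N(0, ucr_residual_sd);
#' measured GFR = -5.1 + 3.3 x BCM/SCr + Gaussian noise (SD calibrated to the
#' target correlation), clamped below at 0.2 mL/min; urine volume log-normal;
#' urinary creatinine concentration back-computed as UCr / volume x 100.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; required here or in the spec. Identical
#'   spec + seed give identical cohorts.
#' @return data frame in the cohort schema with attributes `truth`
#'   (data frame of latent values) and `spec`.
#' @export
generate_cohort <- function(spec = default_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  .validate_spec(spec)
  if (is.null(seed)) stop("a seed is required for reproducible generation",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n <- spec$n

  female <- runif(n) < spec$sex_fraction_female
  male <- as.integer(!female)
  pick <- function(p) list(mu = ifelse(female, p$female[1], p$male[1]),
                           sd = ifelse(female, p$female[2], p$male[2]))

  a <- pick(spec$age)
  age <- .rtnorm(a$mu, a$sd, spec$age$bounds[1], spec$age$bounds[2])
  h <- pick(spec$height)
  height <- .rtnorm(h$mu, h$sd, spec$height$bounds[1], spec$height$bounds[2])
  w <- pick(spec$weight)
  rho <- spec$height_weight_corr
  w_mu <- w$mu + rho * w$sd * (height - h$mu) / h$sd
  weight <- .rtnorm(w_mu, w$sd * sqrt(1 - rho^2),
                    spec$weight$bounds[1], spec$weight$bounds[2])

  b <- spec$bcm
  bcm_mu <- ifelse(female, b$intercept["female"], b$intercept["male"]) +
    b$weight_slope * (weight - w$mu) +
    b$height_slope * (height - h$mu) +
    b$age_slope * (age - a$mu)
  bcm <- .rtnorm(bcm_mu, ifelse(female, b$sd["female"], b$sd["male"]),
                 b$bounds[1], b$bounds[2])

  f <- spec$fat
  fat <- .rtnorm(ifelse(female, f$intercept["female"], f$intercept["male"]) +
                   f$weight_slope * (weight - w$mu),
                 f$sd, f$bounds[1], f$bounds[2])
  e <- spec$ecw
  ecw <- .rtnorm(ifelse(female, e$intercept["female"], e$intercept["male"]) +
                   e$weight_slope * (weight - w$mu),
                 e$sd, e$bounds[1], e$bounds[2])

  s <- spec$scr
  mF <- .cal_meanlog(s$median["female"], s$sdlog, s$bounds[1], s$bounds[2])
  mM <- .cal_meanlog(s$median["male"], s$sdlog, s$bounds[1], s$bounds[2])
  scr <- .rtlnorm(ifelse(female, mF, mM), s$sdlog, s$bounds[1], s$bounds[2])

  ucr_true <- mr_predicted_ucr(bcm, age, scr, weight, male)
  ucr <- ucr_true + rnorm(n, 0, spec$ucr_residual_sd)
  if (any(ucr <= 0)) { # astronomically rare at the default scales
    bad <- ucr <= 0
    ucr[bad] <- abs(ucr_true[bad])
  }

  uvol <- .rtlnorm(rep(spec$uvol$meanlog, n), spec$uvol$sdlog,
                   spec$uvol$bounds[1], spec$uvol$bounds[2])
  ucr_conc <- ucr / uvol * 100

  ratio <- bcm / scr
  gfr_true <- -5.1 + 3.3 * ratio
  gfr_sd <- spec$gfr_residual_sd
  if (is.null(gfr_sd)) {
    r <- spec$gfr_target_r
    gfr_sd <- sd(3.3 * ratio) * sqrt(1 / r^2 - 1)
  }
  gfr_raw <- pmax(gfr_true + rnorm(n, 0, gfr_sd), 0.2)

  xc <- .rtnorm(rep(spec$reactance[1], n), spec$reactance[2], 10, 110)
  res <- .resistance_from_bcm(bcm, xc, height, weight, male)

  bsa_m2 <- bsa(height, weight)
  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(female, "F", "M"),
    age_y = age, height_cm = height, weight_kg = weight,
    bcm_kg = bcm, fat_kg = fat, ecw_kg = ecw,
    resistance_ohm = res, reactance_ohm = xc,
    scr_mg_dl = scr, ucr_conc_mg_dl = ucr_conc, uvol_24h_ml = uvol,
    gfr_ml_min_173 = normalize_bsa(gfr_raw, bsa_m2),
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- data.frame(
    patient_id = cohort$patient_id,
    ucr_true_mg = ucr_true, ucr_mg = ucr,
    gfr_true_ml_min = gfr_true, gfr_raw_ml_min = gfr_raw,
    bsa_m2 = bsa_m2, gfr_residual_sd = gfr_sd,
    stringsAsFactors = FALSE
  )
  attr(cohort, "spec") <- spec
  cohort
}
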