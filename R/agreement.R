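# Method-agreement battery for predicted vs measured renal function:
# Lin's concordance correlation, Bland-Altman limits, RMSE prediction error,
# percent-within accuracy, ROC analysis and correlated-correlation testing.

.check_pairs <- function(predicted, measured, min_n = 3) {
  if (length(predicted) != length(measured))
    stop("predicted/measured length mismatch", call. = FALSE)
  ok <- is.finite(predicted) & is.finite(measured)
  if (!all(ok)) stop("pairs contain missing or non-finite values",
                     call. = FALSE)
  if (length(predicted) < min_n)
    stop("need at least ", min_n, " pairs", call. = FALSE)
  invisible(TRUE)
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with moment (1/n)
#' variances, penalizing both dispersion and location shift; `rho_c = 1` only
#' for perfect agreement on the identity line. The confidence interval uses
#' Lin's (1989) Fisher-z transform with its asymptotic variance.
#'
#' @param predicted,measured paired numeric vectors (same units).
#' @param conf_level confidence level for the CI (default 0.95).
#' @return list with `ccc`, `lower`, `upper`, `pearson_r`, `n`.
#' @references Lin LI (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45:255-268.
#' @export
lin_ccc <- function(predicted, measured, conf_level = 0.95) {
  .check_pairs(predicted, measured)
  n <- length(predicted)
  if (var(predicted) == 0 || var(measured) == 0)
    stop("zero variance in one series: concordance undefined", call. = FALSE)
  mx <- mean(predicted); my <- mean(measured)
  sx2 <- mean((predicted - mx)^2); sy2 <- mean((measured - my)^2)
  sxy <- mean((predicted - mx) * (measured - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  # Lin 1989 variance of z = atanh(ccc)
  vz <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
           2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
           ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (1 - ccc^2 < 1e-15) {           # perfect (anti-)agreement: degenerate CI
    ci <- c(ccc, ccc)
  } else {
    ci <- tanh(atanh(ccc) + c(-1, 1) * zq * sqrt(max(vz, 0)))
  }
  list(ccc = ccc, lower = ci[1], upper = ci[2], pearson_r = r, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Mean of the paired differences (predicted - measured) and limits of
#' agreement `mean +/- multiplier x SD(differences)`; 1.96 gives the usual
#' 95% range of agreement for Gaussian differences.
#'
#' @inheritParams lin_ccc
#' @param multiplier half-width of the limits in SD units (default 1.96).
#' @return list with `mean_diff`, `sd_diff`, `lower`, `upper`, `multiplier`,
#'   `n`.
#' @export
bland_altman <- function(predicted, measured, multiplier = 1.96) {
  .check_pairs(predicted, measured)
  d <- predicted - measured
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       lower = m - multiplier * s, upper = m + multiplier * s,
       multiplier = multiplier, n = length(d))
}

#' Mean prediction error
#'
#' Root-mean-square of the paired differences (default), in the units of the
#' inputs; `type = "mae"` gives the mean absolute difference instead. RMSE is
#' consistent with Bland-Altman limits of ~1.96 x MPE for unbiased Gaussian
#' errors.
#'
#' @inheritParams lin_ccc
#' @param type `"rmse"` (default) or `"mae"`.
#' @return scalar error in input units.
#' @export
mean_prediction_error <- function(predicted, measured,
                                  type = c("rmse", "mae")) {
  type <- match.arg(type)
  .check_pairs(predicted, measured, min_n = 1)
  d <- predicted - measured
  switch(type, rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Fraction of predictions within a relative error threshold
#'
#' Fraction of pairs with `|predicted - measured| / measured <= threshold`
#' (P30 for threshold 0.30, P15 for 0.15).
#'
#' @inheritParams lin_ccc
#' @param threshold relative error as a proportion (0.30 = 30%).
#' @return proportion in \[0, 1\].
#' @export
pct_within <- function(predicted, measured, threshold) {
  .check_pairs(predicted, measured, min_n = 1)
  if (any(measured <= 0))
    stop("measured values must be positive for relative error", call. = FALSE)
  mean(abs(predicted - measured) / measured <= threshold)
}

#' ROC analysis of a renal-function estimate against a GFR-defined condition
#'
#' The condition is renal impairment (measured GFR below a threshold), so the
#' classifier calls a patient positive when the estimate is LOW; scores are
#' oriented accordingly (`direction = ">"`, controls above cases). The AUC is
#' the empirical (trapezoidal / Mann-Whitney) area with DeLong standard error;
#' the reported cutoff maximizes Youden's J, with sensitivity/specificity
#' given in percent.
#'
#' @param scores renal-function estimates (higher = healthier).
#' @param condition logical (or 0/1) vector, TRUE when the patient has the
#'   condition (e.g. measured GFR below the stage threshold).
#' @return object of class `renal_roc`: `auc`, `auc_se`, `cutoff`,
#'   `sensitivity`, `specificity` (percent), `n_pos`, `n_neg`, plus the
#'   underlying `pROC::roc` object in `$roc`.
#' @export
roc_analysis <- function(scores, condition) {
  condition <- as.logical(condition)
  if (length(scores) != length(condition))
    stop("scores/condition length mismatch", call. = FALSE)
  if (length(unique(condition)) < 2)
    stop("both condition classes must be present", call. = FALSE)
  r <- pROC::roc(response = condition, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)
  co <- pROC::coords(r, "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[1, , drop = FALSE]                 # first optimum on ties
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    auc_se = sqrt(pROC::var(r)),
    cutoff = co$threshold,
    sensitivity = 100 * co$sensitivity,
    specificity = 100 * co$specificity,
    n_pos = sum(condition), n_neg = sum(!condition),
    roc = r
  ), class = "renal_roc")
}

#' @export
print.renal_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (SE %.3f), cutoff %.4g, sens %.1f%%, spec %.1f%% (%d+/%d-)\n",
    x$auc, x$auc_se, x$cutoff, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Paired DeLong test for two ROC curves built on the same patients (the
#' standard comparison for two estimates of the same condition). Identical
#' score vectors return p = 1.
#'
#' @param roc_a,roc_b `renal_roc` objects from [roc_analysis()] on the same
#'   condition labels.
#' @param paired treat the curves as paired (default TRUE).
#' @return two-sided p-value.
#' @export
compare_auc <- function(roc_a, roc_b, paired = TRUE) {
  if (!inherits(roc_a, "renal_roc") || !inherits(roc_b, "renal_roc"))
    stop("inputs must come from roc_analysis()", call. = FALSE)
  pa <- roc_a$roc$predictor; pb <- roc_b$roc$predictor
  if (paired && length(pa) != length(pb))
    stop("paired comparison needs equal-length score vectors", call. = FALSE)
  if (paired && isTRUE(all.equal(pa, pb))) return(1)
  p <- tryCatch(
    as.numeric(pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong",
                              paired = paired)$p.value),
    error = function(e) NA_real_)
  if (is.na(p))
    warning("DeLong statistic undefined (degenerate separation); p is NA",
            call. = FALSE)
  p
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests `r_xy = r_xz` when both correlations share the variable x and are
#' computed on the same n subjects (e.g. UCr~BCM vs UCr~weight), accounting
#' for the correlation `r_yz` between the two competing predictors.
#'
#' @param r_xy,r_xz the two correlations being compared.
#' @param r_yz correlation between y and z.
#' @param n number of subjects (> 3).
#' @return list with `t` (statistic, df = n - 3) and `p` (two-sided).
#' @export
compare_dependent_correlations <- function(r_xy, r_xz, r_yz, n) {
  rs <- c(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz)
  if (any(abs(rs) >= 1)) stop("correlations must lie in (-1, 1)",
                              call. = FALSE)
  if (n <= 3) stop("`n` must exceed 3", call. = FALSE)
  detR <- 1 - r_xy^2 - r_xz^2 - r_yz^2 + 2 * r_xy * r_xz * r_yz
  rbar <- (r_xy + r_xz) / 2
  tstat <- (r_xy - r_xz) * sqrt(
    (n - 1) * (1 + r_yz) /
      (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_yz)^3))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 3))
}

#' Full agreement report for one predicted-vs-measured comparison
#'
#' Bundles the whole battery: Lin's CCC with CI, Bland-Altman mean difference
#' and limits, RMSE mean prediction error, P15/P30 accuracy and Pearson r.
#'
#' @inheritParams lin_ccc
#' @param unit unit label carried into printing (e.g. `"mL/min/1.73m2"`).
#' @param multiplier Bland-Altman limit multiplier.
#' @return object of class `agreement_report`; see [as.data.frame.agreement_report()]
#'   for the flat serializable form.
#' @export
agreement_report <- function(predicted, measured, unit = "",
                             multiplier = 1.96) {
  .check_pairs(predicted, measured)
  ccc <- lin_ccc(predicted, measured)
  ba <- bland_altman(predicted, measured, multiplier = multiplier)
  structure(list(
    unit = unit, n = length(predicted),
    ccc = ccc$ccc, ccc_lower = ccc$lower, ccc_upper = ccc$upper,
    pearson_r = ccc$pearson_r,
    mean_diff = ba$mean_diff, ba_lower = ba$lower, ba_upper = ba$upper,
    mpe = mean_prediction_error(predicted, measured),
    pct_within_15 = pct_within(predicted, measured, 0.15),
    pct_within_30 = pct_within(predicted, measured, 0.30)
  ), class = "agreement_report")
}

#' Flatten an agreement report to a one-row data frame
#' @param x an `agreement_report`.
#' @param ... ignored.
#' @return one-row data frame with all report fields.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.agreement_report <- function(x, ...) {
  u <- if (nzchar(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("Agreement over %d pairs%s\n", x$n, u))
  cat(sprintf("  CCC %.4f (95%% CI %.4f to %.4f), Pearson r %.4f\n",
              x$ccc, x$ccc_lower, x$ccc_upper, x$pearson_r))
  cat(sprintf("  Bland-Altman: mean diff %.2f, limits %.2f to %.2f%s\n",
              x$mean_diff, x$ba_lower, x$ba_upper, u))
  cat(sprintf("  MPE %.2f%s; within 15%%: %.0f%%; within 30%%: %.0f%%\n",
              x$mpe, u, 100 * x$pct_within_15, 100 * x$pct_within_30))
  invisible(x)
}
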