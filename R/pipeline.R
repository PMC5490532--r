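# End-to-end pipelines chaining the formulas, the derivation machinery and
# the agreement battery over a cohort table.

#' Formula configuration
#'
#' Bundles the configurable formula choices used by [run_predict()].
#'
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @param mdrd_constant MDRD leading constant (175 = IDMS-traceable).
#' @param ethnicity_factor MDRD ethnicity multiplier.
#' @param bcm_fraction BCM/FFM ratio of the impedance surrogate.
#' @param clamp_negative clamp negative predicted GFR to 0.
#' @return named list of options.
#' @export
renal_config <- function(bsa_formula = "dubois", mdrd_constant = 175,
                         ethnicity_factor = 1, bcm_fraction = 0.47,
                         clamp_negative = TRUE) {
  list(bsa_formula = match.arg(bsa_formula, c("dubois", "mosteller")),
       mdrd_constant = mdrd_constant, ethnicity_factor = ethnicity_factor,
       bcm_fraction = bcm_fraction, clamp_negative = clamp_negative)
}

.male01 <- function(sex) as.integer(sex == "M")

#' Per-patient renal function predictions
#'
#' Chains the closed-form formulas over a cohort table: multiple-regression
#' predicted UCr, the BCM-based creatinine clearance, Cockcroft-Gault,
#' BCM GFR and MDRD GFR, each raw (mL/min) and BSA-normalized
#' (mL/min/1.73 m^2), the measured 24-h clearance when urine data are
#' present, and the KDOQI CKD stage from the BCM GFR. If `bcm_kg` is missing
#' for a patient but raw resistance/reactance are present, BCM is filled via
#' the impedance surrogate; patients with neither get NA for all BCM-based
#' outputs while Cockcroft-Gault and MDRD are still produced.
#'
#' @param cohort cohort data frame (see [read_cohort()]).
#' @param config options from [renal_config()].
#' @return data frame of per-patient estimates; deterministic.
#' @export
run_predict <- function(cohort, config = renal_config()) {
  male <- .male01(cohort$sex)
  bsa_m2 <- bsa(cohort$height_cm, cohort$weight_kg,
                formula = config$bsa_formula)
  bcm <- cohort$bcm_kg
  fill <- is.na(bcm) & !is.na(cohort$resistance_ohm) &
    !is.na(cohort$reactance_ohm)
  if (any(fill))
    bcm[fill] <- bcm_from_impedance(
      cohort$resistance_ohm[fill], cohort$reactance_ohm[fill],
      cohort$height_cm[fill], cohort$weight_kg[fill], male[fill],
      bcm_fraction = config$bcm_fraction)

  out <- data.frame(patient_id = cohort$patient_id, sex = cohort$sex,
                    bsa_m2 = bsa_m2, stringsAsFactors = FALSE)

  has_bcm <- !is.na(bcm)
  nacol <- rep(NA_real_, nrow(cohort))
  out$mr_ucr_mg <- out$mr_bcm_ccr_ml_min <- out$bcm_gfr_ml_min <- nacol
  clamped <- rep(NA, nrow(cohort))
  if (any(has_bcm)) {
    out$mr_ucr_mg[has_bcm] <- suppressWarnings(mr_predicted_ucr(
      bcm[has_bcm], cohort$age_y[has_bcm], cohort$scr_mg_dl[has_bcm],
      cohort$weight_kg[has_bcm], male[has_bcm]))
    out$mr_bcm_ccr_ml_min[has_bcm] <- mr_bcm_ccr(
      pmax(out$mr_ucr_mg[has_bcm], 0), cohort$scr_mg_dl[has_bcm])
    g <- bcm_gfr(bcm[has_bcm], cohort$scr_mg_dl[has_bcm],
                 clamp = config$clamp_negative)
    out$bcm_gfr_ml_min[has_bcm] <- as.numeric(g)
    clamped[has_bcm] <- attr(g, "clamped")
  }
  out$bcm_gfr_clamped <- clamped
  out$cg_ccr_ml_min <- cockcroft_gault(cohort$age_y, cohort$weight_kg,
                                       cohort$scr_mg_dl, male)
  out$mdrd_gfr_norm <- mdrd_gfr(cohort$scr_mg_dl, cohort$age_y, male,
                                constant = config$mdrd_constant,
                                ethnicity_factor = config$ethnicity_factor)

  out$mr_bcm_ccr_norm <- normalize_bsa(out$mr_bcm_ccr_ml_min, bsa_m2)
  out$bcm_gfr_norm <- normalize_bsa(out$bcm_gfr_ml_min, bsa_m2)
  out$cg_ccr_norm <- normalize_bsa(out$cg_ccr_ml_min, bsa_m2)
  out$mdrd_gfr_ml_min <- denormalize_bsa(out$mdrd_gfr_norm, bsa_m2)

  has_urine <- !is.na(cohort$ucr_conc_mg_dl) & !is.na(cohort$uvol_24h_ml)
  out$measured_ucr_mg <- out$mccr_ml_min <- out$mccr_norm <- nacol
  if (any(has_urine)) {
    out$measured_ucr_mg[has_urine] <- ucr_24h(
      cohort$ucr_conc_mg_dl[has_urine], cohort$uvol_24h_ml[has_urine])
    out$mccr_ml_min[has_urine] <- measured_ccr(
      cohort$ucr_conc_mg_dl[has_urine], cohort$uvol_24h_ml[has_urine],
      cohort$scr_mg_dl[has_urine])
    out$mccr_norm[has_urine] <- normalize_bsa(out$mccr_ml_min[has_urine],
                                              bsa_m2[has_urine])
  }
  out$ckd_stage_bcm <- rep(NA_character_, nrow(out))
  ok <- !is.na(out$bcm_gfr_norm)
  out$ckd_stage_bcm[ok] <- as.character(ckd_stage(out$bcm_gfr_norm[ok]))
  out$ckd_stage_mdrd <- as.character(ckd_stage(out$mdrd_gfr_norm))
  out
}

.report_if_enough <- function(predicted, measured, unit) {
  ok <- is.finite(predicted) & is.finite(measured)
  if (sum(ok) < 3) {
    warning("fewer than 3 valid pairs; agreement section skipped",
            call. = FALSE)
    return(NULL)
  }
  tryCatch(agreement_report(predicted[ok], measured[ok], unit = unit),
           error = function(e) {
             warning("agreement section skipped: ", conditionMessage(e),
                     call. = FALSE)
             NULL
           })
}

.by_sex <- function(predicted, measured, sex, unit) {
  lapply(list(all = c("F", "M"), female = "F", male = "M"), function(sx) {
    sel <- sex %in% sx
    .report_if_enough(predicted[sel], measured[sel], unit)
  })
}

#' Validate predictions against the cohort's measured values
#'
#' Assembles the full method-agreement analysis of a cohort: per-method
#' agreement reports (overall and by sex) of predicted UCr vs measured UCr,
#' the BCM-based and Cockcroft-Gault clearances vs the measured 24-h
#' clearance, and the BCM and MDRD GFR estimates vs the measured GFR (all
#' clearances BSA-normalized) plus a ROC table of both GFR estimates at the
#' impairment thresholds 90/60/45/30/15 mL/min/1.73 m^2 with paired DeLong
#' AUC comparison. Sections whose measured counterpart is absent (or has
#' fewer than 3 valid pairs) are skipped with a warning.
#'
#' @param cohort cohort data frame.
#' @param predictions optional precomputed [run_predict()] output.
#' @param config options from [renal_config()].
#' @param roc_thresholds GFR thresholds (mL/min/1.73 m^2) for the ROC table.
#' @return object of class `renal_validation`: list with `agreement` (nested
#'   per method / per sex), `roc` (data frame), `n`.
#' @export
run_validate <- function(cohort, predictions = NULL,
                         config = renal_config(),
                         roc_thresholds = c(90, 60, 45, 30, 15)) {
  pred <- if (is.null(predictions)) run_predict(cohort, config) else predictions
  sex <- cohort$sex
  agreement <- list()
  agreement$ucr <- .by_sex(pred$mr_ucr_mg, pred$measured_ucr_mg, sex, "mg")
  agreement$mr_bcm_ccr <- .by_sex(pred$mr_bcm_ccr_norm, pred$mccr_norm, sex,
                                  "mL/min/1.73m2")
  agreement$cg_ccr <- .by_sex(pred$cg_ccr_norm, pred$mccr_norm, sex,
                              "mL/min/1.73m2")
  gfr <- cohort$gfr_ml_min_173
  roc_tab <- NULL
  if (!is.null(gfr) && sum(is.finite(gfr)) >= 3) {
    agreement$bcm_gfr <- .by_sex(pred$bcm_gfr_norm, gfr, sex, "mL/min/1.73m2")
    agreement$mdrd_gfr <- .by_sex(pred$mdrd_gfr_norm, gfr, sex,
                                  "mL/min/1.73m2")
    rows <- list()
    for (thr in roc_thresholds) {
      cond <- gfr < thr
      ok <- is.finite(gfr) & is.finite(pred$bcm_gfr_norm) &
        is.finite(pred$mdrd_gfr_norm)
      if (length(unique(cond[ok])) < 2) next
      ra <- roc_analysis(pred$bcm_gfr_norm[ok], cond[ok])
      rb <- roc_analysis(pred$mdrd_gfr_norm[ok], cond[ok])
      rows[[length(rows) + 1]] <- data.frame(
        threshold = thr,
        bcm_auc = ra$auc, bcm_cutoff = ra$cutoff,
        bcm_sens = ra$sensitivity, bcm_spec = ra$specificity,
        mdrd_auc = rb$auc, mdrd_cutoff = rb$cutoff,
        mdrd_sens = rb$sensitivity, mdrd_spec = rb$specificity,
        p_delong = compare_auc(ra, rb))
    }
    if (length(rows)) roc_tab <- do.call(rbind, rows)
  } else {
    warning("no measured GFR: GFR agreement and ROC sections skipped",
            call. = FALSE)
  }
  structure(list(agreement = agreement, roc = roc_tab, n = nrow(cohort)),
            class = "renal_validation")
}

#' @export
print.renal_validation <- function(x, ...) {
  cat("Renal function validation over", x$n, "patients\n")
  for (method in names(x$agreement)) {
    rep_all <- x$agreement[[method]]$all
    if (is.null(rep_all)) next
    cat("\n==", method, "==\n")
    print(rep_all)
  }
  if (!is.null(x$roc)) {
    cat("\n== ROC: GFR impairment thresholds ==\n")
    print(transform(x$roc,
                    bcm_auc = round(bcm_auc, 3),
                    mdrd_auc = round(mdrd_auc, 3),
                    p_delong = signif(p_delong, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a validation object to machine-readable tables
#' @param v a `renal_validation` object.
#' @return list with `agreement` (one row per method x subgroup) and `roc`
#'   data frames.
#' @export
validation_tables <- function(v) {
  stopifnot(inherits(v, "renal_validation"))
  rows <- list()
  for (method in names(v$agreement))
    for (grp in names(v$agreement[[method]])) {
      r <- v$agreement[[method]][[grp]]
      if (is.null(r)) next
      rows[[length(rows) + 1]] <-
        cbind(data.frame(method = method, group = grp), as.data.frame(r))
    }
  list(agreement = if (length(rows)) do.call(rbind, rows) else NULL,
       roc = v$roc)
}

#' Re-derive the prediction equations from a cohort
#'
#' Runs the two derivation analyses on a cohort with measured urine data and
#' measured GFR: (1) stepwise multiple regression of 24-h UCr on the
#' candidates BCM, age, SCr, weight, male indicator, height and BMI; (2) the
#' univariate least-squares line of raw measured GFR (mL/min, de-normalized
#' from the stored mL/min/1.73 m^2 using each patient's BSA) on the BCM/SCr
#' ratio.
#'
#' @param cohort cohort data frame with `bcm_kg`, urine columns and
#'   `gfr_ml_min_173`.
#' @param p_enter,p_remove stepwise thresholds (see [stepwise_select()]).
#' @param config options from [renal_config()].
#' @return list with `ucr_model` (`renal_ols`) and `gfr_line`
#'   (`bcm_gfr_line`; NULL when no measured GFR).
#' @export
run_derive <- function(cohort, p_enter = 0.05, p_remove = 0.10,
                       config = renal_config()) {
  need <- c("bcm_kg", "ucr_conc_mg_dl", "uvol_24h_ml")
  ok <- complete.cases(cohort[need])
  if (sum(ok) < 10)
    stop("too few complete rows for derivation", call. = FALSE)
  d <- cohort[ok, ]
  ucr <- ucr_24h(d$ucr_conc_mg_dl, d$uvol_24h_ml)
  candidates <- data.frame(
    bcm = d$bcm_kg, age = d$age_y, scr = d$scr_mg_dl,
    weight = d$weight_kg, male = .male01(d$sex),
    height = d$height_cm, bmi = bmi(d$height_cm, d$weight_kg))
  ucr_model <- stepwise_select(candidates, ucr,
                               p_enter = p_enter, p_remove = p_remove)
  gfr_line <- NULL
  if (!all(is.na(d$gfr_ml_min_173))) {
    g <- !is.na(d$gfr_ml_min_173)
    bsa_m2 <- bsa(d$height_cm[g], d$weight_kg[g],
                  formula = config$bsa_formula)
    gfr_raw <- denormalize_bsa(d$gfr_ml_min_173[g], bsa_m2)
    gfr_line <- fit_bcm_gfr_line(d$bcm_kg[g] / d$scr_mg_dl[g], gfr_raw)
  }
  list(ucr_model = ucr_model, gfr_line = gfr_line)
}
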