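# Re-derivation of the prediction equations from data: stepwise multiple
# regression for 24-h UCr with the diagnostics reported for such models
# (partial r, VIF), and the univariate GFR ~ BCM/SCr line.

.as_design <- function(design) {
  design <- as.data.frame(design)
  if (!ncol(design)) stop("empty design", call. = FALSE)
  if (!all(vapply(design, is.numeric, logical(1))))
    stop("all predictors must be numeric (code sex as 0/1)", call. = FALSE)
  design
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from regressing predictor j
#' on all other predictors. Perfectly collinear predictors are reported as
#' `Inf` rather than raising an error.
#'
#' @param design data frame (or matrix) of numeric predictor columns; at
#'   least two predictors.
#' @return named numeric vector of VIFs, one per column.
#' @export
vif <- function(design) {
  design <- .as_design(design)
  if (ncol(design) < 2)
    stop("VIF needs at least two predictors", call. = FALSE)
  out <- vapply(seq_len(ncol(design)), function(j) {
    # perfect fits are handled explicitly below; silence lm's advisory
    r2 <- suppressWarnings(
      summary(lm(design[[j]] ~ ., data = design[-j]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(design))
}

.check_full_rank <- function(design) {
  X <- cbind(`(constant)` = 1, as.matrix(design))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinary least squares fit with the Table-2-style diagnostics
#'
#' Fits `response ~ predictors` by OLS and reports, per term: coefficient,
#' standard error, t, two-sided p (t distribution, n - k - 1 df), partial
#' correlation `sign(coef) * |t| / sqrt(t^2 + df)`, and VIF. The intercept is
#' labelled `(constant)` and carries no partial r / VIF.
#'
#' @param design data frame of numeric predictors (no constant columns).
#' @param response numeric response vector.
#' @param excluded character vector of candidate names not in the model
#'   (carried through by [stepwise_select()]).
#' @return an object of class `renal_ols`: list with `table` (term,
#'   coefficient, se, t, p, partial_r, vif), `r_squared`, `multiple_r`, `n`,
#'   `df`, `included`, `excluded`, `sigma`.
#' @export
ols_fit <- function(design, response, excluded = character(0)) {
  design <- .as_design(design)
  response <- as.numeric(response)
  n <- length(response)
  if (nrow(design) != n) stop("design/response length mismatch", call. = FALSE)
  k <- ncol(design)
  if (n <= k + 1)
    stop("need more rows than predictors + 1", call. = FALSE)
  if (any(vapply(design, function(x) var(x) == 0, logical(1))))
    stop("constant predictor column in design", call. = FALSE)
  .check_full_rank(design)

  dat <- cbind(design, .response = response)
  fit <- lm(.response ~ ., data = dat)
  sm <- summary(fit)
  ct <- sm$coefficients
  df <- fit$df.residual
  terms <- c("(constant)", names(design))
  partial <- c(NA_real_,
               sign(ct[-1, 1]) * abs(ct[-1, 3]) / sqrt(ct[-1, 3]^2 + df))
  vifs <- c(NA_real_, if (k >= 2) vif(design) else setNames(1, names(design)))
  tab <- data.frame(
    term = terms,
    coefficient = unname(ct[, 1]),
    se = unname(ct[, 2]),
    t = unname(ct[, 3]),
    p = unname(ct[, 4]),
    partial_r = unname(partial),
    vif = unname(vifs),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = tab,
    r_squared = sm$r.squared,
    multiple_r = sqrt(sm$r.squared),
    n = n, df = df, sigma = sm$sigma,
    included = names(design),
    excluded = excluded
  ), class = "renal_ols")
}

#' @export
print.renal_ols <- function(x, digits = 4, ...) {
  cat("Multiple linear regression (", x$n, " obs, ", x$df, " residual df)\n",
      sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("r^2 = %.4f, multiple r = %.4f, residual SD = %.4g\n",
              x$r_squared, x$multiple_r, x$sigma))
  if (length(x$excluded))
    cat("Variables not included in the model:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a `renal_ols` fit
#' @param object a `renal_ols` object.
#' @param ... ignored.
#' @return named coefficient vector (intercept named `(constant)`).
#' @export
coef.renal_ols <- function(object, ...) {
  setNames(object$table$coefficient, object$table$term)
}

.p_of_candidate <- function(included, cand, design, response) {
  dat <- cbind(design[c(included, cand)], .response = response)
  sm <- summary(lm(.response ~ ., data = dat))$coefficients
  sm[cand, 4]
}

#' Stepwise multiple linear regression by p-value thresholds
#'
#' Forward selection with backward elimination after each entry: at each step
#' the candidate with the smallest partial-t p-value enters if p <= `p_enter`
#' (ties broken lexicographically by column name for reproducibility); after
#' an entry, any included term whose p exceeds `p_remove` is removed, worst
#' first. Terminates when no move is possible. Refitting the returned included
#' set with [ols_fit()] reproduces the returned coefficients exactly.
#'
#' @param candidates data frame of numeric candidate predictors.
#' @param response numeric response.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be >= `p_enter`.
#' @return a `renal_ols` object whose `excluded` field lists the rejected
#'   candidates; if nothing enters, a constant-only model with an
#'   intercept-only table.
#' @export
stepwise_select <- function(candidates, response, p_enter = 0.05,
                            p_remove = 0.10) {
  candidates <- .as_design(candidates)
  response <- as.numeric(response)
  if (p_enter > p_remove)
    stop("`p_enter` must not exceed `p_remove`", call. = FALSE)
  pool <- sort(names(candidates))
  included <- character(0)

  repeat {
    moved <- FALSE
    remaining <- setdiff(pool, included)
    if (length(remaining)) {
      ps <- vapply(remaining, .p_of_candidate, numeric(1),
                   included = included, design = candidates,
                   response = response)
      best <- remaining[order(ps, remaining)][1]   # lexicographic tie-break
      if (ps[best] <= p_enter) {
        included <- c(included, best)
        moved <- TRUE
      }
    }
    # backward pass
    repeat {
      if (length(included) < 2) break
      dat <- cbind(candidates[included], .response = response)
      sm <- summary(lm(.response ~ ., data = dat))$coefficients
      pvals <- sm[included, 4]
      if (max(pvals) > p_remove) {
        worst <- included[order(-pvals, included)][1]
        included <- setdiff(included, worst)
        moved <- TRUE
      } else break
    }
    if (!moved) break
  }

  included <- sort(included)   # canonical order: refits are reproducible
  if (!length(included)) {
    n <- length(response)
    tab <- data.frame(term = "(constant)", coefficient = mean(response),
                      se = sd(response) / sqrt(n),
                      t = NA_real_, p = NA_real_,
                      partial_r = NA_real_, vif = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, r_squared = 0, multiple_r = 0,
                          n = n, df = n - 1, sigma = sd(response),
                          included = character(0), excluded = pool),
                     class = "renal_ols"))
  }
  ols_fit(candidates[included], response,
          excluded = setdiff(pool, included))
}

#' Least-squares line relating GFR to the BCM/SCr ratio
#'
#' Fits `gfr = intercept + slope * ratio` by OLS and reports Pearson r. The
#' published body-composition GFR estimate is the special case
#' slope 3.3, intercept -5.1 (see [bcm_gfr()]).
#'
#' @param ratio BCM/SCr values, kg per mg/dL.
#' @param gfr measured GFR values, mL/min.
#' @return object of class `bcm_gfr_line`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `pearson_r`, `n`.
#' @export
fit_bcm_gfr_line <- function(ratio, gfr) {
  ratio <- as.numeric(ratio); gfr <- as.numeric(gfr)
  if (length(ratio) != length(gfr)) stop("length mismatch", call. = FALSE)
  if (length(ratio) < 2) stop("need at least two points", call. = FALSE)
  if (var(ratio) == 0) stop("BCM/SCr ratio is constant", call. = FALSE)
  fit <- lm(gfr ~ ratio)
  ct <- summary(fit)$coefficients
  structure(list(
    slope = ct["ratio", 1], intercept = ct["(Intercept)", 1],
    slope_se = ct["ratio", 2], intercept_se = ct["(Intercept)", 2],
    pearson_r = cor(ratio, gfr), n = length(ratio)
  ), class = "bcm_gfr_line")
}

#' @export
print.bcm_gfr_line <- function(x, ...) {
  cat(sprintf("GFR = %.4g + %.4g x BCM/SCr  (r = %.4f, n = %d)\n",
              x$intercept, x$slope, x$pearson_r, x$n))
  invisible(x)
}
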