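# Independent brute-force oracles used to cross-check the implementation.

# OLS by explicit normal equations (no lm)
oracle_normal_equations <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# Empirical AUC by exhaustive concordant-pair counting, for the convention
# "condition positive <=> low score" (ties count 1/2).
oracle_auc <- function(scores, condition) {
  pos <- scores[condition]
  neg <- scores[!condition]
  total <- 0
  for (p in pos)
    total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Lin's concordance by direct arithmetic on moments
oracle_ccc <- function(x, y) {
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# small valid cohort table built in code
make_cohort <- function(n = 6) {
  data.frame(
    patient_id = sprintf("X%03d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    age_y = seq(35, 75, length.out = n),
    height_cm = rep(c(155, 172), length.out = n),
    weight_kg = seq(55, 90, length.out = n),
    bcm_kg = seq(16, 33, length.out = n),
    fat_kg = rep(20, n), ecw_kg = rep(15, n),
    resistance_ohm = rep(450, n), reactance_ohm = rep(45, n),
    scr_mg_dl = seq(0.8, 4.5, length.out = n),
    ucr_conc_mg_dl = rep(70, n),
    uvol_24h_ml = rep(1500, n),
    gfr_ml_min_173 = seq(80, 12, length.out = n),
    stringsAsFactors = FALSE
  )
}
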