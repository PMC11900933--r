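# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, n_a) group
# assignments of the pooled ranks (no ties assumed).
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- combn(n, na)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Closed-form 2x2 Pearson chi-squared statistic n(ad - bc)^2 / product of
# marginals.
oracle_chisq_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# A zero profile and a helper to build profiles with selected sites set.
zero_profile <- function() {
  setNames(rep(0, 5), clock_sites())
}

profile_with <- function(...) {
  p <- zero_profile()
  vals <- c(...)
  p[names(vals)] <- vals
  p
}

# Hand-evaluated clock value for (ELOVL2=50, C1orf132=40, TRIM59=30, KLF14=5,
# FHL2=20), computed term by term from the published coefficients before the
# implementation existed.
HAND_CLOCK_VALUE <- 30.42245172321073

# A fixed risk profile for the grid-search inversion oracle.
fixture_risk_profile <- function() {
  list(age = 55, sex = "M", sbp = 150, on_htn_treatment = TRUE,
       smoker = FALSE, diabetic = TRUE, total_chol = 210, hdl_chol = 38)
}

# Fine-grid inversion oracle: minimise |reference risk(age) - target| over a
# 0.001-year grid.
oracle_vascular_age_grid <- function(target_risk, sex, ref = frs_reference(),
                                     step = 0.001, lower = 15, upper = 120) {
  ages <- seq(lower, upper, by = step)
  rr <- suppressWarnings(general_cvd_risk(
    ages, sex, ref$sbp, ref$on_htn_treatment, ref$smoker, ref$diabetic,
    ref$total_chol, ref$hdl_chol
  ))
  ages[which.min(abs(rr - target_risk))]
}

# Random valid risk profile within the nominal validity ranges.
random_risk_profile <- function() {
  list(
    age = runif(1, 30, 74),
    sex = sample(c("F", "M"), 1),
    sbp = runif(1, 95, 175),
    on_htn_treatment = runif(1) < 0.4,
    smoker = runif(1) < 0.3,
    diabetic = runif(1) < 0.25,
    total_chol = runif(1, 130, 280),
    hdl_chol = runif(1, 28, 90)
  )
}
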