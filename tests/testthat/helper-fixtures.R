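# Shared fixtures, all built in code.

# Linear test tariff: utility = 1 - dec * sum(level - 1). Closed form makes
# expected utilities trivially computable in tests.
linear_test_tariff <- function(dec = 0.05) {
  co <- stats::setNames(
    rep(dec * (1:4), 5),
    paste0(rep(c("MO", "SC", "UA", "PD", "AD"), each = 4), 2:5))
  tariff_from_coefficients(co, name = sprintf("linear-%.2f", dec))
}

# Brute-force oracle for the linear tariff, independent of the package's
# expansion path.
linear_tariff_oracle <- function(levels, dec = 0.05) {
  1 - dec * sum(levels - 1)
}

# A small complete (no-missingness) synthetic trial.
small_complete_trial <- function(n_per_arm = 40, seed = 11, ...) {
  generate_trial(generator_config(
    n_per_arm = n_per_arm, seed = seed,
    missing_rates = zero_missing_rates(), ...))
}

zero_missing_rates <- function() {
  list(eq5d = c(0, 0, 0), resource = c(0, 0, 0),
       other_item_soft = 0, other_item_hard = 0,
       coupling = 0, monotone_boost = 0)
}

# A tiny analysis frame with a known linear structure, for imputation and
# SUR tests that should not depend on the full generator.
toy_analysis_frame <- function(n = 120, seed = 3) {
  set.seed(seed)
  arm <- factor(rep(c("control", "intervention"), each = n / 2),
                levels = c("control", "intervention"))
  age <- rnorm(n, 60, 8)
  bmi <- rnorm(n, 28, 4)
  pain_nrs_0 <- sample(4:10, n, replace = TRUE)
  grip_strength <- rnorm(n, 20, 6)
  analgesic <- runif(n) < 0.6
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.8, 0.2))
  u0 <- pmin(0.6 + 0.02 * (7 - pain_nrs_0) + rnorm(n, 0, 0.15), 1)
  u6 <- pmin(u0 + rnorm(n, 0.02, 0.1), 1)
  u12 <- pmin(u0 + rnorm(n, 0.02, 0.1), 1)
  hc0 <- rgamma(n, 1, scale = 300)
  hc6 <- rgamma(n, 1, scale = 250)
  hc12 <- rgamma(n, 1, scale = 250)
  data.frame(id = sprintf("T%03d", 1:n), arm, age, gender, bmi, pain_nrs_0,
             grip_strength, analgesic, u0, u6, u12, hc0, hc6, hc12,
             ext0 = 0, ext6 = 0, ext12 = 0,
             med_cost = rgamma(n, 2, scale = 140),
             drug_cost = ifelse(arm == "intervention", 42, 0),
             pain_nrs_6 = pmin(pmax(pain_nrs_0 +
                                      round(rnorm(n, -0.5, 1.5)), 0), 10),
             pain_nrs_12 = pmin(pmax(pain_nrs_0 +
                                       round(rnorm(n, -0.5, 1.5)), 0), 10),
             stringsAsFactors = FALSE)
}
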