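test_that("generator produces balanced arms of the configured size", {
  tr <- generate_trial(generator_config(n_per_arm = 124, seed = 1))
  expect_equal(nrow(tr$data), 248)
  expect_equal(sum(tr$data$arm == "intervention"), 124)
  expect_equal(sum(tr$data$arm == "control"), 124)
  expect_true(all(!duplicated(tr$data$id)))
})

test_that("zero missing rates give a dataset with no missing fields", {
  tr <- small_complete_trial(n_per_arm = 20)
  non_drug <- setdiff(names(tr$data), c("hcq_dose_mg", "hcq_days"))
  expect_false(anyNA(tr$data[, non_drug]))
  # drug fields are structurally absent only in the control arm
  expect_false(anyNA(tr$data[tr$data$arm == "intervention",
                             c("hcq_dose_mg", "hcq_days")]))
})

test_that("identical seed and config reproduce identical output", {
  cfg <- generator_config(n_per_arm = 30, seed = 99)
  expect_identical(generate_trial(cfg)$data, generate_trial(cfg)$data)
  tr <- generate_trial(cfg)
  m1 <- apply_mar_missingness(tr$complete, cfg$missing_rates,
                              cfg$mar_coefficients, seed = 5)
  m2 <- apply_mar_missingness(tr$complete, cfg$missing_rates,
                              cfg$mar_coefficients, seed = 5)
  expect_identical(m1, m2)
})

test_that("realized visit-level missingness stays within binomial error", {
  cfg <- generator_config(
    n_per_arm = 124, seed = 21,
    missing_rates = list(eq5d = c(0, 0.1, 0.25), resource = c(0, 0.1, 0.25),
                         other_item_soft = 0, other_item_hard = 0,
                         coupling = 0.5, monotone_boost = 1.0))
  tr <- generate_trial(cfg)
  frac12 <- mean(is.na(tr$data$eq5d_mo_12))
  tol <- 3 * sqrt(0.25 * 0.75 / 248)
  expect_lt(abs(frac12 - 0.25), tol)
  frac6 <- mean(is.na(tr$data$eq5d_mo_6))
  expect_lt(abs(frac6 - 0.10), 3 * sqrt(0.1 * 0.9 / 248))
})

test_that("masking driven by a maskable field is rejected as MNAR", {
  tr <- small_complete_trial(n_per_arm = 10)
  expect_error(
    apply_mar_missingness(tr$complete,
                          mar_coefficients = c(u12 = 0.5), seed = 1),
    "missing not at random")
  expect_error(generator_config(mar_coefficients = c(qaly = 1)),
               "missing not at random")
})

test_that("missingness is weakly monotone: missing at 6m raises the 12m rate", {
  cfg <- generator_config(n_per_arm = 1500, seed = 31)
  tr <- generate_trial(cfg)
  m6 <- is.na(tr$data$eq5d_mo_6)
  m12 <- is.na(tr$data$eq5d_mo_12)
  expect_gt(mean(m12[m6]), mean(m12[!m6]))
})

test_that("complete-data arm contrasts converge to the configured truths", {
  cfg <- generator_config(n_per_arm = 5000, seed = 8,
                          missing_rates = zero_missing_rates())
  tr <- generate_trial(cfg)
  fa <- finalize_analysis_data(build_analysis_data(
    tr$data, tariff = cfg$tariff, unit_costs = cfg$unit_costs,
    medication_costs = cfg$medication_costs))
  int <- fa$arm == "intervention"
  dq <- mean(fa$qaly[int]) - mean(fa$qaly[!int])
  dc <- mean(fa$total_cost[int]) - mean(fa$total_cost[!int])
  se_q <- sqrt(var(fa$qaly[int]) / sum(int) + var(fa$qaly[!int]) / sum(!int))
  se_c <- sqrt(var(fa$total_cost[int]) / sum(int) +
                 var(fa$total_cost[!int]) / sum(!int))
  expect_lt(abs(dq - (-0.0052)), 3 * se_q)
  expect_lt(abs(dc - (-11.80)), 3 * se_c)
})

test_that("arm label carries no outcome signal when the true deltas are zero", {
  cfg <- generator_config(
    n_per_arm = 1000, seed = 17, true_delta_cost = 0, true_delta_qaly = 0,
    pain_delta = 0, med_cost_mean = c(intervention = 291, control = 291),
    missing_rates = zero_missing_rates())
  tr <- generate_trial(cfg)
  fa <- finalize_analysis_data(build_analysis_data(
    tr$data, tariff = cfg$tariff, unit_costs = cfg$unit_costs,
    medication_costs = cfg$medication_costs))
  int <- fa$arm == "intervention"
  # permutation test of the arm mean contrast at alpha = 0.01
  perm_p <- function(y) {
    obs <- abs(mean(y[int]) - mean(y[!int]))
    set.seed(1)
    null <- replicate(499, {
      s <- sample(int)
      abs(mean(y[s]) - mean(y[!s]))
    })
    mean(c(obs, null) >= obs)
  }
  expect_gt(perm_p(fa$qaly), 0.01)
  expect_gt(perm_p(fa$total_cost), 0.01)
  expect_gt(perm_p(fa$pain_nrs_6), 0.01)
})

test_that("pain/discomfort marginal places >= 95% of participants above level 1", {
  tr <- small_complete_trial(n_per_arm = 500, seed = 13)
  for (t in c("0", "6", "12")) {
    expect_gte(mean(tr$data[[paste0("eq5d_pd_", t)]] > 1), 0.95)
  }
})

test_that("scored utilities have the configured baseline location and spread", {
  tr <- small_complete_trial(n_per_arm = 2000, seed = 23)
  u0 <- build_analysis_data(tr$data, tariff = tr$config$tariff,
                            unit_costs = tr$config$unit_costs,
                            medication_costs = tr$config$medication_costs)$u0
  # profile discretisation shifts the mean by at most ~0.01
  expect_lt(abs(mean(u0) - 0.613), 0.02)
  expect_lt(abs(sd(u0) - 0.178), 0.03)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_per_arm = 1), "n_per_arm")
  expect_error(generator_config(baseline_utility_sd = -0.1), "sd")
  expect_error(generator_config(
    missing_rates = list(eq5d = c(0, 0.5, 1.2), resource = c(0, 0, 0),
                         other_item_soft = 0, other_item_hard = 0,
                         coupling = 0, monotone_boost = 0)),
    "probabilities")
  expect_error(generator_config(hcq_full_duration_prob = -0.2),
               "probabilities")
})

test_that("participant CSV round-trips with a truth sidecar", {
  d <- withr::local_tempdir()
  tr <- generate_trial(generator_config(n_per_arm = 25, seed = 5))
  p <- file.path(d, "trial.csv")
  write_trial_csv(tr, p)
  expect_true(file.exists(paste0(p, ".truth.json")))
  back <- read_trial_csv(p)
  expect_equal(nrow(back), nrow(tr$data))
  expect_equal(back$age, tr$data$age)
  expect_equal(is.na(back$eq5d_mo_12), is.na(tr$data$eq5d_mo_12))
  truth <- jsonlite::read_json(paste0(p, ".truth.json"))
  expect_equal(truth$true_delta_qaly, -0.0052)
})
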