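test_that("SUR with identical regressors equals per-equation least squares", {
  df <- finalize_analysis_data(toy_analysis_frame(200, seed = 5))
  fit <- fit_sur(df)
  fml <- total_cost ~ arm + baseline_utility + baseline_cost + pain_nrs_0 +
    analgesic + grip_strength + bmi + age + gender
  ols_c <- lm(fml, data = df)
  ols_q <- lm(update(fml, qaly ~ .), data = df)
  expect_lt(abs(fit$delta_cost - coef(ols_c)[["armintervention"]]), 1e-8)
  expect_lt(abs(fit$delta_qaly - coef(ols_q)[["armintervention"]]), 1e-8)
  expect_lt(max(abs(fit$coefficients[, "cost"] - coef(ols_c))), 1e-8)
  expect_lt(max(abs(fit$coefficients[, "qaly"] - coef(ols_q))), 1e-8)
})

test_that("SUR rejects singular designs naming the collinear column", {
  df <- finalize_analysis_data(toy_analysis_frame(80))
  df$bmi <- df$age  # exact collinearity after both enter
  expect_error(fit_sur(df, sur_spec(covariates = c("age", "bmi"))),
               "collinear.*bmi|bmi.*collinear")
  expect_error(fit_sur(df[0, ]))  # degenerate input: no rows
})

test_that("SUR refuses missing modelled fields", {
  df <- finalize_analysis_data(toy_analysis_frame(60))
  df$qaly[3] <- NA
  expect_error(fit_sur(df), "missing")
})

test_that("bootstrap cloud is seed-deterministic and stratified by arm", {
  df <- finalize_analysis_data(toy_analysis_frame(80))
  stat <- function(d) c(delta_cost = mean(d$total_cost), delta_qaly = 0)
  c1 <- bootstrap_cloud(df, stat, B = 25, seed = 3)
  c2 <- bootstrap_cloud(df, stat, B = 25, seed = 3)
  expect_identical(c1$replicates, c2$replicates)
  expect_equal(nrow(c1$replicates), 25)
  # B = 1 gives a one-pair cloud
  c3 <- bootstrap_cloud(df, stat, B = 1, seed = 1)
  expect_equal(dim(c3$replicates), c(1L, 2L))
  # stratified resampling preserves per-arm sizes on every replicate
  count_stat <- function(d) c(delta_cost = sum(d$arm == "intervention"),
                              delta_qaly = sum(d$arm == "control"))
  cc <- bootstrap_cloud(df, count_stat, B = 20, seed = 2)
  expect_true(all(cc$replicates[, "delta_cost"] == 40))
  expect_true(all(cc$replicates[, "delta_qaly"] == 40))
})

test_that("bootstrap cloud mean agrees with the point estimate", {
  df <- finalize_analysis_data(toy_analysis_frame(150, seed = 12))
  stat <- function(d) {
    f <- fit_sur(d)
    c(delta_cost = f$delta_cost, delta_qaly = f$delta_qaly)
  }
  point <- stat(df)
  cl <- bootstrap_cloud(df, stat, B = 600, seed = 4)
  for (k in c("delta_cost", "delta_qaly")) {
    mc_se <- sd(cl$replicates[, k]) / sqrt(cl$B)
    expect_lt(abs(mean(cl$replicates[, k]) - point[[k]]), 4 * mc_se)
  }
})

test_that("bootstrap aborts when more than 1% of replicates fail", {
  df <- finalize_analysis_data(toy_analysis_frame(40))
  flaky <- function(d) if (runif(1) < 0.2) stop("boom") else
    c(delta_cost = 1, delta_qaly = 1)
  expect_error(bootstrap_cloud(df, flaky, B = 200, seed = 1), "failed")
})

test_that("percentile endpoints are order statistics and BCa reduces to percentile", {
  cloud <- as.numeric(1:1000)
  pi <- percentile_interval(cloud, level = 0.95)
  expect_equal(as.numeric(pi), c(25, 975))  # exact rank check
  # symmetric cloud about the estimate: z0 = 0 and a = 0 force equality
  set.seed(6)
  sym <- c(-(1:500), 1:500) / 100
  point <- 0
  bca_forced <- bca_interval(sym, point, z0 = 0, a = 0)
  expect_equal(as.numeric(bca_forced), as.numeric(percentile_interval(sym)))
  # exactly half the replicates below the estimate gives z0 = 0
  bca_auto <- bca_interval(sym, point, jackknife = NULL)
  expect_equal(attr(bca_auto, "z0"), 0)
  expect_equal(attr(bca_auto, "a"), 0)
  expect_equal(as.numeric(bca_auto), as.numeric(bca_forced))
})

test_that("degenerate clouds give degenerate intervals", {
  ci <- bca_interval(rep(2.5, 300), 2.5)
  expect_equal(as.numeric(ci), c(2.5, 2.5))
  expect_error(bca_interval(rnorm(50), 0), "100")
})

test_that("BCa agrees with the boot package on a skewed mean", {
  skip_if_not_installed("boot")
  set.seed(10)
  x <- rexp(60)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 1999)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- bca_interval(as.numeric(bt$t), mean(x), jack)
  # same replicate set; endpoint conventions differ by interpolation only
  expect_lt(max(abs(unname(mine) - ref)), 0.02)
})

test_that("pain GLS equals OLS arm effects in balanced panels", {
  df <- toy_analysis_frame(80, seed = 21)
  long <- pain_long(df)
  fit <- fit_pain_mixed_model(long)
  ols <- lm(pain ~ visit + pain_nrs_0 + analgesic + grip_strength + bmi +
              age + gender + visit:arm, data = transform(
                long, visit = factor(visit),
                arm = factor(arm, levels = c("control", "intervention"))))
  expect_equal(fit$arm_effects$estimate,
               unname(coef(ols)[c("visit6:armintervention",
                                  "visit12:armintervention")]),
               tolerance = 1e-6)
  expect_true(fit$rho > -1 && fit$rho < 1)
})

test_that("duplicating every observation leaves the arm effect unchanged", {
  df <- toy_analysis_frame(6, seed = 33)
  long <- pain_long(df)
  fit1 <- fit_pain_mixed_model(long, covariates = "pain_nrs_0")
  fit2 <- fit_pain_mixed_model(rbind(long, long), covariates = "pain_nrs_0")
  expect_equal(fit1$arm_effects$estimate, fit2$arm_effects$estimate,
               tolerance = 1e-6)
})

test_that("the pain model recovers a configured arm shift", {
  cfg <- generator_config(n_per_arm = 2000, seed = 14, pain_delta = 0.16,
                          missing_rates = zero_missing_rates())
  tr <- generate_trial(cfg)
  fit <- fit_pain_mixed_model(pain_long(tr$data))
  eff6 <- fit$arm_effects[fit$arm_effects$visit == "6", ]
  expect_lt(abs(eff6$estimate - 0.16), 3 * eff6$se)
})
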