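test_that("zero-missingness input returns m identical copies", {
  df <- toy_analysis_frame(60)
  res <- mice_pmm(df, imputation_spec(m = 3, seed = 1))
  expect_length(res$imputations, 3)
  expect_identical(res$imputations[[1]], df)
  expect_identical(res$imputations[[2]], df)
  expect_length(res$imputed_vars, 0)
})

test_that("every imputed value is an observed donor value and observed cells are untouched", {
  set.seed(4)
  df <- toy_analysis_frame(150)
  miss <- df
  holes <- list()
  for (v in c("u12", "hc6", "hc12")) {
    idx <- sample(nrow(df), 30)
    holes[[v]] <- idx
    miss[[v]][idx] <- NA
  }
  res <- mice_pmm(miss, imputation_spec(m = 4, iterations = 5, seed = 2))
  for (imp in res$imputations) {
    for (v in names(holes)) {
      observed_pool <- df[[v]][-holes[[v]]]
      # PMM guarantee: donors are observed values of the same variable
      expect_true(all(imp[[v]][holes[[v]]] %in% observed_pool))
      # untouched elsewhere
      expect_identical(imp[[v]][-holes[[v]]], miss[[v]][-holes[[v]]])
    }
    # completed datasets differ from the input only at originally-missing cells
    same_cols <- setdiff(names(df), names(holes))
    expect_identical(imp[, same_cols], miss[, same_cols])
  }
})

test_that("MCAR deletion is recovered within Monte-Carlo error", {
  set.seed(7)
  df <- toy_analysis_frame(600, seed = 8)
  truth_mean <- mean(df$u12)
  miss <- df
  idx <- sample(nrow(df), 120)  # 20%
  miss$u12[idx] <- NA
  res <- mice_pmm(miss, imputation_spec(m = 10, iterations = 5, seed = 3))
  pooled_mean <- mean(vapply(res$imputations,
                             function(d) mean(d$u12), numeric(1)))
  # bound: 3 * sd * sqrt(2 * n_miss) / n for the imputed-cell contribution
  tol <- 3 * sd(df$u12) * sqrt(2 * length(idx)) / nrow(df)
  expect_lt(abs(pooled_mean - truth_mean), tol)
})

test_that("degenerate imputation inputs raise informative errors", {
  df <- toy_analysis_frame(40)
  df$u12 <- NA_real_
  expect_error(mice_pmm(df, imputation_spec(m = 2, seed = 1)), "donors")
  df2 <- toy_analysis_frame(40)
  df2$gender[3] <- NA
  expect_error(mice_pmm(df2, imputation_spec(m = 2, seed = 1)),
               "non-numeric|covariates")
  expect_error(imputation_spec(m = 1), "m must be")
  expect_error(imputation_spec(pmm_donors = 0), "pmm_donors")
})

test_that("Rubin pooling matches hand arithmetic", {
  # estimates {1, 3}, variances {0, 0}: pooled 2, total var (1 + 1/2) * 2 = 3
  p <- pool_rubin(c(1, 3), c(0, 0))
  expect_equal(p$estimate, 2)
  expect_equal(p$between, 2)
  expect_equal(p$variance, 3)
  # identical estimates: between-variance zero, pooled = the value
  p2 <- pool_rubin(c(5, 5, 5), c(1, 1, 1))
  expect_equal(p2$estimate, 5)
  expect_equal(p2$between, 0)
  expect_equal(p2$variance, 1)
  expect_equal(p2$df, Inf)
  # invariant to imputation ordering
  e <- c(0.3, -1.2, 2.2, 0.7); v <- c(0.5, 0.2, 0.9, 0.4)
  o <- c(3, 1, 4, 2)
  expect_equal(pool_rubin(e, v), pool_rubin(e[o], v[o]))
  expect_error(pool_rubin(c(1, 2), c(1, 2, 3)), "matching")
  expect_error(pool_rubin(1, 1), "m >= 2")
})

test_that("Barnard-Rubin df is finite and below the complete-data df", {
  p <- pool_rubin(c(1, 2, 1.5, 1.8), c(0.5, 0.6, 0.55, 0.5), dfcom = 100)
  expect_true(is.finite(p$df))
  expect_lt(p$df, 100)
  expect_gt(p$df, 0)
})
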