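test_that("anchor state scores exactly 1 and missing dimensions propagate", {
  tar_lin <- linear_test_tariff()
  tar_syn <- load_tariff(system.file("extdata",
                                     "tariff_synthetic_decrements.csv",
                                     package = "trialcea"))
  expect_identical(score_eq5d(c(1, 1, 1, 1, 1), tar_lin), 1)
  expect_identical(score_eq5d(c(1, 1, 1, 1, 1), tar_syn), 1)
  expect_true(is.na(score_eq5d(c(2, 1, 1, 1, NA), tar_lin)))
  expect_true(is.na(score_eq5d(c(NA, NA, NA, NA, NA), tar_syn)))
})

test_that("linear test tariff matches its closed form, e.g. 33333 -> 0.50", {
  tar <- linear_test_tariff(0.05)
  expect_equal(score_eq5d(c(3, 3, 3, 3, 3), tar), 0.50)
  expect_equal(score_eq5d(c(5, 5, 5, 5, 5), tar), 0)
  # spot-check a batch against the brute-force closed form
  set.seed(1)
  profs <- matrix(sample(1:5, 50 * 5, replace = TRUE), ncol = 5)
  expect_equal(score_eq5d(profs, tar),
               apply(profs, 1, linear_tariff_oracle))
})

test_that("invalid levels raise errors naming the dimension", {
  tar <- linear_test_tariff()
  expect_error(score_eq5d(c(0, 1, 1, 1, 1), tar), "MO")
  expect_error(score_eq5d(c(1, 1, 1, 6, 1), tar), "PD")
  expect_error(score_eq5d(c(1, 1, 1), tar), "5")
})

test_that("coefficient tariff agrees with exhaustive expansion on all 3125 states", {
  tar_co <- linear_test_tariff(0.05)
  # oracle: brute-force expansion computed independently of the package
  states <- as.matrix(expand.grid(AD = 1:5, PD = 1:5, UA = 1:5,
                                  SC = 1:5, MO = 1:5))[, 5:1]
  oracle_u <- 1 - 0.05 * (rowSums(states) - 5)
  exhaustive <- data.frame(state = apply(states, 1, paste0, collapse = ""),
                           utility = oracle_u)
  tar_ex <- tariff_from_states(exhaustive)
  expect_equal(score_eq5d(states, tar_co), score_eq5d(states, tar_ex))
  expect_equal(score_eq5d(states, tar_co), oracle_u)
})

test_that("tariff CSV round-trips in both dialects with validation errors", {
  tar <- linear_test_tariff(0.03)
  d <- withr::local_tempdir()

  # exhaustive dialect
  p_ex <- file.path(d, "exhaustive.csv")
  write.csv(expand_tariff(tar), p_ex, row.names = FALSE, quote = FALSE)
  loaded <- load_tariff(p_ex)
  expect_equal(loaded$utilities, tar$utilities)

  # coefficient dialect
  p_co <- file.path(d, "coef.csv")
  co <- data.frame(term = paste0(rep(c("MO", "SC", "UA", "PD", "AD"),
                                     each = 4), 2:5),
                   value = rep(0.03 * (1:4), 5))
  write.csv(co, p_co, row.names = FALSE, quote = FALSE)
  expect_equal(load_tariff(p_co)$utilities, tar$utilities)

  # missing state
  p_bad <- file.path(d, "missing.csv")
  tab <- expand_tariff(tar)
  write.csv(tab[tab$state != "55555", ], p_bad, row.names = FALSE,
            quote = FALSE)
  expect_error(load_tariff(p_bad), "55555")

  # duplicate state
  p_dup <- file.path(d, "dup.csv")
  write.csv(rbind(tab, tab[1, ]), p_dup, row.names = FALSE, quote = FALSE)
  expect_error(load_tariff(p_dup), "duplicate")

  # broken anchor
  p_anchor <- file.path(d, "anchor.csv")
  tab2 <- tab
  tab2$utility[tab2$state == "11111"] <- 0.9
  write.csv(tab2, p_anchor, row.names = FALSE, quote = FALSE)
  expect_error(load_tariff(p_anchor), "11111")
})

test_that("nonnegative-decrement tariffs are monotone in every dimension", {
  for (tar in list(linear_test_tariff(),
                   load_tariff(system.file(
                     "extdata", "tariff_synthetic_decrements.csv",
                     package = "trialcea")))) {
    u <- array(tar$utilities, dim = c(5, 5, 5, 5, 5))  # AD fastest index
    for (d in 1:5) {
      worse <- apply(u, setdiff(1:5, d), diff)
      expect_true(all(worse <= 1e-12),
                  label = paste("dimension", d, "monotone for", tar$name))
    }
  }
})

test_that("scoring is pure: identical inputs give identical outputs", {
  tar <- load_tariff(system.file("extdata",
                                 "tariff_synthetic_decrements.csv",
                                 package = "trialcea"))
  prof <- c(2, 3, 1, 4, 2)
  expect_identical(score_eq5d(prof, tar), score_eq5d(prof, tar))
})
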