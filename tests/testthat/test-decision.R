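test_that("ICER quadrant semantics follow the CE-plane conventions", {
  sw <- icer(-11.80, -0.0052)
  expect_equal(sw$quadrant, "SW")
  expect_equal(sw$interpretation, "cost saved per QALY lost")
  expect_equal(sw$value, -11.80 / -0.0052)  # positive saving per QALY lost
  expect_gt(sw$value, 0)

  ne <- icer(100, 0.01)
  expect_equal(ne$quadrant, "NE")
  expect_equal(ne$value, 10000)
  expect_equal(ne$interpretation, "cost per QALY gained")

  se <- icer(-1, 0.001)
  expect_equal(se$quadrant, "SE")
  expect_equal(se$interpretation, "dominant")
  expect_true(is.na(se$value))

  nw <- icer(5, -0.001)
  expect_equal(nw$quadrant, "NW")
  expect_equal(nw$interpretation, "dominated")

  zero <- icer(10, 0)
  expect_true(is.na(zero$value))
  expect_match(zero$interpretation, "zero effect")
})

test_that("net benefit is lambda * dE - dC, linear in lambda", {
  expect_equal(net_benefit(-11.80, -0.0052, 20000), -92.20)
  expect_equal(net_benefit(0, 0, 35000), 0)
  expect_error(net_benefit(1, 1, 0), "lambda")
  set.seed(3)
  dc <- rnorm(20); dq <- rnorm(20, 0, 0.01)
  l1 <- 15000; l2 <- 27000; w <- 0.3
  expect_equal(net_benefit(dc, dq, w * l1 + (1 - w) * l2),
               w * net_benefit(dc, dq, l1) + (1 - w) * net_benefit(dc, dq, l2))
  expect_equal(net_health_benefit_qaly(-11.80, -0.0052, 20000),
               -0.0052 + 11.80 / 20000)
})

test_that("CEAC equals brute-force net-benefit counting", {
  set.seed(8)
  cloud <- cbind(delta_cost = rnorm(400, 0, 50),
                 delta_qaly = rnorm(400, 0, 0.01))
  grid <- seq(0, 50000, by = 2500)
  curve <- ceac(cloud, grid)
  brute <- vapply(grid, function(l) {
    hits <- 0
    for (b in seq_len(nrow(cloud))) {
      nb <- l * cloud[b, "delta_qaly"] - cloud[b, "delta_cost"]
      if (nb > 0) hits <- hits + 1
    }
    hits / nrow(cloud)
  }, numeric(1))
  expect_equal(curve$probability, brute)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("CEAC degenerate and symmetric cases behave as counted", {
  se_cloud <- cbind(delta_cost = -abs(rnorm(50)) - 1,
                    delta_qaly = abs(rnorm(50)) + 0.001)
  expect_true(all(ceac(se_cloud)$probability == 1))
  two <- cbind(delta_cost = c(-1, 1), delta_qaly = c(0, 0))
  expect_equal(ceac(two, 10000)$probability, 0.5)
  set.seed(12)
  sym <- cbind(delta_cost = c(rnorm(2000)), delta_qaly = c(rnorm(2000, 0, 0.01)))
  sym <- rbind(sym, -sym)  # exactly symmetric about the origin
  pr <- ceac(sym, c(0, 20000, 30000, 50000))$probability
  expect_true(all(abs(pr - 0.5) < 3 * sqrt(0.25 / nrow(sym)) + 1e-9))
  expect_error(ceac(sym, numeric(0)), "grid")
  expect_error(ceac(sym[0, , drop = FALSE]), "empty")
})

test_that("CE-plane quadrant shares partition the cloud", {
  set.seed(5)
  cloud <- cbind(delta_cost = rnorm(999), delta_qaly = rnorm(999, 0, 0.01))
  cp <- ce_plane_summary(cloud)
  expect_equal(sum(cp$quadrant_shares), 1)
  expect_equal(nrow(cp$points), 999)
  # symmetric cloud: each quadrant ~ 1/4
  sym <- rbind(cloud, cbind(delta_cost = -cloud[, 1],
                            delta_qaly = -cloud[, 2]))
  shares <- ce_plane_summary(sym)$quadrant_shares
  expect_true(all(abs(shares - 0.25) < 3 * sqrt(0.25 * 0.75 / nrow(sym)) + 0.01))
  # boundary convention: the origin counts as a gain and a cost increase
  origin <- ce_plane_summary(cbind(delta_cost = c(0, 0),
                                   delta_qaly = c(0, 0)))
  expect_equal(unname(origin$quadrant_shares["NE"]), 1)
  expect_equal(sum(origin$quadrant_shares), 1)
})

test_that("cost-effectiveness status changes at most once along the threshold grid", {
  set.seed(9)
  cloud <- cbind(delta_cost = rnorm(300, 0, 40),
                 delta_qaly = rnorm(300, 0, 0.008))
  cloud <- cloud[cloud[, "delta_qaly"] != 0, ]
  grid <- seq(0, 50000, by = 500)
  status <- sapply(grid, function(l)
    l * cloud[, "delta_qaly"] - cloud[, "delta_cost"] > 0)
  flips <- apply(status, 1, function(s) sum(diff(s) != 0))
  expect_true(all(flips <= 1))
})

test_that("in the SW quadrant |ICER| > lambda and positive net benefit agree", {
  set.seed(11)
  dc <- rnorm(500, 0, 60)
  dq <- -abs(rnorm(500, 0, 0.01)) - 1e-6  # all QALY-losing replicates
  for (lambda in c(20000, 30000)) {
    ratio_rule <- (dc / dq) > lambda          # saving per QALY lost exceeds lambda
    nb_rule <- net_benefit(dc, dq, lambda) > 0
    expect_identical(ratio_rule, nb_rule)
  }
})
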