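test_that("Marcus rate reproduces the 10-Angstrom solvated-pair value", {
  r <- marcus_rate(0.115, 0.66, 0.39, 300)
  expect_equal(signif(r$k, 1), 0.03)
  expect_equal(r$region, "normal")
  # joint corner scan over the reported lambda / Delta A intervals
  rb <- marcus_rate(0.115, 0.66, 0.39, 300,
                    bounds = list(lambda_reorg = c(0.63, 0.71),
                                  delta_A = c(0.38, 0.39)))
  expect_equal(signif(rb$k_bounds, 1), c(0.02, 0.04))
  expect_true(rb$k_bounds[1] <= rb$k && rb$k <= rb$k_bounds[2])
})

test_that("Marcus rate limits and scaling laws hold", {
  expect_equal(marcus_rate(0, 0.66, 0.39)$k, 0)
  # activationless: rate equals the hand-evaluated prefactor
  hbar <- 6.582120e-16; kT <- kT300
  pref <- 2 * pi / hbar * 0.115^2 / sqrt(4 * pi * 0.66 * kT) * 1e-9
  expect_equal(marcus_rate(0.115, 0.66, -0.66)$k, pref, tolerance = 1e-12)
  # |H|^2 scaling for random coupling pairs
  set.seed(4)
  for (i in 1:5) {
    h <- runif(2, 0.001, 0.3)
    expect_equal(marcus_rate(h[2], 0.5, 0.1)$k / marcus_rate(h[1], 0.5, 0.1)$k,
                 (h[2] / h[1])^2, tolerance = 1e-10)
  }
  # unit round trip: independent s^-1 computation converted to ns^-1
  k_si <- 2 * pi / hbar * 0.115^2 / sqrt(4 * pi * 0.66 * kT) *
    exp(-(0.66 + 0.39)^2 / (4 * 0.66 * kT))
  expect_equal(marcus_rate(0.115, 0.66, 0.39)$k, k_si * 1e-9,
               tolerance = 1e-12)
  expect_error(marcus_rate(0.1, 0, 0.3), "lambda")
})

test_that("rate is maximal at the activationless point (Marcus turnover)", {
  dAs <- seq(-1.5, 0.5, by = 0.01)
  ks <- vapply(dAs, function(d) marcus_rate(0.1, 0.66, d)$k, numeric(1))
  expect_equal(dAs[which.max(ks)], -0.66, tolerance = 0.011)
  # monotone decrease beyond the turnover in both directions
  expect_true(all(diff(ks[dAs >= -0.66]) < 0))
  expect_true(all(diff(ks[dAs <= -0.66]) > 0))
  # lambda -> large with fixed Delta A drives k -> 0 past the turnover
  lams <- seq(0.7, 3, by = 0.1)
  kl <- vapply(lams, function(l) marcus_rate(0.1, l, 0.39)$k, numeric(1))
  expect_true(all(diff(kl) < 0))
})

test_that("initial-rate estimate is the same formula at the photoexcited ensemble", {
  relaxed <- marcus_rate(0.115, 0.66, 0.39)
  init <- initial_rate(0.115, 0.63, 0.39)
  # same order of magnitude as the relaxed rate
  expect_gt(init$k / relaxed$k, 0.5)
  expect_lt(init$k / relaxed$k, 2)
  expect_equal(initial_rate(0.115, 0.66, 0.39)$k, relaxed$k)
})

test_that("protein-pocket parameters suppress the rate by >= 6 orders of magnitude", {
  k_solvent <- marcus_rate(0.115, 0.66, 0.39)$k
  k_protein <- marcus_rate(0.115, 0.55, 0.84)$k
  expect_gte(log10(k_solvent / k_protein), 6)
})

test_that("orbital-energy decay constant follows sqrt(-2 eps) in atomic units", {
  expect_equal(round(coupling_decay_constant(-6.5), 1), 1.3)
  # hydrogen 1s: eps = -13.6057 eV = -0.5 Ha -> 1 bohr^-1
  expect_equal(coupling_decay_constant(-27.2114 / 2), 1 / 0.529177,
               tolerance = 1e-6)
  # doubling |eps| multiplies n by sqrt(2)
  expect_equal(coupling_decay_constant(-13) / coupling_decay_constant(-6.5),
               sqrt(2), tolerance = 1e-12)
  expect_error(coupling_decay_constant(0.5), "negative")
})

test_that("coupling decays by a factor ~13 per additional 2 Angstrom", {
  n <- round(coupling_decay_constant(-6.5), 1)   # 1.3, as quoted
  h10 <- coupling_at_distance(0.115, 10, n, 10)
  expect_equal(h10, 0.115)
  factor2A <- coupling_at_distance(0.115, 10, n, 10) /
    coupling_at_distance(0.115, 10, n, 12)
  expect_equal(round(factor2A), 13)
  # |H|^2 (hence k) falls by ~ two orders of magnitude per 2 Angstrom
  expect_equal(factor2A^2, exp(2 * n * 2), tolerance = 1e-12)
  expect_gt(log10(factor2A^2), 2)
})

test_that("rate-distance profile combines coupling decay with per-distance parameters", {
  n <- 1.3
  # constant Marcus parameters: consecutive ratio is exp(-2 n dR) in k
  tab <- data.frame(distance = c(8, 10, 12),
                    lambda_reorg = rep(0.66, 3), delta_A = rep(0.39, 3))
  prof <- rate_distance_profile(tab, 0.115, 10, n)
  expect_equal(prof$k_ns[1] / prof$k_ns[2], exp(2 * n * 2), tolerance = 1e-10)
  expect_equal(prof$k_ns[2] / prof$k_ns[3], exp(2 * n * 2), tolerance = 1e-10)
  # increasing lambda + Delta A (normal region): k strictly decreasing, and
  # each row equals an elementwise direct evaluation
  tab2 <- data.frame(distance = c(8, 10, 12, 14),
                     lambda_reorg = c(0.60, 0.66, 0.70, 0.72),
                     delta_A = c(0.33, 0.39, 0.43, 0.45))
  prof2 <- rate_distance_profile(tab2, 0.115, 10, n)
  direct <- mapply(function(H, l, d) marcus_rate(H, l, d)$k,
                   prof2$coupling, tab2$lambda_reorg, tab2$delta_A)
  expect_equal(prof2$k_ns, unname(direct), tolerance = 1e-12)
  expect_true(all(diff(prof2$k_ns) < 0))
  # single row reduces to marcus_rate at the reference coupling
  single <- rate_distance_profile(data.frame(distance = 10, lambda_reorg = 0.66,
                                             delta_A = 0.39), 0.115, 10, n)
  expect_equal(single$k_ns, marcus_rate(0.115, 0.66, 0.39)$k)
  # missing fields are reported with their location
  bad <- data.frame(distance = c(8, 10), lambda_reorg = c(0.6, NA),
                    delta_A = c(0.3, 0.4))
  expect_error(rate_distance_profile(bad, 0.115, 10, n), "row 2")
})

test_that("branching fraction quantifies the charge separation vs fluorescence race", {
  expect_equal(branching_fraction(0.2, 0.2), 0.5)
  expect_equal(branching_fraction(0.03, 0.2), 0.03 / 0.23, tolerance = 1e-12)
  expect_equal(branching_fraction(0.03, 0), 1.0)
  expect_error(branching_fraction(0, 0), "positive")
})

test_that("coupling selection policies pick max / mean / median", {
  h <- c(0.01, 0.115, 0.003)
  expect_equal(select_coupling(h), 0.115)
  expect_equal(select_coupling(h, "mean"), mean(h))
  expect_equal(select_coupling(h, "median"), 0.01)
})

test_that("rate envelope from a fitted model brackets the point rate", {
  fit <- fes_fit(generate_cs_trajectory(gap_model_spec(seed = 2)), "cs")
  kb <- marcus_rate_envelope(fit, 0.115)
  k <- marcus_rate(0.115, fit$pair$lambda_reorg, fit$pair$delta_A)$k
  expect_true(kb[1] <= k && k <= kb[2])
})
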