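test_that("gap-distribution fit is the ML normal fit with exact intervals", {
  f <- fit_gap_distribution(c(0, 1, 2))
  expect_equal(f$mu, 1.0)
  expect_equal(f$sigma, 1.0)  # sample SD, denominator n-1
  expect_true(f$mu_ci[1] <= f$mu && f$mu <= f$mu_ci[2])
  expect_true(f$sigma_ci[1] <= f$sigma && f$sigma <= f$sigma_ci[2])
  expect_error(fit_gap_distribution(c(1, 1, 1)), "variance")
  expect_error(fit_gap_distribution(c(1, 2)), "at least 3")
  expect_error(fit_gap_distribution(c(0, 1, NA)), "finite")
})

test_that("mean CI attains nominal coverage on Gaussian samples", {
  set.seed(42)
  covered <- vapply(1:100, function(i) {
    s <- rnorm(500, 0.27, 0.185)
    ci <- fit_gap_distribution(s)$mu_ci
    ci[1] <= 0.27 && 0.27 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)  # nominal 0.95, binomial slack
})

test_that("sampled surface is the linear-response parabola", {
  kT <- kT300
  # unit-variance reduction: mu = 0, sigma = sqrt(kT) gives V(x) = x^2/2
  V <- build_sampled_fes(list(mu = 0, sigma = sqrt(kT)), 300)
  xs <- seq(-1, 1, 0.25)
  expect_equal(predict(V, xs), xs^2 / 2, tolerance = 1e-12)
  # direct substitution at mu +/- sigma
  V2 <- build_sampled_fes(list(mu = 0.27, sigma = 0.1847), 300)
  expect_equal(predict(V2, 0.27 + 0.1847), kT / 2, tolerance = 1e-12)
  expect_equal(predict(V2, 0.27 - 0.1847), kT / 2, tolerance = 1e-12)
  expect_equal(unname(fes_minimum(V2)), c(0.27, 0), tolerance = 1e-12)
  # even about the minimum
  d <- runif(5)
  expect_equal(predict(V2, 0.27 + d), predict(V2, 0.27 - d), tolerance = 1e-12)
})

test_that("Boltzmann inversion is self-consistent: exp(-V/kT) is the fitted density", {
  set.seed(9)
  f <- fit_gap_distribution(rnorm(400, 0.3, 0.2))
  V <- build_sampled_fes(f, 300)
  grid <- seq(f$mu - 4 * f$sigma, f$mu + 4 * f$sigma, length.out = 201)
  # exp(-V/kT) with the Gaussian normalization constant is the fitted density
  p_fes <- exp(-predict(V, grid) / kT300) / (f$sigma * sqrt(2 * pi))
  p_norm <- dnorm(grid, f$mu, f$sigma)
  expect_equal(p_fes, p_norm, tolerance = 1e-12)
})

test_that("companion construction matches closed forms and a numerical oracle", {
  kT <- kT300
  mu <- 0.27; sigma <- 0.1847286
  cs <- build_sampled_fes(list(mu = mu, sigma = sigma, axis = "ES_minus_CS"), 300)
  es <- companion_surface(cs)
  # V_ES(x) = V_CS(x) + x pointwise
  xs <- seq(-2, 2, length.out = 21)
  expect_equal(predict(es, xs), predict(cs, xs) + xs, tolerance = 1e-12)
  pair <- summarize_surface_pair(es, cs)
  expect_equal(pair$lambda_reorg, sigma^2 / (2 * kT), tolerance = 1e-10)
  expect_equal(pair$delta_A, sigma^2 / (2 * kT) - mu, tolerance = 1e-10)
  # oracle: golden-section minimization of both surfaces
  m_es <- num_minimum(es, mu - 5, mu + 5)
  m_cs <- num_minimum(cs, mu - 5, mu + 5)
  expect_equal(unname(m_es["x"]), mu - sigma^2 / kT, tolerance = 1e-7)
  lambda_num <- predict(cs, m_es["x"]) - m_cs["V"]
  expect_equal(pair$lambda_reorg, unname(lambda_num), tolerance = 1e-10)
  dA_num <- m_cs["V"] - m_es["V"]
  expect_equal(pair$delta_A, unname(dA_num), tolerance = 1e-10)
  # reduced units (sigma^2 = kT => V_CS = x^2/2): ES minimum at -1, V = -1/2
  u <- companion_surface(build_sampled_fes(list(mu = 0, sigma = sqrt(kT),
                                                axis = "ES_minus_CS"), 300))
  expect_equal(unname(fes_minimum(u)), c(-1, -1 / 2), tolerance = 1e-12)
  expect_error(companion_surface(build_sampled_fes(
    list(mu = 0, sigma = 1, axis = "CS_minus_GS"), 300)), "axis")
})

test_that("linear gap relation fit handles exact, noisy and degenerate input", {
  x <- seq(0, 1, length.out = 10)
  rel <- suppressWarnings(fit_gap_relation(x, 2 * x))  # exact fit warns in summary.lm
  expect_equal(rel$slope_a, 2, tolerance = 1e-12)
  expect_equal(rel$intercept_b, 0, tolerance = 1e-12)
  expect_equal(rel$residual_sd, 0, tolerance = 1e-10)
  expect_error(fit_gap_relation(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(fit_gap_relation(1:5, 1:4), "equal length")
})

test_that("cross-fit surface matches closed forms and a numerical oracle", {
  kT <- kT300
  mu_x <- 3.32; sigma_x <- 0.3609; a <- -0.5; b <- 1.9
  cs <- build_sampled_fes(list(mu = mu_x, sigma = sigma_x, axis = "CS_minus_GS"), 300)
  rel <- structure(list(slope_a = a, intercept_b = b), class = "gap_relation")
  es <- crossfit_es_surface(cs, rel)
  xs <- seq(2, 5, length.out = 31)
  expect_equal(predict(es, xs), predict(cs, xs) + a * xs + b, tolerance = 1e-12)
  pair <- summarize_surface_pair(es, cs)
  expect_equal(unname(fes_minimum(es)["x"]), mu_x - a * sigma_x^2 / kT,
               tolerance = 1e-10)
  expect_equal(pair$lambda_reorg, a^2 * sigma_x^2 / (2 * kT), tolerance = 1e-10)
  expect_equal(pair$delta_A, a^2 * sigma_x^2 / (2 * kT) - a * mu_x - b,
               tolerance = 1e-10)
  m_es <- num_minimum(es, mu_x - 20, mu_x + 20)
  expect_equal(pair$lambda_reorg,
               unname(predict(cs, m_es["x"]) - fes_minimum(cs)["V"]),
               tolerance = 1e-8)
  # re-expression onto the ES-CS gap axis preserves surface values
  re <- es$reexpressed
  expect_false(es$reexpress_failed)
  expect_equal(predict(re, a * xs + b), predict(es, xs), tolerance = 1e-10)
})

test_that("zero-slope relation rigidly shifts the surface and flags re-expression", {
  cs <- build_sampled_fes(list(mu = 1, sigma = 0.2, axis = "CS_minus_GS"), 300)
  rel0 <- structure(list(slope_a = 0, intercept_b = 0.7), class = "gap_relation")
  es <- crossfit_es_surface(cs, rel0)
  expect_true(es$reexpress_failed)
  expect_null(es$reexpressed)
  pair <- summarize_surface_pair(es, cs)
  expect_equal(pair$lambda_reorg, 0, tolerance = 1e-12)
  expect_equal(pair$delta_A, -0.7, tolerance = 1e-12)
})

test_that("noiseless synthetic pipeline reproduces crossfit closed forms to 1e-10 eV", {
  spec <- gap_model_spec(resid_sd = 0, n_frames = 400, seed = 21)
  tab <- generate_gs_trajectory(spec)
  fit <- fes_fit(tab, "gs")
  kT <- kT300
  x <- tab$E_CS_eV - tab$E_GS_eV
  mu_x <- mean(x); s_x <- sd(x)
  expect_equal(fit$pair$lambda_reorg, spec$slope_a^2 * s_x^2 / (2 * kT),
               tolerance = 1e-10)
  expect_equal(fit$pair$delta_A,
               spec$slope_a^2 * s_x^2 / (2 * kT) - spec$slope_a * mu_x -
                 spec$intercept_b,
               tolerance = 1e-10)
})

test_that("surface-pair summary: crossing identity, degenerate cases, region", {
  kT <- kT300
  # equal-curvature surfaces: barrier is the Marcus activation energy
  sigma <- 0.18
  cs <- build_sampled_fes(list(mu = 0.3, sigma = sigma, axis = "ES_minus_CS"), 300)
  es <- companion_surface(cs)
  pair <- summarize_surface_pair(es, cs)
  lam <- pair$lambda_reorg; dA <- pair$delta_A
  expect_equal(pair$crossing_energy_above_ES_min, (lam + dA)^2 / (4 * lam),
               tolerance = 1e-10)
  # oracle: root of the difference by uniroot between the two minima
  m_es <- fes_minimum(es); m_cs <- fes_minimum(cs)
  root <- uniroot(function(x) predict(es, x) - predict(cs, x),
                  sort(c(m_es["x"], m_cs["x"])), tol = 1e-13)$root
  expect_equal(pair$crossing_x, root, tolerance = 1e-8)
  # identical surfaces: everything zero
  same <- summarize_surface_pair(cs, cs)
  expect_equal(same$delta_A, 0)
  expect_equal(same$lambda_reorg, 0)
  expect_equal(same$crossing_energy_above_ES_min, 0)
  # inverted region flag: -delta_A > lambda needs mu > 2 lambda (strongly
  # downhill charge separation)
  cs2 <- build_sampled_fes(list(mu = 2.0, sigma = sigma, axis = "ES_minus_CS"), 300)
  pair2 <- summarize_surface_pair(companion_surface(cs2), cs2)
  expect_true(-pair2$delta_A > pair2$lambda_reorg)
  expect_equal(pair2$marcus_region, "inverted")
  expect_error(summarize_surface_pair(
    es, build_sampled_fes(list(mu = 0, sigma = 1, axis = "CS_minus_GS"), 300)),
    "axis")
})

test_that("companion and cross-fit constructions agree on self-consistent data", {
  # a generator whose CS-trajectory and GS-trajectory parameter sets encode
  # the same surfaces yields matching lambda estimates from both routes
  spec <- gap_model_spec(n_frames = 2000, seed = 31, resid_sd = 0.005)
  fit_cs <- fes_fit(generate_cs_trajectory(spec), "cs")
  fit_gs <- fes_fit(generate_gs_trajectory(spec), "gs")
  kT <- kT300
  lambda_cs_true <- spec$sigma_cs^2 / (2 * kT)
  lambda_gs_true <- spec$slope_a^2 * spec$sigma_gs_axis^2 / (2 * kT)
  expect_lt(abs(fit_cs$pair$lambda_reorg - lambda_cs_true), 0.05)
  expect_lt(abs(fit_gs$pair$lambda_reorg - lambda_gs_true), 0.05)
  # the two constructions describe the relaxed vs initial ensembles, whose
  # reorganization energies differ by < 0.05 eV under the default model
  expect_lt(abs(fit_cs$pair$lambda_reorg - fit_gs$pair$lambda_reorg), 0.1)
})

test_that("corner-scan uncertainty propagation matches closed forms", {
  # identity evaluator returns the parameter's own CI
  env <- propagate_uncertainty(list(p = list(point = 2, ci = c(1, 4))),
                               function(p) p)
  expect_equal(c(env$lower, env$upper), c(1, 4))
  # monotone evaluator attains the envelope at the endpoints
  env2 <- propagate_uncertainty(list(p = list(point = 2, ci = c(1, 4))),
                                function(p) exp(p))
  expect_equal(c(env2$lower, env2$upper), exp(c(1, 4)))
  # lambda envelope from the sigma CI
  kT <- kT300
  env3 <- propagate_uncertainty(
    list(sigma = list(point = 0.18, ci = c(0.17, 0.20))),
    function(sigma) sigma^2 / (2 * kT))
  expect_equal(c(env3$lower, env3$upper), c(0.17, 0.20)^2 / (2 * kT),
               tolerance = 1e-12)
  # a failing corner is flagged, not dropped silently
  env4 <- propagate_uncertainty(
    list(p = list(point = 1, ci = c(-1, 2))),
    function(p) { if (p < 0) stop("negative"); sqrt(p) })
  expect_length(env4$failed, 1L)
  expect_match(env4$failed, "negative")
  # envelope over the corners that did evaluate: sqrt(1), sqrt(2)
  expect_equal(c(env4$lower, env4$upper), c(1, sqrt(2)), tolerance = 1e-12)
  expect_error(propagate_uncertainty(list(p = list(point = 5, ci = c(1, 2))),
                                     identity), "bracket")
})
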