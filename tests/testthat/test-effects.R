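test_that("simulate_mediators obeys its limits and closed forms", {
  cf0 <- mediation_coefficients(
    alpha_L = 2, beta_L = -1, sigma_L = 1e-12,
    alpha_T = 1, beta_T = 0.5, gamma_T = 0.3, sigma_T = 1e-12
  )
  med <- simulate_mediators(cf0, a_L = 1, a_T = 1, K = 5, seed = 1)
  expect_equal(med$LD, rep(1, 5), tolerance = 1e-9)
  expect_equal(med$TD, rep(1 + 0.5 + 0.3 * 1, 5), tolerance = 1e-9)

  cf <- mediation_coefficients(
    alpha_L = 2, beta_L = 0, sigma_L = 1,
    alpha_T = 1, beta_T = 0.5, gamma_T = 0.3, sigma_T = 0.8
  )
  z <- stratmed:::crn_matrix(1000, seed = 2)
  m1 <- simulate_mediators(cf, a_L = 1, a_T = 0, K = 1000, z = z)
  m0 <- simulate_mediators(cf, a_L = 0, a_T = 0, K = 1000, z = z)
  expect_identical(m1$LD, m0$LD) # beta_L = 0 with common random numbers

  cf2 <- default_true_coefficients()
  big <- simulate_mediators(cf2, a_L = 1, a_T = 1, K = 1e6, seed = 3)
  expect_equal(mean(big$LD), cf2$alpha_L + cf2$beta_L, tolerance = 5e-3)
  expect_equal(
    mean(big$TD),
    cf2$alpha_T + cf2$beta_T + cf2$gamma_T * (cf2$alpha_L + cf2$beta_L),
    tolerance = 5e-3
  )
})

test_that("expected_canopy handles degenerate settings exactly", {
  s <- counterfactual_setting(1, 1, 1, 1, 1)
  expect_equal(expected_canopy(mediation_coefficients(), s, K = 10, seed = 1), 0.5)
  cf <- mediation_coefficients(alpha_C = 0.4, beta_C = -1)
  expect_equal(
    expected_canopy(cf, s, K = 10, seed = 1),
    plogis(0.4 - 1),
    tolerance = 1e-12
  )
  s0 <- counterfactual_setting(0, 0, 0, 0, 0)
  expect_equal(expected_canopy(cf, s0, K = 10, seed = 1), plogis(0.4), tolerance = 1e-12)
  expect_error(counterfactual_setting(1, 1, 1, 1), "a_F")
  expect_error(counterfactual_setting(1, 1, 1, 1, 2), "0 or 1")
})

test_that("Monte Carlo expectations agree with the quadrature route", {
  cf <- default_true_coefficients()
  z <- stratmed:::crn_matrix(2e5, seed = 4)
  for (s in stratmed:::telescope_settings()) {
    m <- cf$alpha_C + cf$beta_C * s$a +
      cf$lambda * (cf$alpha_L + cf$beta_L * s$a_L) +
      cf$tau * (cf$alpha_T + cf$beta_T * s$a_T +
        cf$gamma_T * (cf$alpha_L + cf$beta_L * s$a_TL)) +
      cf$phi * (cf$alpha_F + cf$beta_F * s$a_F)
    v <- (cf$lambda + cf$tau * cf$gamma_T)^2 * cf$sigma_L^2 +
      cf$tau^2 * cf$sigma_T^2 + cf$phi^2 * cf$sigma_F^2
    quad <- integrate(function(u) plogis(m + sqrt(v) * u) * dnorm(u), -Inf, Inf)$value
    expect_equal(expected_canopy(cf, s, z = z), quad, tolerance = 1e-3)
  }
})

test_that("per-draw telescoping additivity and the edge identity are exact", {
  set.seed(6)
  for (i in 1:10) {
    cf <- mediation_coefficients(
      alpha_L = rnorm(1, 4), beta_L = rnorm(1), sigma_L = runif(1, 0.3, 2),
      alpha_T = rnorm(1, 1), beta_T = rnorm(1, 0, 0.5),
      gamma_T = rnorm(1, 0, 0.3), sigma_T = runif(1, 0.3, 1.5),
      alpha_F = rnorm(1), beta_F = rnorm(1, 0, 0.6), sigma_F = runif(1, 0.3, 2),
      alpha_C = rnorm(1), beta_C = rnorm(1), lambda = rnorm(1, 0, 0.2),
      tau = rnorm(1, 0, 0.2), phi = rnorm(1, 0, 1)
    )
    eff <- effect_decomposition(cf, K = 200, seed = i)
    g <- glance(eff)
    expect_lt(g$additivity_max_error, 1e-12)
    expect_lt(g$edge_identity_max_error, 1e-12)
    expect_true(all(abs(as.matrix(eff$draws)) <= 1))
  }
})

test_that("a null structural model yields exactly null effects", {
  cf <- mediation_coefficients(
    alpha_L = 4, sigma_L = 1, alpha_T = 1, gamma_T = 0.2, sigma_T = 0.8,
    alpha_F = 0, sigma_F = 1, alpha_C = -0.2, lambda = 0.05, tau = -0.05, phi = 0.8
  )
  eff <- effect_decomposition(cf, K = 500, seed = 2)
  expect_true(all(abs(as.matrix(eff$draws)) < 1e-12))
  expect_true(all(abs(as.numeric(effects_quadrature(cf)[1, ])) < 1e-10))
})

test_that("a composition-only model moves only the composition effect", {
  cf <- mediation_coefficients(
    alpha_L = 4, sigma_L = 1, alpha_T = 1, gamma_T = 0.2, sigma_T = 0.8,
    alpha_F = -0.3, beta_F = 1, sigma_F = 1,
    alpha_C = -0.2, phi = 0.9
  )
  quad <- effects_quadrature(cf)
  expect_equal(quad$light_effect, 0, tolerance = 1e-12)
  expect_equal(quad$temperature_effect, 0, tolerance = 1e-12)
  expect_equal(quad$nde, 0, tolerance = 1e-12)
  expect_gt(quad$sce, 0.05)
  mc <- oracle_effects(cf, K = 1e6, seed = 5)
  expect_equal(mc$sce, quad$sce, tolerance = 1e-3)
  expect_equal(quad$edge_effect, 0, tolerance = 1e-12)
})

test_that("oracle effects are Monte Carlo stable and match quadrature", {
  cf <- default_true_coefficients()
  o1 <- oracle_effects(cf, K = 1e6, seed = 1)
  o2 <- oracle_effects(cf, K = 1e6, seed = 2)
  quad <- effects_quadrature(cf)
  for (e in names(o1)) {
    expect_equal(o1[[e]], o2[[e]], tolerance = 1.5e-3)
    expect_equal(o1[[e]], quad[[e]], tolerance = 1e-3)
  }
})

test_that("Monte Carlo error shrinks like one over root K", {
  cf <- default_true_coefficients()
  sce_sd <- vapply(c(100, 10000), function(K) {
    reps <- vapply(1:30, function(r) {
      effect_decomposition(cf, K = K, seed = 1000 + r)$draws$sce
    }, 0)
    sd(reps)
  }, 0)
  ratio <- sce_sd[1] / sce_sd[2]
  # K grows 100-fold: sd should shrink about 10-fold
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
})
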