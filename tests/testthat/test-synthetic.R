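test_that("the generator is byte-deterministic given the seed", {
  cfg <- sim_config(n_days = 4)
  d1 <- tempfile()
  d2 <- tempfile()
  d3 <- tempfile()
  write_sim_study(sim_study(cfg, seed = 5), d1)
  write_sim_study(sim_study(cfg, seed = 5), d2)
  write_sim_study(sim_study(cfg, seed = 6), d3)
  for (f in c("captures.csv", "loggers.csv", "sites.csv", "fct_priors.csv")) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = paste("same-seed", f)
    )
  }
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "captures.csv"))),
    unname(tools::md5sum(file.path(d3, "captures.csv")))
  ))
  expect_error(sim_study(cfg), "seed is mandatory")
})

test_that("noise-free, gap-free loggers equal the deterministic diurnal curves", {
  cfg <- sim_config(
    n_days = 2,
    sigma_proc = c(temperature_C = 1e-9, log_light = 1e-9),
    sigma_obs = c(temperature_C = 1e-9, log_light = 1e-9),
    missingness = list(logger_mcar = 0, logger_mar_first_half = 0, fct_missing = 0)
  )
  ab <- sim_abiotic(cfg, seed = 2)
  temp <- dplyr::filter(ab$loggers, .data$variable == "temperature_C") |>
    dplyr::left_join(dplyr::select(ab$sites, "site_id", "habitat"), by = "site_id") |>
    dplyr::mutate(hour = stratmed:::hour_of(.data$timestamp))
  truth <- mapply(function(h, s, hr) {
    stratmed:::diurnal_baseline(cfg$curves, h, s, "temperature_C", hr)
  }, temp$habitat, temp$stratum, temp$hour)
  expect_equal(temp$value, unname(truth), tolerance = 1e-6)
})

test_that("injected gaps match the configured missingness rate", {
  cfg_full <- sim_config(
    n_days = 10,
    missingness = list(logger_mcar = 0, logger_mar_first_half = 0, fct_missing = 0)
  )
  cfg_gap <- sim_config(
    n_days = 10,
    missingness = list(logger_mcar = 0.2, logger_mar_first_half = 0, fct_missing = 0)
  )
  n_full <- nrow(sim_abiotic(cfg_full, seed = 3)$loggers)
  n_gap <- nrow(sim_abiotic(cfg_gap, seed = 3)$loggers)
  frac <- n_gap / n_full
  tol <- 3 * sqrt(0.2 * 0.8 / n_full)
  expect_lt(abs(frac - 0.8), tol + 0.005)
})

test_that("early-study logger shortage raises first-half missingness", {
  cfg <- sim_config(
    n_days = 10,
    missingness = list(logger_mcar = 0.05, logger_mar_first_half = 0.3, fct_missing = 0)
  )
  logs <- sim_abiotic(cfg, seed = 4)$loggers
  day <- as.integer(as.Date(logs$timestamp) - as.Date("2015-06-01")) + 1
  n_first <- sum(day <= 5)
  n_second <- sum(day > 5)
  expect_lt(n_first, 0.85 * n_second)
})

test_that("the edge understory microclimate resembles the forest canopy", {
  ab <- sim_abiotic(sim_config(n_days = 10), seed = 8)
  hs <- suppressMessages(hourly_summary(ab$loggers, ab$sites))
  day <- dplyr::filter(hs, .data$variable == "log_light", .data$hour %in% 9:15)
  agg <- day |>
    dplyr::group_by(.data$habitat, .data$stratum) |>
    dplyr::summarise(m = mean(.data$mean), .groups = "drop")
  val <- function(h, s) agg$m[agg$habitat == h & agg$stratum == s]
  eu <- val("edge", "understory")
  expect_lt(abs(eu - val("ridge", "canopy")), abs(eu - val("ridge", "understory")))
})

test_that("null outcome coefficients give a half-and-half stratum split", {
  cfg <- sim_config(
    n_days = 15,
    coefficients = mediation_coefficients(
      alpha_L = 4, beta_L = -3, sigma_L = 1, alpha_T = 1, beta_T = 0.5,
      gamma_T = 0.2, sigma_T = 0.8, alpha_F = 0, beta_F = 0, sigma_F = 1
    )
  )
  study <- sim_study(cfg, seed = 9)
  n <- nrow(study$captures)
  frac <- mean(study$captures$stratum == "canopy")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("species tendencies drive strata when only phi is active", {
  cfg <- sim_config(
    n_days = 15, capture_rate = 2,
    coefficients = mediation_coefficients(
      alpha_L = 4, beta_L = -3, sigma_L = 1, alpha_T = 1, beta_T = 0.5,
      gamma_T = 0.2, sigma_T = 0.8, alpha_F = 0, beta_F = 0.8, sigma_F = 1.2,
      phi = 1.5
    )
  )
  study <- sim_study(cfg, seed = 10)
  caps <- dplyr::left_join(
    study$captures,
    dplyr::select(study$truth$species, "species", "fct_true"),
    by = "species"
  )
  by_sp <- caps |>
    dplyr::group_by(.data$species, .data$fct_true) |>
    dplyr::summarise(
      n = dplyr::n(), canopy = mean(.data$stratum == "canopy"), .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 40)
  expect_gt(nrow(by_sp), 2)
  pred <- plogis(1.5 * by_sp$fct_true)
  tol <- 3 * sqrt(pred * (1 - pred) / by_sp$n) + 0.02
  expect_true(all(abs(by_sp$canopy - pred) <= tol))
})

test_that("defaults land at the emulated study's scale", {
  study <- sim_study(sim_config(), seed = 1)
  expect_gt(nrow(study$captures), 550)
  expect_lt(nrow(study$captures), 880)
  n_sp <- length(unique(study$captures$species))
  expect_gt(n_sp, 70)
  expect_lt(n_sp, 112)
  expect_equal(length(unique(study$captures$tribe)), 12)
  expect_equal(nrow(study$sites), 32)
  expect_equal(
    as.integer(table(study$sites$habitat)[c("edge", "ridge", "valley")]),
    c(10L, 12L, 10L)
  )
})

test_that("null count generator is valid and nearly tie-free", {
  counts <- sim_null_counts(500, seed = 12)
  expect_true(all(counts[, c("EC", "EU", "FC", "FU")] >= 0))
  d <- delta_edge(counts)
  expect_lt(mean(d$delta_edge == 0), 0.05)
  # sign symmetric about zero under the null
  expect_lt(abs(mean(d$delta_edge > 0) - mean(d$delta_edge < 0)), 0.12)
})
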