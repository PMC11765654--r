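test_that("with tiny fixed observation noise the states follow the data", {
  pair <- sim_ar1_pair(
    n_days = 4, rho = 0.7, sd_proc = 0.5, sd_obs = 0.05, seed = 3
  )
  fit <- fit_abiotic_states(pair$loggers, pair$sites,
    config = sampler_config(seed = 5, adapt = 300, warmup = 300, draws = 500),
    sd_obs_fixed = 0.05
  )
  st <- dplyr::filter(fit$states, .data$stratum == "canopy",
    .data$variable == "temperature_C")
  err <- abs(st$mean - pair$canopy$y)
  expect_gt(mean(err <= 2 * 0.05), 0.95)
})

test_that("a single missing hour is imputed near the Gaussian-bridge mean", {
  pair <- sim_ar1_pair(
    n_days = 6, rho = 0.7, sd_proc = 0.4, sd_obs = 0.2, seed = 11
  )
  y <- pair$canopy$y
  hole <- 70 # interior hour
  y_mis <- y
  y_mis[hole] <- NA
  loggers <- dplyr::filter(
    pair$loggers,
    !(.data$stratum == "canopy" & .data$timestamp == pair$stamps[hole])
  )
  fit <- fit_abiotic_states(loggers, pair$sites,
    config = sampler_config(seed = 6, adapt = 400, warmup = 400, draws = 800)
  )
  st <- dplyr::filter(fit$states, .data$stratum == "canopy",
    .data$variable == "temperature_C")
  oracle <- ar1_smoother_oracle(
    y_mis, pair$canopy$baseline,
    rho = 0.7, sd_proc = 0.4, sd_obs = 0.2, sd0 = 0.4 / sqrt(1 - 0.7^2)
  )
  expect_lt(abs(st$mean[hole] - oracle[hole]), 0.35)
})

test_that("posterior contrasts match attached observed contrasts and cover
           never-instrumented sites", {
  pair <- sim_ar1_pair(
    n_days = 4, rho = 0.7, sd_proc = 0.5, sd_obs = 0.1, seed = 9
  )
  fit <- fit_abiotic_states(pair$loggers, pair$sites,
    config = sampler_config(seed = 7, adapt = 300, warmup = 300, draws = 500)
  )
  # site S99 never carried a logger but shares the ridge habitat series
  caps <- tibble::tibble(
    individual_id = c("i1", "i2"),
    timestamp = pair$stamps[c(30, 40)],
    site_id = c("S01", "S99"), habitat = "ridge",
    stratum = "canopy", species = "A a", tribe = "T1"
  )
  imp <- impute_LD_TD(fit, caps)
  truth_td <- pair$canopy$x[c(30, 40)] - pair$understory$x[c(30, 40)]
  expect_equal(imp$TD, truth_td, tolerance = 0.5)
  expect_true(all(imp$TD_sd > 0))
  # observed-hour contrast agrees with direct attachment up to observation noise
  obs <- suppressWarnings( # the light contrast is absent from this fixture
    attach_abiotic(caps[1, ], abiotic_series(pair$loggers, pair$sites))
  )
  expect_equal(imp$TD[1], obs$TD[1], tolerance = 3 * 0.1 * sqrt(2))
})

test_that("doubling the mean-level prior sd barely moves the contrasts", {
  set.seed(21)
  n_days <- 12
  Tn <- n_days * 24
  hod <- (seq_len(Tn) - 1) %% 24
  stamps <- as.POSIXct("2015-06-01", tz = "UTC") + (seq_len(Tn) - 1) * 3600
  sites <- tibble::tibble(
    site_id = "S01", habitat = "ridge",
    canopy_height_m = 22, understory_height_m = 1
  )
  make_series <- function(level, amp) {
    b <- level + amp * cos(2 * pi * (hod - 12) / 24)
    d <- stats::filter(rnorm(Tn, 0, 0.5), 0.7, method = "recursive")
    exp(pmax(b + as.numeric(d), 0)) - 1
  }
  loggers <- dplyr::bind_rows(
    tibble::tibble(
      timestamp = stamps, site_id = "S01", stratum = "canopy",
      variable = "light_lux", value = make_series(4, 4)
    ),
    tibble::tibble(
      timestamp = stamps, site_id = "S01", stratum = "understory",
      variable = "light_lux", value = make_series(1.5, 1.5)
    )
  )
  sc <- sampler_config(seed = 4, adapt = 300, warmup = 300, draws = 500)
  fit1 <- fit_abiotic_states(loggers, sites, priors = abiotic_priors(), config = sc)
  fit2 <- fit_abiotic_states(loggers, sites,
    priors = abiotic_priors(log_light_sd = 6), config = sc
  )
  mean_ld <- function(fit) {
    wide <- tidyr::pivot_wider(
      dplyr::select(
        dplyr::filter(fit$states, .data$variable == "log_light"),
        "stratum", "t", "mean"
      ),
      names_from = "stratum", values_from = "mean"
    )
    mean(wide$canopy - wide$understory)
  }
  expect_lt(abs(mean_ld(fit1) - mean_ld(fit2)), 0.1)
})
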