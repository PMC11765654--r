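# Independent oracles used to cross-check the package implementations.

# Likelihood-ratio sign-test statistic via binomial log-likelihoods
# (saturated vs null), an independent route to the O*ln(O/E) sum.
g_oracle <- function(k, n) {
  ll_sat <- dbinom(k, n, k / n, log = TRUE)
  ll_null <- dbinom(k, n, 0.5, log = TRUE)
  G <- 2 * (ll_sat - ll_null)
  list(G = G, p = pchisq(G, df = 1, lower.tail = FALSE))
}

# Exact Gaussian-conditioning smoother for a harmonic-baseline AR(1) series
# observed with Gaussian noise: posterior mean of the latent states given the
# observed values, at the true parameters. `sd0` is the sd of the initial
# deviation from baseline.
ar1_smoother_oracle <- function(y, baseline, rho, sd_proc, sd_obs, sd0) {
  Tn <- length(y)
  V <- numeric(Tn)
  V[1] <- sd0^2
  for (t in 2:Tn) V[t] <- rho^2 * V[t - 1] + sd_proc^2
  S <- matrix(0, Tn, Tn)
  for (u in 1:Tn) {
    S[u, u:Tn] <- V[u] * rho^(0:(Tn - u))
    S[u:Tn, u] <- S[u, u:Tn]
  }
  obs <- which(!is.na(y))
  So <- S[obs, obs, drop = FALSE] + diag(sd_obs^2, length(obs))
  w <- solve(So, y[obs] - baseline[obs])
  as.numeric(baseline + S[, obs, drop = FALSE] %*% w)
}

# Simulate one harmonic-AR(1) temperature pair (canopy/understory, one site)
# with known parameters; returns loggers/sites plus the latent truth.
sim_ar1_pair <- function(n_days, rho, sd_proc, sd_obs, seed,
                         miss_frac = 0, level = c(26, 24), amp = c(3, 1.2)) {
  set.seed(seed)
  Tn <- n_days * 24
  hod <- (seq_len(Tn) - 1) %% 24
  stamps <- as.POSIXct("2015-06-01", tz = "UTC") + (seq_len(Tn) - 1) * 3600
  sites <- tibble::tibble(
    site_id = "S01", habitat = "ridge",
    canopy_height_m = 22, understory_height_m = 1
  )
  out <- lapply(1:2, function(s) {
    b <- level[s] + amp[s] * cos(2 * pi * (hod - 14) / 24)
    d <- numeric(Tn)
    d[1] <- rnorm(1, 0, sd_proc / sqrt(1 - rho^2))
    for (t in 2:Tn) d[t] <- rho * d[t - 1] + rnorm(1, 0, sd_proc)
    x <- b + d
    y <- x + rnorm(Tn, 0, sd_obs)
    miss <- runif(Tn) < miss_frac
    list(baseline = b, x = x, y = y, miss = miss)
  })
  loggers <- dplyr::bind_rows(
    tibble::tibble(
      timestamp = stamps[!out[[1]]$miss], site_id = "S01", stratum = "canopy",
      variable = "temperature_C", value = out[[1]]$y[!out[[1]]$miss]
    ),
    tibble::tibble(
      timestamp = stamps[!out[[2]]$miss], site_id = "S01", stratum = "understory",
      variable = "temperature_C", value = out[[2]]$y[!out[[2]]$miss]
    )
  )
  list(
    loggers = loggers, sites = sites, stamps = stamps,
    canopy = out[[1]], understory = out[[2]]
  )
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_mediation(...)))
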