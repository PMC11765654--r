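#' Priors for the abiotic state-space model
#'
#' Broad, informative priors for the per-series mean levels. Temperature
#' priors are centred on typical lowland wet-forest values; log-light priors
#' differ by stratum (the canopy is brighter) and are broad. These are package
#' defaults, configurable per analysis.
#'
#' @param temperature_mean,temperature_sd Prior mean/sd for mean temperature
#'   (degrees C) of every temperature series.
#' @param log_light_canopy_mean,log_light_understory_mean Prior means for mean
#'   log-light by stratum.
#' @param log_light_sd Prior sd for mean log-light.
#' @return A list of class `abiotic_priors`.
#' @export
abiotic_priors <- function(temperature_mean = 25, temperature_sd = 5,
                           log_light_canopy_mean = 6,
                           log_light_understory_mean = 2,
                           log_light_sd = 3) {
  stopifnot(temperature_sd > 0, log_light_sd > 0)
  structure(
    list(
      temperature_mean = temperature_mean, temperature_sd = temperature_sd,
      log_light_canopy_mean = log_light_canopy_mean,
      log_light_understory_mean = log_light_understory_mean,
      log_light_sd = log_light_sd
    ),
    class = "abiotic_priors"
  )
}

# The 12 habitat x stratum x variable series, with their mean-level priors.
series_table <- function(priors, habitats = HABITATS) {
  grid <- tidyr::expand_grid(
    habitat = habitats, stratum = STRATA, variable = ABIOTIC_VARIABLES
  )
  dplyr::mutate(
    grid,
    series = dplyr::row_number(),
    prior_mean = ifelse(.data$variable == "temperature_C",
      priors$temperature_mean,
      ifelse(.data$stratum == "canopy",
        priors$log_light_canopy_mean, priors$log_light_understory_mean
      )
    ),
    prior_sd = ifelse(.data$variable == "temperature_C",
      priors$temperature_sd, priors$log_light_sd
    )
  )
}

#' Build the abiotic state-space model block
#'
#' Assembles everything needed to model the hourly habitat-stratum abiotic
#' series jointly: one latent series per habitat x stratum x variable
#' combination (12 when all three habitats are instrumented), each following
#' an hour-of-day harmonic baseline (first and second harmonics) plus AR(1)
#' deviations, observed through logger records with Gaussian noise. Loggers
#' from all sites of one habitat-stratum pair inform the same shared series,
#' which is what makes captures at never-instrumented sites imputable. Hours
#' with no record simply carry latent states with no likelihood term.
#'
#' @param loggers Logger records (see [read_loggers()]).
#' @param sites Site table.
#' @param priors An [abiotic_priors()] object.
#' @param offset Light log-transform offset.
#' @param grid_span Optional POSIXct length-2 vector forcing the hourly grid
#'   to span at least this range (used when captures extend past the loggers).
#' @return A list of class `state_space_spec`: `series` (series table), `grid`
#'   (hourly timestamps), `obs` (observation table with series/time indices),
#'   and the JAGS data for the block.
#' @export
build_state_space <- function(loggers, sites, priors = abiotic_priors(),
                              offset = 1, grid_span = NULL) {
  obs <- abiotic_series(loggers, sites, offset = offset)
  ser <- series_table(priors, habitats = sort(unique(sites$habitat)))
  span <- range(obs$timestamp)
  if (!is.null(grid_span)) {
    span <- range(c(span, floor_hour(grid_span)))
  }
  grid <- seq(span[1], span[2], by = 3600)
  obs <- obs |>
    dplyr::inner_join(
      dplyr::select(ser, "habitat", "stratum", "variable", "series"),
      by = c("habitat", "stratum", "variable")
    ) |>
    dplyr::mutate(t = match(.data$timestamp, grid))
  if (any(is.na(obs$series)) || any(is.na(obs$t))) {
    abort("logger record maps to no modelled series or grid hour")
  }
  hour <- hour_of(grid)
  structure(
    list(
      series = ser, grid = grid, obs = obs, priors = priors,
      jags_data = list(
        S = nrow(ser), Tn = length(grid), N_obs = nrow(obs),
        y = obs$value, ser = obs$series, tt = obs$t,
        c1 = cos(2 * pi * hour / 24), s1 = sin(2 * pi * hour / 24),
        c2 = cos(4 * pi * hour / 24), s2 = sin(4 * pi * hour / 24),
        prior_mean = ser$prior_mean, prior_sd = ser$prior_sd
      )
    ),
    class = "state_space_spec"
  )
}

state_space_code <- function() {
  "
  for (s in 1:S) {
    b[s, 1] <- mu_s[s] + A1[s] * c1[1] + B1[s] * s1[1] + A2[s] * c2[1] + B2[s] * s2[1]
    x[s, 1] ~ dnorm(b[s, 1], pow(3 * sd_proc[s], -2))
    for (t in 2:Tn) {
      b[s, t] <- mu_s[s] + A1[s] * c1[t] + B1[s] * s1[t] + A2[s] * c2[t] + B2[s] * s2[t]
      x[s, t] ~ dnorm(b[s, t] + rho[s] * (x[s, t - 1] - b[s, t - 1]), prec_proc[s])
    }
    mu_s[s] ~ dnorm(prior_mean[s], pow(prior_sd[s], -2))
    A1[s] ~ dnorm(0, 0.01)
    B1[s] ~ dnorm(0, 0.01)
    A2[s] ~ dnorm(0, 0.01)
    B2[s] ~ dnorm(0, 0.01)
    rho[s] ~ dunif(-0.999, 0.999)
    sd_proc[s] ~ dunif(0.001, 50)
    sd_obs[s] ~ dunif(0.001, 50)
    prec_proc[s] <- pow(sd_proc[s], -2)
    prec_obs[s] <- pow(sd_obs[s], -2)
  }
  for (k in 1:N_obs) {
    y[k] ~ dnorm(x[ser[k], tt[k]], prec_obs[ser[k]])
  }
"
}

#' Fit the abiotic state-space model
#'
#' Fits the model assembled by [build_state_space()] by MCMC and returns
#' posterior summaries of every latent series-hour, so that missing logger
#' hours are imputed as parameters of the posterior.
#'
#' @param loggers,sites,priors,offset,grid_span Passed to [build_state_space()],
#'   or give `spec` directly.
#' @param spec A prebuilt `state_space_spec` (overrides the raw inputs).
#' @param config A [sampler_config()].
#' @param sd_obs_fixed Optional fixed observation sd (used by degenerate-noise
#'   checks); `NULL` estimates it.
#' @return An object of class `abiotic_fit`: `states` (tibble with posterior
#'   mean/sd per series-hour), `params` (parameter draws), `diagnostics`,
#'   `converged`, and the state draws matrix needed by [impute_LD_TD()].
#' @export
fit_abiotic_states <- function(loggers = NULL, sites = NULL,
                               priors = abiotic_priors(), offset = 1,
                               grid_span = NULL, spec = NULL,
                               config = sampler_config(),
                               sd_obs_fixed = NULL) {
  spec <- spec %||% build_state_space(loggers, sites, priors, offset, grid_span)
  code <- state_space_code()
  jd <- spec$jags_data
  if (!is.null(sd_obs_fixed)) {
    stopifnot(sd_obs_fixed > 0)
    code <- sub("sd_obs\\[s\\] ~ dunif\\(0.001, 50\\)", "sd_obs[s] <- sd_obs_fix", code)
    jd$sd_obs_fix <- sd_obs_fixed
  }
  code <- paste0("model {\n", code, "}\n")
  param_monitors <- c("mu_s", "A1", "B1", "A2", "B2", "rho", "sd_proc",
    if (is.null(sd_obs_fixed)) "sd_obs")
  samples <- run_jags(code, jd, c(param_monitors, "x"), config)
  m <- as.matrix(samples[[1]])
  all_mat <- do.call(rbind, lapply(samples, as.matrix))
  xcols <- grep("^x\\[", colnames(all_mat), value = TRUE)
  pcols <- setdiff(colnames(all_mat), xcols)
  idx <- regmatches(xcols, regexec("^x\\[(\\d+),(\\d+)\\]$", xcols))
  s_i <- as.integer(vapply(idx, `[`, "", 2))
  t_i <- as.integer(vapply(idx, `[`, "", 3))
  xmean <- colMeans(all_mat[, xcols, drop = FALSE])
  xsd <- apply(all_mat[, xcols, drop = FALSE], 2, sd)
  states <- tibble::tibble(
    series = s_i, t = t_i,
    timestamp = spec$grid[t_i],
    mean = unname(xmean), sd = unname(xsd)
  ) |>
    dplyr::left_join(
      dplyr::select(spec$series, "series", "habitat", "stratum", "variable"),
      by = "series"
    ) |>
    dplyr::arrange(.data$series, .data$t)
  diag <- mcmc_diagnostics(samples, pcols)
  structure(
    list(
      spec = spec,
      states = states,
      params = draws_tibble(samples[, pcols, drop = FALSE]),
      x_draws = all_mat[, xcols, drop = FALSE],
      x_index = tibble::tibble(col = xcols, series = s_i, t = t_i),
      diagnostics = diag,
      converged = all(diag$rhat <= config$rhat_max),
      config = config
    ),
    class = "abiotic_fit"
  )
}

#' @export
print.abiotic_fit <- function(x, ...) {
  cat(
    "Abiotic state-space fit:", max(x$spec$jags_data$S), "series x",
    x$spec$jags_data$Tn, "hours;", x$spec$jags_data$N_obs, "observed values\n"
  )
  cat(
    "  max split R-hat:", round(max(x$diagnostics$rhat), 4),
    "| converged:", x$converged, "\n"
  )
  invisible(x)
}

#' Posterior abiotic contrasts for captures
#'
#' For every capture, forms the canopy-minus-understory light and temperature
#' contrasts of the capture's habitat at the capture hour from the latent
#' states, per posterior draw. All captures are resolvable by construction,
#' including captures at sites that never carried a logger (their habitat's
#' shared series is used).
#'
#' @param fit An [fit_abiotic_states()] result.
#' @param captures Capture records.
#' @return `captures` with posterior-mean `LD`, `TD` and posterior sds
#'   `LD_sd`, `TD_sd`; the per-draw contrast matrices are attached as the
#'   `"draws"` attribute (columns = captures).
#' @export
impute_LD_TD <- function(fit, captures) {
  stopifnot(inherits(fit, "abiotic_fit"))
  assert_columns(captures, c("timestamp", "habitat"), "captures")
  grid <- fit$spec$grid
  tcap <- match(floor_hour(captures$timestamp), grid)
  if (any(is.na(tcap))) {
    abort("capture hour outside the fitted state-space grid")
  }
  ser <- fit$spec$series
  lookup <- function(hab, stratum, variable) {
    key <- paste(ser$habitat, ser$stratum, ser$variable)
    ser$series[match(paste(hab, stratum, variable), key)]
  }
  col_of <- function(s, t) {
    match(paste0("x[", s, ",", t, "]"), fit$x_index$col)
  }
  s_lc <- lookup(captures$habitat, "canopy", "log_light")
  s_lu <- lookup(captures$habitat, "understory", "log_light")
  s_tc <- lookup(captures$habitat, "canopy", "temperature_C")
  s_tu <- lookup(captures$habitat, "understory", "temperature_C")
  LD <- fit$x_draws[, col_of(s_lc, tcap), drop = FALSE] -
    fit$x_draws[, col_of(s_lu, tcap), drop = FALSE]
  TD <- fit$x_draws[, col_of(s_tc, tcap), drop = FALSE] -
    fit$x_draws[, col_of(s_tu, tcap), drop = FALSE]
  out <- captures
  out$LD <- unname(colMeans(LD))
  out$TD <- unname(colMeans(TD))
  out$LD_sd <- apply(LD, 2, stats::sd)
  out$TD_sd <- apply(TD, 2, stats::sd)
  attr(out, "draws") <- list(LD = LD, TD = TD)
  out
}
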