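#' Default diurnal curve parameters
#'
#' Hour-of-day baselines for the 12 habitat x stratum x variable series:
#' `level + amp1 * cos(2*pi*(h - peak)/24) + amp2 * cos(4*pi*(h - peak)/24)`.
#' Defaults emulate lowland wet-forest trap loggers: canopy brighter and
#' hotter than the understory by day but slightly cooler at night (the larger
#' canopy amplitude dips below the understory level after dark); edge strata
#' bright and hot, with the edge understory resembling the forest canopy more
#' than the forest understory.
#'
#' @return A tibble `habitat, stratum, variable, level, amp1, amp2, peak`.
#' @export
default_diurnal_curves <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(habitat = HABITATS, stratum = STRATA) |>
      dplyr::mutate(
        variable = "temperature_C",
        level = c(24.5, 24.0, 24.0, 23.8, 23.7, 23.5)[dplyr::row_number()],
        amp1 = ifelse(.data$stratum == "canopy",
          ifelse(.data$habitat == "edge", 3.4, 3.0),
          ifelse(.data$habitat == "edge", 2.4, 1.2)
        ),
        amp2 = 0.4, peak = 14
      ),
    tidyr::expand_grid(habitat = HABITATS, stratum = STRATA) |>
      dplyr::mutate(
        variable = "log_light",
        level = dplyr::case_when(
          .data$stratum == "canopy" ~ ifelse(.data$habitat == "edge", 4.3, 4.0),
          .data$habitat == "edge" ~ 3.6,
          TRUE ~ 1.4
        ),
        amp1 = dplyr::case_when(
          .data$stratum == "canopy" ~ ifelse(.data$habitat == "edge", 4.3, 4.0),
          .data$habitat == "edge" ~ 3.5,
          TRUE ~ 1.4
        ),
        amp2 = 0.5, peak = 12
      )
  )
}

default_true_coefficients <- function() {
  mediation_coefficients(
    alpha_L = 4.5, beta_L = -3.0, sigma_L = 1.0,
    alpha_T = 1.0, beta_T = 0.5, gamma_T = 0.2, sigma_T = 0.8,
    alpha_F = -0.5, beta_F = 0.8, sigma_F = 1.2,
    alpha_C = -0.5, beta_C = -0.9, lambda = 0.02, tau = -0.05, phi = 0.9
  )
}

#' Synthetic-study configuration
#'
#' Ground-truth parameters for the generator. Defaults mirror the field
#' design being emulated: 10 edge, 12 ridge and 10 valley trap sites, each
#' with a paired canopy/understory trap; on the order of 90 species across 12
#' tribes with a long-tailed (log-series) abundance distribution and
#' tribe-clustered canopy tendencies; hourly or two-hourly loggers with
#' missing stretches; diurnal light and temperature curves differing by
#' habitat and stratum; and capture strata driven by the logistic outcome
#' equation. `n_days` is kept at desk scale by default.
#'
#' @param n_sites Named vector of sites per habitat.
#' @param n_species,n_tribes Size of the regional species pool and number of
#'   tribes. With the default pool of 120 and the log-series abundance tail,
#'   a default-length study observes on the order of 90 species, matching the
#'   richness scale being emulated.
#' @param tribe_hyper_sd Spread of tribe-level mean tendencies (logit scale).
#' @param tribe_sd Within-tribe species tendency sd.
#' @param coefficients True [mediation_coefficients()]. The outcome equation
#'   uses them directly; the LD/TD equations define the SCM-mode generator.
#' @param edge_composition_shift Exponential-tilt strength of species
#'   sampling weights at edge sites (positive favours high-tendency species
#'   at the edge).
#' @param curves Diurnal curve table (see [default_diurnal_curves()]).
#' @param rho AR(1) persistence of the latent abiotic deviations.
#' @param sigma_proc,sigma_obs Named (`temperature_C`, `log_light`) process /
#'   observation sds.
#' @param capture_rate Expected captures per site-day.
#' @param capture_hours Hours-of-day in which traps are checked.
#' @param missingness List: `logger_mcar` (uniform missing fraction),
#'   `logger_mar_first_half` (extra missing probability in the first half of
#'   the study, emulating the early-study logger shortage), `fct_missing`
#'   (fraction of species without a prior-study tendency).
#' @param prior_sd,prior_noise Logit sd reported by the emulated prior study,
#'   and noise between true tendency and its reported prior mean.
#' @param n_days Study length in days.
#' @param start Study start date.
#' @param logseries_x Log-series abundance parameter in (0, 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = c(edge = 10, ridge = 12, valley = 10),
                       n_species = 120, n_tribes = 12,
                       tribe_hyper_sd = 1.0, tribe_sd = 0.7,
                       coefficients = default_true_coefficients(),
                       edge_composition_shift = 0.5,
                       curves = default_diurnal_curves(),
                       rho = 0.7,
                       sigma_proc = c(temperature_C = 0.5, log_light = 0.6),
                       sigma_obs = c(temperature_C = 0.3, log_light = 0.4),
                       capture_rate = 0.75,
                       capture_hours = 8:16,
                       missingness = list(
                         logger_mcar = 0.15,
                         logger_mar_first_half = 0.2,
                         fct_missing = 0.2
                       ),
                       prior_sd = 0.5, prior_noise = 0.3,
                       n_days = 30,
                       start = as.Date("2015-06-01"),
                       logseries_x = 0.99) {
  stopifnot(
    all(names(n_sites) %in% HABITATS), all(n_sites >= 1),
    n_species >= 1, n_tribes >= 1,
    abs(rho) < 1, all(sigma_proc > 0), all(sigma_obs > 0),
    logseries_x > 0, logseries_x < 1
  )
  rates <- unlist(missingness)
  if (any(rates < 0 | rates > 1)) abort("missingness rates must lie in [0, 1]")
  cfg <- as.list(environment())
  cfg$rates <- NULL
  structure(cfg, class = "sim_config")
}

# Fisher log-series abundance sampler (long tail, many singletons).
rlogseries <- function(n, x, kmax = 50000) {
  k <- seq_len(kmax)
  p <- x^k / k
  sample(k, n, replace = TRUE, prob = p)
}

diurnal_baseline <- function(curves, habitat, stratum, variable, hour) {
  row <- curves[
    curves$habitat == habitat & curves$stratum == stratum &
      curves$variable == variable,
  ]
  stopifnot(nrow(row) == 1)
  row$level + row$amp1 * cos(2 * pi * (hour - row$peak) / 24) +
    row$amp2 * cos(4 * pi * (hour - row$peak) / 24)
}

#' Generate sites, latent abiotic series and logger records
#'
#' Simulates the 12 latent habitat-stratum series over the configured span
#' (diurnal baseline plus AR(1) deviations) and noisy logger records from
#' every site, at hourly or two-hourly cadence (alternating by site), with
#' gaps injected per the missingness configuration. Light is exported in lux
#' (`exp(x) - 1`, floored at 0).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list: `sites`, `loggers`, `latent` (true latent series on the
#'   analysis scale).
#' @export
sim_abiotic <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    sites <- tibble::tibble(
      habitat = rep(names(config$n_sites), config$n_sites)
    ) |>
      dplyr::mutate(
        site_id = sprintf("S%02d", dplyr::row_number()),
        canopy_height_m = round(pmax(rnorm(dplyr::n(), 22.7, 5.3), 8), 1),
        understory_height_m = round(pmax(rnorm(dplyr::n(), 0.9, 0.2), 0.3), 1),
        .before = 1
      ) |>
      dplyr::select("site_id", "habitat", "canopy_height_m", "understory_height_m")

    hours <- seq(0, config$n_days * 24 - 1)
    stamps <- as.POSIXct(config$start, tz = "UTC") + hours * 3600
    hod <- hours %% 24
    grid <- tidyr::expand_grid(
      habitat = HABITATS, stratum = STRATA, variable = ABIOTIC_VARIABLES
    )
    latent <- purrr::pmap_dfr(grid, function(habitat, stratum, variable) {
      b <- diurnal_baseline(config$curves, habitat, stratum, variable, hod)
      sp <- config$sigma_proc[[variable]]
      d <- numeric(length(hours))
      d[1] <- rnorm(1, 0, sp / sqrt(1 - config$rho^2))
      for (t in 2:length(hours)) d[t] <- config$rho * d[t - 1] + rnorm(1, 0, sp)
      tibble::tibble(
        habitat = habitat, stratum = stratum, variable = variable,
        timestamp = stamps, hour = hod, value = b + d
      )
    })

    loggers <- purrr::pmap_dfr(
      dplyr::mutate(sites, cadence = ifelse(dplyr::row_number() %% 2 == 0, 2, 1)),
      function(site_id, habitat, cadence, ...) {
        keep <- (hours %% cadence) == 0
        purrr::map_dfr(seq_len(nrow(grid)), function(g) {
          if (grid$habitat[g] != habitat) {
            return(NULL)
          }
          lat <- latent$value[
            latent$habitat == habitat & latent$stratum == grid$stratum[g] &
              latent$variable == grid$variable[g]
          ]
          so <- config$sigma_obs[[grid$variable[g]]]
          obs <- lat[keep] + rnorm(sum(keep), 0, so)
          tibble::tibble(
            timestamp = stamps[keep], site_id = site_id,
            stratum = grid$stratum[g],
            variable = ifelse(grid$variable[g] == "log_light",
              "light_lux", "temperature_C"
            ),
            value = if (grid$variable[g] == "log_light") {
              pmax(exp(obs) - 1, 0)
            } else {
              obs
            },
            day = (hours[keep] %/% 24) + 1
          )
        })
      }
    )
    p_miss <- config$missingness$logger_mcar +
      config$missingness$logger_mar_first_half * (loggers$day <= config$n_days / 2)
    keep <- runif(nrow(loggers)) >= p_miss
    loggers <- dplyr::select(loggers[keep, ], -"day")
    list(sites = sites, loggers = loggers, latent = latent)
  })
}

sim_species_pool <- function(config, seed) {
  with_seed(seed, {
    tribe_names <- sprintf("Tribe%02d", seq_len(config$n_tribes))
    tribe_mean <- rnorm(config$n_tribes, 0, config$tribe_hyper_sd)
    tribe_idx <- sample(config$n_tribes, config$n_species, replace = TRUE)
    genus_within <- sample(3, config$n_species, replace = TRUE)
    mu <- tribe_mean[tribe_idx]
    tibble::tibble(
      species = sprintf(
        "Genus%02d%s sp%03d", tribe_idx, letters[genus_within],
        seq_len(config$n_species)
      ),
      tribe = tribe_names[tribe_idx],
      tribe_mean = mu,
      fct_true = rnorm(config$n_species, mu, config$tribe_sd),
      abundance = rlogseries(config$n_species, config$logseries_x)
    )
  })
}

#' Generate capture records from the latent series
#'
#' Draws capture events site-by-site and day-by-day (Poisson counts, daylight
#' trap hours), assigns species with abundance-weighted sampling whose weights
#' are exponentially tilted towards high canopy tendency at edge sites
#' (the composition shift), computes the true `LD`/`TD` contrasts from the
#' latent series at the capture hour, and draws the canopy/understory stratum
#' from the logistic outcome equation.
#'
#' @param config A [sim_config()].
#' @param abiotic Output of [sim_abiotic()].
#' @param seed Integer seed.
#' @return A list: `captures` (capture records), `species` (per-species
#'   truth), `truth_rows` (per-capture true `LD`, `TD`, `fct`, canopy
#'   probability).
#' @export
sim_captures <- function(config, abiotic, seed) {
  cf <- config$coefficients
  pool <- sim_species_pool(config, derive_seeds(seed, 2)[1])
  contrasts <- abiotic$latent |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "value") |>
    dplyr::mutate(contrast = .data$canopy - .data$understory) |>
    dplyr::select("habitat", "variable", "timestamp", "contrast") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "contrast") |>
    dplyr::rename(LD = "log_light", TD = "temperature_C")
  with_seed(derive_seeds(seed, 2)[2], {
    events <- tidyr::expand_grid(
      site_id = abiotic$sites$site_id, day = seq_len(config$n_days)
    ) |>
      dplyr::left_join(dplyr::select(abiotic$sites, "site_id", "habitat"), by = "site_id") |>
      dplyr::mutate(n_cap = rpois(dplyr::n(), config$capture_rate)) |>
      tidyr::uncount(.data$n_cap) |>
      dplyr::mutate(
        hour = sample(config$capture_hours, dplyr::n(), replace = TRUE),
        timestamp = as.POSIXct(config$start, tz = "UTC") +
          ((.data$day - 1) * 24 + .data$hour) * 3600,
        FE = fe_indicator(.data$habitat)
      )
    w <- outer(rep(1, nrow(events)), pool$abundance)
    tilt <- exp(config$edge_composition_shift * outer(events$FE, pool$fct_true))
    sp_idx <- vapply(seq_len(nrow(events)), function(i) {
      sample(nrow(pool), 1, prob = w[i, ] * tilt[i, ])
    }, 0L)
    events <- events |>
      dplyr::mutate(
        species = pool$species[sp_idx],
        tribe = pool$tribe[sp_idx],
        fct_true = pool$fct_true[sp_idx]
      ) |>
      dplyr::left_join(contrasts, by = c("habitat", "timestamp"))
    p_can <- plogis(
      cf$alpha_C + cf$beta_C * events$FE + cf$lambda * events$LD +
        cf$tau * events$TD + cf$phi * events$fct_true
    )
    events$stratum <- ifelse(rbinom(nrow(events), 1, p_can) == 1, "canopy", "understory")
    captures <- events |>
      dplyr::mutate(
        individual_id = sprintf("ind%05d", dplyr::row_number()),
        hour_assumed = FALSE
      ) |>
      dplyr::select(
        "individual_id", "timestamp", "site_id", "habitat", "stratum",
        "species", "tribe", "hour"
      )
    truth_rows <- dplyr::select(events, "LD", "TD", fct = "fct_true") |>
      dplyr::mutate(p_can = p_can)
    list(captures = captures, species = pool, truth_rows = truth_rows)
  })
}

#' Generate a complete synthetic study
#'
#' Runs the full generator: sites, latent abiotic series, gappy loggers,
#' captures, and a species canopy-tendency prior table with a configurable
#' fraction of species missing. Returns everything plus the ground truth
#' needed by recovery tests, including oracle effect values computed from the
#' true coefficients.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory); all outputs are byte-reproducible
#'   given it.
#' @return A list: `captures`, `loggers`, `sites`, `fct_priors`, and `truth`
#'   (config, coefficients, species table, latent series, per-capture truth,
#'   oracle effects).
#' @export
sim_study <- function(config = sim_config(), seed) {
  if (missing(seed)) abort("seed is mandatory")
  seeds <- derive_seeds(seed, 4)
  abiotic <- sim_abiotic(config, seeds[1])
  caps <- sim_captures(config, abiotic, seeds[2])
  fct_priors <- with_seed(seeds[3], {
    keep <- runif(nrow(caps$species)) >= config$missingness$fct_missing
    caps$species[keep, ] |>
      dplyr::transmute(
        species = .data$species, tribe = .data$tribe,
        logit_mean = .data$fct_true + rnorm(sum(keep), 0, config$prior_noise),
        logit_sd = config$prior_sd
      )
  })
  list(
    captures = caps$captures,
    loggers = abiotic$loggers,
    sites = abiotic$sites,
    fct_priors = fct_priors,
    truth = list(
      config = config,
      coefficients = config$coefficients,
      species = caps$species,
      latent = abiotic$latent,
      rows = caps$truth_rows,
      oracle_effects = effects_quadrature(config$coefficients)
    )
  )
}

#' Write a synthetic study to a directory
#'
#' Serialises a [sim_study()] result as the pipeline's CSV formats plus a
#' JSON ground-truth sidecar.
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_captures(study$captures, file.path(dir, "captures.csv"))
  write_loggers(study$loggers, file.path(dir, "loggers.csv"))
  write_sites(study$sites, file.path(dir, "sites.csv"))
  write_fct_priors(study$fct_priors, file.path(dir, "fct_priors.csv"))
  truth <- list(
    coefficients = unclass(study$truth$coefficients),
    oracle_effects = as.list(study$truth$oracle_effects[1, ]),
    species = study$truth$species
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Model-faithful structural generator
#'
#' Generates observations directly from the structural equations: exposure
#' from the site layout, then `LD`, `TD` and `fct` from their Gaussian
#' regressions and `CAN` from the logistic outcome equation, all at the
#' supplied true coefficients. This is the generator used for coefficient and
#' effect recovery studies, where the fitted model's functional form must
#' match the data-generating process exactly; the field-emulation generator
#' ([sim_study()]) draws `LD`/`TD` from diurnal latent series instead.
#'
#' @param n Number of observations.
#' @param coeffs True [mediation_coefficients()].
#' @param seed Integer seed.
#' @param n_sites Named habitat site counts (fixes the edge fraction).
#' @return A tibble `site_id, habitat, FE, LD, TD, fct, CAN`.
#' @export
sim_scm <- function(n, coeffs = default_true_coefficients(), seed,
                    n_sites = c(edge = 10, ridge = 12, valley = 10)) {
  if (missing(seed)) abort("seed is mandatory")
  with_seed(seed, {
    sites <- tibble::tibble(
      site_id = sprintf("S%02d", seq_len(sum(n_sites))),
      habitat = rep(names(n_sites), n_sites)
    )
    idx <- sample(nrow(sites), n, replace = TRUE)
    FE <- fe_indicator(sites$habitat[idx])
    LD <- coeffs$alpha_L + coeffs$beta_L * FE + rnorm(n, 0, coeffs$sigma_L)
    TD <- coeffs$alpha_T + coeffs$beta_T * FE + coeffs$gamma_T * LD +
      rnorm(n, 0, coeffs$sigma_T)
    fct <- coeffs$alpha_F + coeffs$beta_F * FE + rnorm(n, 0, coeffs$sigma_F)
    CAN <- rbinom(n, 1, plogis(
      coeffs$alpha_C + coeffs$beta_C * FE + coeffs$lambda * LD +
        coeffs$tau * TD + coeffs$phi * fct
    ))
    tibble::tibble(
      site_id = sites$site_id[idx], habitat = sites$habitat[idx],
      FE = FE, LD = LD, TD = TD, fct = fct, CAN = CAN
    )
  })
}

#' Null species-count generator for sign-test calibration
#'
#' Simulates per-species edge/forest canopy-understory counts with a common
#' canopy probability in both habitats, so the delta-edge sign is symmetric
#' about zero and the sign G-test's nominal size can be checked. Per-habitat
#' totals are kept away from tiny values so exact ties (delta edge 0) are
#' rare.
#'
#' @param n_species Number of species.
#' @param seed Integer seed.
#' @param size_base,size_mean Per-habitat totals are
#'   `size_base + Poisson(size_mean)`.
#' @return A counts tibble (`species, EC, EU, FC, FU`).
#' @export
sim_null_counts <- function(n_species = 41, seed, size_base = 10, size_mean = 10) {
  if (missing(seed)) abort("seed is mandatory")
  with_seed(seed, {
    n_e <- size_base + rpois(n_species, size_mean)
    n_f <- size_base + rpois(n_species, size_mean)
    p <- runif(n_species, 0.2, 0.8)
    EC <- rbinom(n_species, n_e, p)
    FC <- rbinom(n_species, n_f, p)
    tibble::tibble(
      species = sprintf("Genus%03d sp%03d", seq_len(n_species), seq_len(n_species)),
      EC = EC, EU = n_e - EC, FC = FC, FU = n_f - FC
    )
  })
}

#' Monte Carlo oracle for the effect decomposition
#'
#' Evaluates the telescoping counterfactual contrasts at a single true
#' coefficient vector with a very large number of common-random-number
#' mediator draws. Serves as the recovery target for synthetic studies; it is
#' cross-checked against the deterministic quadrature route
#' ([effects_quadrature()]).
#'
#' @param coeffs True [mediation_coefficients()].
#' @param K Monte Carlo size.
#' @param seed Integer seed.
#' @return A one-row tibble of the six effects.
#' @export
oracle_effects <- function(coeffs, K = 1e6, seed = 1) {
  with_seed(seed, {
    z1 <- rnorm(K)
    z2 <- rnorm(K)
    z3 <- rnorm(K)
    Eval <- function(a, a_L, a_TL, a_T, a_F) {
      LD <- coeffs$alpha_L + coeffs$beta_L * a_L + coeffs$sigma_L * z1
      LD_in <- coeffs$alpha_L + coeffs$beta_L * a_TL + coeffs$sigma_L * z1
      TD <- coeffs$alpha_T + coeffs$beta_T * a_T + coeffs$gamma_T * LD_in +
        coeffs$sigma_T * z2
      fct <- coeffs$alpha_F + coeffs$beta_F * a_F + coeffs$sigma_F * z3
      mean(plogis(
        coeffs$alpha_C + coeffs$beta_C * a + coeffs$lambda * LD +
          coeffs$tau * TD + coeffs$phi * fct
      ))
    }
    E <- c(
      Eval(0, 0, 0, 0, 0), Eval(1, 0, 0, 0, 0), Eval(1, 1, 0, 0, 0),
      Eval(1, 1, 1, 1, 0), Eval(1, 1, 1, 1, 1)
    )
    effects_from_expectations(E)
  })
}
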