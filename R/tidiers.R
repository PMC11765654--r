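#' Tidy a mediation fit
#'
#' @param x A [fit_mediation()] result.
#' @param conf.level Credible-interval level.
#' @param ... Unused.
#' @return A tibble with one row per structural coefficient: posterior mean,
#'   sd, credible bounds, split R-hat and effective sample size.
#' @export
tidy.mediation_fit <- function(x, conf.level = 0.95, ...) {
  draws <- posterior_coefficients(x)
  a <- (1 - conf.level) / 2
  est <- purrr::imap_dfr(draws, function(v, nm) {
    tibble::tibble(
      term = nm,
      estimate = mean(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, a)),
      conf.high = unname(quantile(v, 1 - a))
    )
  })
  dplyr::left_join(est, x$diagnostics, by = "term")
}

#' Summarise a mediation fit
#'
#' @param x A [fit_mediation()] result.
#' @param ... Unused.
#' @return A one-row tibble: sample size, sampler size, worst diagnostics and
#'   the convergence flag.
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    n = x$model$jags_data$n,
    mode = x$model$mode,
    chains = x$config$chains,
    draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess),
    n_divergent = x$n_divergent,
    identified = x$identified,
    converged = x$converged
  )
}

#' Tidy an effect decomposition
#'
#' @param x An [effect_decomposition()] result.
#' @param ... Unused.
#' @return One row per effect with the posterior mean and central 50% and 95%
#'   credible intervals.
#' @export
tidy.effect_estimates <- function(x, ...) {
  purrr::imap_dfr(x$draws, function(v, nm) {
    tibble::tibble(
      term = nm,
      estimate = mean(v),
      conf.low.50 = unname(quantile(v, 0.25)),
      conf.high.50 = unname(quantile(v, 0.75)),
      conf.low.95 = unname(quantile(v, 0.025)),
      conf.high.95 = unname(quantile(v, 0.975))
    )
  })
}

#' Summarise an effect decomposition
#'
#' @param x An [effect_decomposition()] result.
#' @param ... Unused.
#' @return A one-row tibble with the Monte Carlo settings and the largest
#'   per-draw violation of the telescoping additivity identity (should be at
#'   numerical zero).
#' @export
glance.effect_estimates <- function(x, ...) {
  resid <- with(
    x$draws,
    nde + light_effect + temperature_effect + sce - tce
  )
  tibble::tibble(
    n_draws = x$n_draws,
    K = x$K,
    n_population = x$n_population,
    additivity_max_error = max(abs(resid)),
    edge_identity_max_error = max(abs(x$draws$edge_effect - (x$draws$tce - x$draws$sce)))
  )
}
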