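EFFECT_NAMES <- c(
  "nde", "light_effect", "temperature_effect", "sce", "tce", "edge_effect"
)

#' Counterfactual setting
#'
#' A fully explicit assignment for the canopy-outcome equation under the
#' potential-outcomes notation: the exposure `a` entering the outcome
#' directly, and the exposure arguments of each mediator — `a_L` for the
#' light difference `LD(a_L)`, `a_T` and `a_TL` for the temperature
#' difference `TD(a_T, LD(a_TL))`, and `a_F` for the canopy tendency
#' `FCT(a_F)`. No defaults: every argument must be specified.
#'
#' @param a,a_L,a_TL,a_T,a_F Each 0 or 1.
#' @return A list of class `counterfactual_setting`.
#' @export
#' @examples
#' # edge exposure with forest light, forest temperature, forest composition
#' counterfactual_setting(a = 1, a_L = 0, a_TL = 0, a_T = 0, a_F = 0)
counterfactual_setting <- function(a, a_L, a_TL, a_T, a_F) {
  vals <- list(a = a, a_L = a_L, a_TL = a_TL, a_T = a_T, a_F = a_F)
  if (any(vapply(vals, function(v) length(v) != 1 || !(v %in% c(0, 1)), TRUE))) {
    abort("every counterfactual argument must be specified as 0 or 1")
  }
  structure(vals, class = "counterfactual_setting")
}

# The telescoping sequence: consecutive differences give NDE, light,
# temperature and species-composition effects; the endpoints give the TCE.
telescope_settings <- function() {
  list(
    counterfactual_setting(0, 0, 0, 0, 0),
    counterfactual_setting(1, 0, 0, 0, 0),
    counterfactual_setting(1, 1, 0, 0, 0),
    counterfactual_setting(1, 1, 1, 1, 0),
    counterfactual_setting(1, 1, 1, 1, 1)
  )
}

# Common random numbers: one K x 3 standard-normal matrix shared by every
# counterfactual setting, so the telescoping identity holds exactly per draw.
crn_matrix <- function(K, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, matrix(rnorm(3 * K), K, 3)))
  }
  matrix(rnorm(3 * K), K, 3)
}

#' Simulate potential mediator values
#'
#' Draws `K` joint values of the light and temperature differences under the
#' stated counterfactual exposures: `LD(a_L)` and `TD(a_T, LD(a_TL))`, with
#' the light value entering the temperature equation drawn under the
#' temperature equation's own light argument. Supplying `z` (a `K x 3`
#' standard-normal matrix) enforces common random numbers across settings.
#'
#' @param coeffs A [mediation_coefficients()] object.
#' @param a_L Exposure for the reported light difference.
#' @param a_T Exposure for the temperature equation.
#' @param a_TL Exposure of the light value inside the temperature equation
#'   (defaults to `a_T`).
#' @param K Number of draws.
#' @param z Optional common-random-number matrix from `K` standard normals
#'   (`K x 3`); drawn fresh when `NULL`.
#' @param seed Optional seed used when `z` is `NULL`.
#' @return A tibble with columns `LD`, `TD`.
#' @export
simulate_mediators <- function(coeffs, a_L, a_T, a_TL = a_T, K = 1000,
                               z = NULL, seed = NULL) {
  stopifnot(K >= 1)
  z <- z %||% crn_matrix(K, seed)
  LD <- coeffs$alpha_L + coeffs$beta_L * a_L + coeffs$sigma_L * z[, 1]
  LD_inner <- coeffs$alpha_L + coeffs$beta_L * a_TL + coeffs$sigma_L * z[, 1]
  TD <- coeffs$alpha_T + coeffs$beta_T * a_T + coeffs$gamma_T * LD_inner +
    coeffs$sigma_T * z[, 2]
  tibble::tibble(LD = LD, TD = TD)
}

#' Expected canopy probability under a counterfactual setting
#'
#' Monte Carlo estimate of `E{CAN(a, LD(a_L), TD(a_T, LD(a_TL)), FCT(a_F))}`:
#' the mean over `K` mediator draws of the inverse-logit outcome equation,
#' with the tendency drawn from the `FCT(a_F)` regression.
#'
#' @inheritParams simulate_mediators
#' @param setting A [counterfactual_setting()].
#' @return A single probability in \[0, 1\].
#' @export
expected_canopy <- function(coeffs, setting, K = 1000, z = NULL, seed = NULL) {
  stopifnot(inherits(setting, "counterfactual_setting"))
  z <- z %||% crn_matrix(K, seed)
  med <- simulate_mediators(coeffs, setting$a_L, setting$a_T, setting$a_TL,
    K = nrow(z), z = z
  )
  fct <- coeffs$alpha_F + coeffs$beta_F * setting$a_F + coeffs$sigma_F * z[, 3]
  mean(plogis(
    coeffs$alpha_C + coeffs$beta_C * setting$a + coeffs$lambda * med$LD +
      coeffs$tau * med$TD + coeffs$phi * fct
  ))
}

effects_from_expectations <- function(E) {
  tibble::tibble(
    nde = E[2] - E[1],
    light_effect = E[3] - E[2],
    temperature_effect = E[4] - E[3],
    sce = E[5] - E[4],
    tce = E[5] - E[1],
    edge_effect = (E[5] - E[1]) - (E[5] - E[4])
  )
}

#' Potential-outcomes effect decomposition
#'
#' Computes the causal effect decomposition of the forest edge on canopy
#' probability from a fitted mediation model: per posterior draw, the expected
#' canopy probability is evaluated along the telescoping sequence of
#' counterfactual settings (edge exposure switched on first, then edge light,
#' then edge temperature, then edge species composition) under common random
#' numbers, giving the natural direct effect, light effect, temperature
#' effect, species composition effect, their total (TCE), and the edge effect
#' defined as TCE minus SCE. By construction the four component effects sum
#' exactly to the TCE within every draw.
#'
#' @param x A converged [fit_mediation()] result, or a single
#'   [mediation_coefficients()] vector.
#' @param K Mediator Monte Carlo draws per posterior draw. When a reference
#'   `population` is given, `K` defaults to its row count (the population's
#'   covariate roles are fully replaced by counterfactual draws, so it only
#'   fixes the Monte Carlo size).
#' @param seed Seed for the mediator draws.
#' @param population Optional reference population (a tibble of captures).
#' @param force Compute even from a non-converged fit.
#' @return An object of class `effect_estimates`: `draws` (one row per
#'   posterior draw, one column per effect) plus metadata. Use [tidy()] for
#'   posterior means with 50% and 95% credible intervals.
#' @export
effect_decomposition <- function(x, K = NULL, seed = 1, population = NULL,
                                 force = FALSE) {
  if (inherits(x, "mediation_coefficients")) {
    coef_draws <- tibble::as_tibble(unclass(x)[COEF_NAMES])
  } else if (inherits(x, "mediation_fit")) {
    if (!x$converged && !force) {
      abort(paste0(
        "refusing to decompose effects from a non-converged fit; ",
        "inspect diagnostics or use force = TRUE"
      ))
    }
    coef_draws <- posterior_coefficients(x)
  } else {
    abort("x must be a mediation_fit or mediation_coefficients")
  }
  K <- K %||% (if (!is.null(population)) nrow(population) else 1000L)
  stopifnot(K >= 1)
  settings <- telescope_settings()
  D <- nrow(coef_draws)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, D, 6)
    for (d in seq_len(D)) {
      cf <- as_mediation_coefficients(as.list(coef_draws[d, ]))
      z <- crn_matrix(K)
      E <- vapply(settings, function(s) expected_canopy(cf, s, z = z), 0)
      out[d, ] <- as.numeric(effects_from_expectations(E)[1, ])
    }
    out
  })
  colnames(draws) <- EFFECT_NAMES
  structure(
    list(
      draws = tibble::as_tibble(draws),
      K = as.integer(K), seed = seed,
      n_population = if (is.null(population)) NA_integer_ else nrow(population),
      n_draws = D
    ),
    class = "effect_estimates"
  )
}

#' Closed-form effect decomposition by quadrature
#'
#' For a single coefficient vector the outcome-equation argument is a linear
#' function of the three jointly Gaussian noise variables, so every expected
#' canopy probability is a one-dimensional Gaussian-logistic integral. This
#' evaluates the same telescoping contrasts as [effect_decomposition()] by
#' adaptive quadrature — an independent deterministic route used to
#' cross-check the Monte Carlo path and to compute oracle truths for
#' synthetic data.
#'
#' @param coeffs A [mediation_coefficients()] object.
#' @return A one-row tibble of the six effects.
#' @export
effects_quadrature <- function(coeffs) {
  E <- vapply(telescope_settings(), function(s) {
    m <- coeffs$alpha_C + coeffs$beta_C * s$a +
      coeffs$lambda * (coeffs$alpha_L + coeffs$beta_L * s$a_L) +
      coeffs$tau * (coeffs$alpha_T + coeffs$beta_T * s$a_T +
        coeffs$gamma_T * (coeffs$alpha_L + coeffs$beta_L * s$a_TL)) +
      coeffs$phi * (coeffs$alpha_F + coeffs$beta_F * s$a_F)
    v <- (coeffs$lambda + coeffs$tau * coeffs$gamma_T)^2 * coeffs$sigma_L^2 +
      coeffs$tau^2 * coeffs$sigma_T^2 + coeffs$phi^2 * coeffs$sigma_F^2
    if (v == 0) {
      return(plogis(m))
    }
    integrate(
      function(u) plogis(m + sqrt(v) * u) * dnorm(u),
      -Inf, Inf,
      rel.tol = 1e-10
    )$value
  }, 0)
  effects_from_expectations(E)
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(
    "Effect decomposition:", x$n_draws, "posterior draws, K =", x$K,
    "mediator draws each\n"
  )
  print(tidy(x), ...)
  invisible(x)
}
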