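#' Fit a normal distribution to logit-scale quantiles
#'
#' Species canopy-tendency priors are built by fitting a normal distribution to
#' the logit-transformed quantiles of a canopy-probability posterior from a
#' previous study. The fit is least squares of `qlogis(value)` on the standard
#' normal quantiles `qnorm(prob)`: the intercept is the logit-scale mean and
#' the slope the logit-scale sd.
#'
#' @param probs Strictly increasing probabilities in (0, 1).
#' @param values Quantile values in (0, 1) (probability scale).
#' @return A list with `logit_mean`, `logit_sd` and `rss` (residual sum of
#'   squares of the quantile fit, 0 when the source is exactly logit-normal).
#' @export
#' @examples
#' fit_logit_normal_from_quantiles(
#'   probs = c(0.25, 0.75),
#'   values = plogis(1 + 2 * qnorm(c(0.25, 0.75)))
#' )
fit_logit_normal_from_quantiles <- function(probs, values) {
  if (length(probs) != length(values)) abort("probs and values must have equal length")
  if (length(probs) < 2) abort("at least two quantile pairs are required")
  if (any(probs <= 0) || any(probs >= 1)) abort("probs must lie strictly in (0, 1)")
  if (any(diff(probs) <= 0)) abort("probs must be strictly increasing")
  if (any(values <= 0) || any(values >= 1)) {
    abort("quantile values at 0 or 1 have undefined logit; values must lie strictly in (0, 1)")
  }
  z <- qnorm(probs)
  y <- qlogis(values)
  fit <- lm(y ~ z)
  sd_hat <- unname(coef(fit)[2])
  if (!is.finite(sd_hat) || sd_hat <= 0) {
    abort("fitted logit_sd is not positive; quantile values are not increasing")
  }
  list(
    logit_mean = unname(coef(fit)[1]),
    logit_sd = sd_hat,
    rss = sum(stats::residuals(fit)^2)
  )
}

#' Assemble the species canopy-tendency prior table
#'
#' Produces exactly one prior row per species observed in the capture data.
#' Species present in the prior-study table keep their fitted logit-normal
#' prior (`source = "prior_study"`); species absent from it are marked
#' `source = "imputed"` with `NA` moments, and their tendencies are drawn from
#' their tribe's hyperdistribution inside the joint model.
#'
#' @param captures Capture records (need `species` and `tribe` columns).
#' @param fct_priors Prior-study table (see [read_fct_priors()]), or `NULL`
#'   for none.
#' @return A tibble `species, tribe, logit_mean, logit_sd, source`.
#' @export
fct_prior_table <- function(captures, fct_priors = NULL) {
  assert_columns(captures, c("species", "tribe"), "captures")
  species <- captures |>
    dplyr::distinct(.data$species, .data$tribe) |>
    dplyr::arrange(.data$species)
  if (anyDuplicated(species$species)) {
    dup <- species$species[duplicated(species$species)]
    abort(paste0(
      "species mapped to more than one tribe: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (any(is.na(species$tribe) | species$tribe == "")) {
    abort("every species must have a known tribe")
  }
  if (is.null(fct_priors)) {
    return(dplyr::mutate(species,
      logit_mean = NA_real_, logit_sd = NA_real_, source = "imputed"
    ))
  }
  assert_columns(fct_priors, c("species", "logit_mean", "logit_sd"), "fct_priors")
  out <- dplyr::left_join(
    species,
    dplyr::select(fct_priors, "species", "logit_mean", "logit_sd"),
    by = "species"
  )
  dplyr::mutate(out,
    source = ifelse(is.na(.data$logit_mean), "imputed", "prior_study")
  )
}
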