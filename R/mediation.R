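COEF_NAMES <- c(
  "alpha_L", "beta_L", "sigma_L",
  "alpha_T", "beta_T", "gamma_T", "sigma_T",
  "alpha_F", "beta_F", "sigma_F",
  "alpha_C", "beta_C", "lambda", "tau", "phi"
)

#' Mediation coefficient vector
#'
#' The structural-causal model has four equations. Three Gaussian regressions
#' for the mediators: `LD = alpha_L + beta_L*FE + e_L`, `TD = alpha_T +
#' beta_T*FE + gamma_T*LD + e_T`, `FCT = alpha_F + beta_F*FE + e_F`; and one
#' logistic regression for the canopy outcome: `logit P(CAN = 1) = alpha_C +
#' beta_C*FE + lambda*LD + tau*TD + phi*FCT`.
#'
#' @param alpha_L,beta_L,sigma_L Light-difference equation.
#' @param alpha_T,beta_T,gamma_T,sigma_T Temperature-difference equation.
#' @param alpha_F,beta_F,sigma_F Canopy-tendency equation.
#' @param alpha_C,beta_C,lambda,tau,phi Canopy outcome equation (logit scale).
#' @return A named list of class `mediation_coefficients`.
#' @export
mediation_coefficients <- function(alpha_L = 0, beta_L = 0, sigma_L = 1,
                                   alpha_T = 0, beta_T = 0, gamma_T = 0, sigma_T = 1,
                                   alpha_F = 0, beta_F = 0, sigma_F = 1,
                                   alpha_C = 0, beta_C = 0, lambda = 0,
                                   tau = 0, phi = 0) {
  out <- list(
    alpha_L = alpha_L, beta_L = beta_L, sigma_L = sigma_L,
    alpha_T = alpha_T, beta_T = beta_T, gamma_T = gamma_T, sigma_T = sigma_T,
    alpha_F = alpha_F, beta_F = beta_F, sigma_F = sigma_F,
    alpha_C = alpha_C, beta_C = beta_C, lambda = lambda, tau = tau, phi = phi
  )
  if (!all(vapply(out, is.numeric, TRUE))) abort("coefficients must be numeric")
  if (out$sigma_L <= 0 || out$sigma_T <= 0 || out$sigma_F <= 0) {
    abort("error sds must be positive")
  }
  structure(out, class = "mediation_coefficients")
}

#' @rdname mediation_coefficients
#' @param x A named list or numeric vector with the 15 coefficient names.
#' @export
as_mediation_coefficients <- function(x) {
  x <- as.list(x)
  missing <- setdiff(COEF_NAMES, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing coefficient(s): ", paste(missing, collapse = ", ")))
  }
  do.call(mediation_coefficients, x[COEF_NAMES])
}

#' Bernoulli-logit log-likelihood of the canopy outcome block
#'
#' @param coeffs A [mediation_coefficients()] object.
#' @param data Tibble with `FE`, `CAN`, `LD`, `TD` and `fct` columns.
#' @return The summed log-likelihood.
#' @export
canopy_loglik <- function(coeffs, data) {
  assert_columns(data, c("FE", "CAN", "LD", "TD", "fct"), "data")
  eta <- coeffs$alpha_C + coeffs$beta_C * data$FE + coeffs$lambda * data$LD +
    coeffs$tau * data$TD + coeffs$phi * data$fct
  sum(stats::dbinom(data$CAN, 1, plogis(eta), log = TRUE))
}

#' Build the joint mediation / missing-data model
#'
#' Assembles the joint model: the four structural equations, plus (depending
#' on the inputs) the tribe-hierarchical block for species canopy tendencies
#' and the abiotic state-space block. The joint density is the product of the
#' state-space likelihood, the tendency hierarchy, the three mediator
#' regressions, the canopy logistic likelihood, and the priors — one posterior,
#' so information flows freely between the mediation and missing-data parts.
#' Regression coefficients get flat (vague normal) priors and error sds
#' uniform (0, 50] priors.
#'
#' Model form is chosen from the inputs:
#' * `data` has an `fct` column: observed-tendency form.
#' * otherwise: species-level tendencies are latent, with prior-study priors
#'   where available (`fct_priors`) and tribe-hierarchical imputation where not.
#' * `loggers` + `sites` supplied: the state-space block is included and every
#'   capture's `LD`/`TD` is the latent canopy-understory contrast of its
#'   habitat at its capture hour. Otherwise `LD`/`TD` columns are used, with
#'   `NA` values imputed from their regression distributions.
#'
#' @param data Observation table from [prepare_mediation_data()] (needs `FE`,
#'   `CAN`, and either `fct` or `species` + `tribe`; `LD`/`TD` unless the
#'   state-space block supplies them).
#' @param fct_priors Optional prior-study tendency table ([read_fct_priors()]).
#' @param loggers,sites Optional logger and site tables for the joint form.
#' @param priors [abiotic_priors()] for the state-space block.
#' @param offset Light log-transform offset.
#' @return A list of class `mediation_model` with the model `code`, JAGS
#'   `jags_data`, `monitors`, `mode` and metadata.
#' @export
build_joint_model <- function(data, fct_priors = NULL, loggers = NULL,
                              sites = NULL, priors = abiotic_priors(),
                              offset = 1) {
  assert_columns(data, c("FE", "CAN"), "data")
  if (nrow(data) == 0) {
    abort("no observations: the flat-prior model has no proper prior-only posterior")
  }
  if (!all(data$FE %in% c(0, 1)) || !all(data$CAN %in% c(0, 1))) {
    abort("FE and CAN must be 0/1")
  }
  identified <- var(data$FE) > 0
  if (!identified) {
    warn("all observations share one exposure level; edge coefficients are unidentified")
  }
  joint <- !is.null(loggers)
  species_mode <- !("fct" %in% names(data))
  n <- nrow(data)

  jd <- list(n = n, FE = data$FE, CAN = data$CAN)
  monitors <- c(COEF_NAMES)
  code_obs <- character()
  code_sp <- character()
  meta <- list()

  if (joint) {
    if (is.null(sites)) abort("sites are required with loggers")
    spec <- build_state_space(loggers, sites, priors, offset,
      grid_span = range(data$timestamp)
    )
    jd <- c(jd, spec$jags_data)
    ser <- spec$series
    key <- paste(ser$habitat, ser$stratum, ser$variable)
    look <- function(stratum, variable) {
      ser$series[match(paste(data$habitat, stratum, variable), key)]
    }
    jd$s_lc <- look("canopy", "log_light")
    jd$s_lu <- look("understory", "log_light")
    jd$s_tc <- look("canopy", "temperature_C")
    jd$s_tu <- look("understory", "temperature_C")
    jd$tcap <- match(floor_hour(data$timestamp), spec$grid)
    if (any(is.na(jd$tcap))) abort("capture hour outside the state-space grid")
    code_obs <- c(code_obs, "
    ld_i[i] <- x[s_lc[i], tcap[i]] - x[s_lu[i], tcap[i]]
    td_i[i] <- x[s_tc[i], tcap[i]] - x[s_tu[i], tcap[i]]")
    ld_term <- "ld_i[i]"
    td_term <- "td_i[i]"
    meta$state_space <- spec

    # Mediator regressions. Where the capture's habitat-hour has an observed
    # logger contrast the regression observes it as data; captures that
    # cannot be matched contribute latent outcomes (the canopy equation uses
    # the latent state contrasts for every capture either way). Keeping the
    # observed contrasts as regression data pins the error sds: a regression
    # whose outcomes are all latent has a degenerate mode with the outcomes
    # collapsed onto the regression plane and the sd at zero.
    obs_contr <- spec$obs |>
      dplyr::select("habitat", "stratum", "variable", "timestamp", "value") |>
      tidyr::pivot_wider(names_from = "stratum", values_from = "value") |>
      dplyr::mutate(contrast = .data$canopy - .data$understory) |>
      dplyr::select("habitat", "variable", "timestamp", "contrast") |>
      tidyr::pivot_wider(names_from = "variable", values_from = "contrast")
    cap_key <- paste(data$habitat, floor_hour(data$timestamp))
    obs_key <- paste(obs_contr$habitat, obs_contr$timestamp)
    mi <- match(cap_key, obs_key)
    ld_obs <- if ("log_light" %in% names(obs_contr)) obs_contr$log_light[mi] else rep(NA_real_, n)
    td_obs <- if ("temperature_C" %in% names(obs_contr)) obs_contr$temperature_C[mi] else rep(NA_real_, n)
    reg_block <- function(y, label, obs_line, mis_line) {
      io <- which(!is.na(y))
      im <- which(is.na(y))
      out <- character()
      if (length(io) > 0) {
        jd[[paste0("y", label)]] <<- y[io]
        jd[[paste0("io", label)]] <<- io
        jd[[paste0("n_obs_", label)]] <<- length(io)
        out <- c(out, obs_line)
      }
      if (length(im) > 0) {
        jd[[paste0("z", label)]] <<- rep(0, length(im))
        jd[[paste0("im", label)]] <<- im
        jd[[paste0("n_mis_", label)]] <<- length(im)
        out <- c(out, mis_line)
      }
      out
    }
    code_sp <- c(code_sp,
      reg_block(ld_obs, "LD", "
  for (j in 1:n_obs_LD) {
    yLD[j] ~ dnorm(alpha_L + beta_L * FE[ioLD[j]], prec_L)
  }", "
  for (j in 1:n_mis_LD) {
    zLD[j] ~ dnorm(ld_i[imLD[j]] - alpha_L - beta_L * FE[imLD[j]], prec_L)
  }"),
      reg_block(td_obs, "TD", "
  for (j in 1:n_obs_TD) {
    yTD[j] ~ dnorm(alpha_Tc + beta_T * FE[ioTD[j]] + gamma_T * (ld_i[ioTD[j]] - cLD), prec_T)
  }", "
  for (j in 1:n_mis_TD) {
    zTD[j] ~ dnorm(td_i[imTD[j]] - alpha_Tc - beta_T * FE[imTD[j]] - gamma_T * (ld_i[imTD[j]] - cLD), prec_T)
  }")
    )
    wide <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(spec$obs, .data$stratum, .data$variable),
        m = mean(.data$value), .groups = "drop"
      ),
      names_from = c("stratum", "variable"), values_from = "m"
    )
    jd$cLD <- (wide$canopy_log_light %||% 0) - (wide$understory_log_light %||% 0)
    jd$cTD <- (wide$canopy_temperature_C %||% 0) - (wide$understory_temperature_C %||% 0)
  } else {
    assert_columns(data, c("LD", "TD"), "data")
    jd$LD <- data$LD
    jd$TD <- data$TD
    code_obs <- c(code_obs, "
    LD[i] ~ dnorm(alpha_L + beta_L * FE[i], prec_L)
    TD[i] ~ dnorm(alpha_Tc + beta_T * FE[i] + gamma_T * (LD[i] - cLD), prec_T)")
    ld_term <- "LD[i]"
    td_term <- "TD[i]"
    jd$cLD <- mean(data$LD, na.rm = TRUE)
    jd$cTD <- mean(data$TD, na.rm = TRUE)
    if (!is.finite(jd$cLD)) jd$cLD <- 0
    if (!is.finite(jd$cTD)) jd$cTD <- 0
  }

  if (species_mode) {
    assert_columns(data, c("species", "tribe"), "data")
    sp_tbl <- fct_prior_table(data, fct_priors)
    tribes <- sort(unique(sp_tbl$tribe))
    sp_tbl$tribe_idx <- match(sp_tbl$tribe, tribes)
    jd$sp <- match(data$species, sp_tbl$species)
    has_prior <- sp_tbl$source == "prior_study"
    if (any(has_prior)) {
      jd$sp_prior <- which(has_prior)
      jd$prior_m <- sp_tbl$logit_mean[has_prior]
      jd$prior_p <- sp_tbl$logit_sd[has_prior]^-2
      jd$n_sp_prior <- sum(has_prior)
      code_sp <- c(code_sp, "
  for (j in 1:n_sp_prior) {
    fct_sp[sp_prior[j]] ~ dnorm(prior_m[j], prior_p[j])
  }")
    }
    if (any(!has_prior)) {
      jd$sp_mis <- which(!has_prior)
      jd$tribe_mis <- sp_tbl$tribe_idx[!has_prior]
      jd$n_sp_mis <- sum(!has_prior)
      jd$n_tribe <- length(tribes)
      code_sp <- c(code_sp, "
  for (j in 1:n_sp_mis) {
    fct_sp[sp_mis[j]] ~ dnorm(mu_tribe[tribe_mis[j]], prec_tribe[tribe_mis[j]])
  }
  for (g in 1:n_tribe) {
    mu_tribe[g] ~ dnorm(0, 0.16)
    sd_tribe[g] ~ dnorm(0, 0.4444444) T(0.001,)
    prec_tribe[g] <- pow(sd_tribe[g], -2)
  }")
      monitors <- c(monitors, "mu_tribe", "sd_tribe")
    }
    monitors <- c(monitors, "fct_sp")
    code_obs <- c(code_obs, "
    fct_i[i] <- fct_sp[sp[i]]")
    # Composition regression. For species with prior-study tendencies the
    # outcome is their reported logit mean (observed data); a fully latent
    # outcome for every observation would let the tendencies collapse onto
    # the regression plane with sigma_F -> 0 (a degenerate joint mode), so
    # only prior-less species contribute latent outcomes, through their
    # tribe-imputed tendencies.
    obs_pinned <- which(has_prior[jd$sp])
    obs_free <- which(!has_prior[jd$sp])
    if (length(obs_pinned) > 0) {
      jd$obs_pin <- obs_pinned
      jd$n_obs_pin <- length(obs_pinned)
      jd$y_fct <- sp_tbl$logit_mean[jd$sp[obs_pinned]]
      code_sp <- c(code_sp, "
  for (j in 1:n_obs_pin) {
    y_fct[j] ~ dnorm(alpha_F + beta_F * FE[obs_pin[j]], prec_F)
  }")
    }
    if (length(obs_free) > 0) {
      jd$obs_free <- obs_free
      jd$n_obs_free <- length(obs_free)
      jd$zf <- rep(0, length(obs_free))
      code_sp <- c(code_sp, "
  for (j in 1:n_obs_free) {
    zf[j] ~ dnorm(fct_sp[sp[obs_free[j]]] - alpha_F - beta_F * FE[obs_free[j]], prec_F)
  }")
    }
    fct_term <- "fct_i[i]"
    jd$cF <- if (any(has_prior)) mean(sp_tbl$logit_mean[has_prior]) else 0
    meta$species <- sp_tbl
    meta$tribes <- tribes
  } else {
    jd$fct <- data$fct
    code_obs <- c(code_obs, "
    fct[i] ~ dnorm(alpha_F + beta_F * FE[i], prec_F)")
    fct_term <- "fct[i]"
    jd$cF <- mean(data$fct, na.rm = TRUE)
    if (!is.finite(jd$cF)) jd$cF <- 0
  }
  # In the latent-tendency forms the logistic block is updated by generic
  # samplers; clamping keeps its likelihood computable when the linear
  # predictor saturates in floating point during early adaptation. The
  # observed-covariate form keeps the bare inverse-logit so the backend's
  # specialised GLM samplers recognise the structure.
  eta <- sprintf(
    "alpha_Cc + beta_C * FE[i] + lambda * (%s - cLD) + tau * (%s - cTD) + phi * (%s - cF)",
    ld_term, td_term, fct_term
  )
  if (species_mode || joint) {
    code_obs <- c(code_obs, sprintf("
    eta[i] <- %s
    CAN[i] ~ dbern(min(max(ilogit(eta[i]), 1.0E-12), 1 - 1.0E-12))", eta))
  } else {
    code_obs <- c(code_obs, sprintf("
    CAN[i] ~ dbern(ilogit(%s))", eta))
  }

  code <- paste0(
    "model {\n",
    if (joint) state_space_code() else "",
    "  for (i in 1:n) {", paste(code_obs, collapse = ""), "\n  }\n",
    paste(code_sp, collapse = ""), "
  alpha_L ~ dnorm(0, 1.0E-6)\n  beta_L ~ dnorm(0, 1.0E-6)
  alpha_Tc ~ dnorm(0, 1.0E-6)\n  beta_T ~ dnorm(0, 1.0E-6)\n  gamma_T ~ dnorm(0, 1.0E-6)
  alpha_T <- alpha_Tc - gamma_T * cLD
  alpha_F ~ dnorm(0, 1.0E-6)\n  beta_F ~ dnorm(0, 1.0E-6)
  alpha_Cc ~ dnorm(0, 1.0E-6)\n  beta_C ~ dnorm(0, 1.0E-6)
  alpha_C <- alpha_Cc - lambda * cLD - tau * cTD - phi * cF
  lambda ~ dnorm(0, 1.0E-6)\n  tau ~ dnorm(0, 1.0E-6)\n  phi ~ dnorm(0, 1.0E-6)
  sigma_L ~ dunif(0.001, 50)\n  sigma_T ~ dunif(0.001, 50)\n  sigma_F ~ dunif(0.001, 50)
  prec_L <- pow(sigma_L, -2)\n  prec_T <- pow(sigma_T, -2)\n  prec_F <- pow(sigma_F, -2)
}\n"
  )
  structure(
    list(
      code = code, jags_data = jd, monitors = monitors,
      mode = if (joint) "joint" else if (species_mode) "species" else "covariate",
      identified = identified, data = data, meta = meta
    ),
    class = "mediation_model"
  )
}

#' Fit the mediation model
#'
#' Runs the Gibbs sampler on a model built by [build_joint_model()] (a data
#' frame is built into a model first) and attaches convergence diagnostics.
#' Runs failing the gate (split R-hat above the threshold, effective sample
#' size below it) are returned with `converged = FALSE` and a warning — never
#' silently.
#'
#' @param x A `mediation_model` or an observation table (see
#'   [build_joint_model()] for the recognised shapes).
#' @param config A [sampler_config()]; `config$seed` makes the fit
#'   reproducible draw-for-draw.
#' @param ... Passed to [build_joint_model()] when `x` is a data frame.
#' @return An object of class `mediation_fit` with elements `draws` (tibble of
#'   posterior draws), `diagnostics`, `converged`, `n_divergent` (always 0 for
#'   a Gibbs backend: the diagnostic does not arise), `model` and `config`.
#' @export
fit_mediation <- function(x, config = sampler_config(), ...) {
  model <- if (inherits(x, "mediation_model")) x else build_joint_model(x, ...)
  samples <- run_jags(model$code, model$jags_data, model$monitors, config)
  present <- intersect(COEF_NAMES, colnames(samples[[1]]))
  diag <- mcmc_diagnostics(samples, present)
  converged <- all(diag$rhat <= config$rhat_max) && all(diag$ess >= config$ess_min)
  if (!converged) {
    warn(paste0(
      "mediation fit did not meet the convergence gate (max R-hat ",
      round(max(diag$rhat), 3), ", min ESS ", round(min(diag$ess)),
      "); results are returned flagged non-converged"
    ))
  }
  structure(
    list(
      draws = draws_tibble(samples),
      diagnostics = diag,
      converged = converged && model$identified,
      identified = model$identified,
      n_divergent = 0L,
      model = model,
      config = config
    ),
    class = "mediation_fit"
  )
}

#' Posterior draws of the structural coefficients
#'
#' @param fit A [fit_mediation()] result.
#' @return A tibble of draws, one column per coefficient.
#' @export
posterior_coefficients <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  dplyr::select(fit$draws, dplyr::all_of(COEF_NAMES))
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Joint Bayesian mediation fit (", x$model$mode, " form), n = ",
    x$model$jags_data$n, "\n",
    sep = ""
  )
  cat(
    "  chains:", x$config$chains, "| draws/chain:", x$config$draws,
    "| max split R-hat:", round(max(x$diagnostics$rhat), 4),
    "| min ESS:", round(min(x$diagnostics$ess)), "\n"
  )
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' @export
print.mediation_model <- function(x, ...) {
  cat("Mediation model (", x$mode, " form), n = ", x$jags_data$n, "\n", sep = "")
  invisible(x)
}
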