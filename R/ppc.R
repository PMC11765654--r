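skewness <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(0)
  }
  mean((x - m)^3) / s^3
}

#' Posterior predictive checks for the mediation model
#'
#' For each Gaussian regression (LD, TD, FCT): replicates the response from
#' the fitted equation under a subsample of posterior draws and reports
#' discrepancy p-values for the mean, sd and skewness of the response
#' (`p = P(T(rep) >= T(obs))`; values near 0 or 1 flag misfit). For the
#' logistic canopy equation: a reliability (calibration) table of binned
#' predicted probabilities against empirical canopy frequencies.
#'
#' @param fit A [fit_mediation()] result.
#' @param n_rep Number of posterior draws used for replication.
#' @param bins Number of equal-width probability bins for the calibration
#'   table.
#' @param seed Seed for draw subsampling and replication noise.
#' @return A list of class `ppc_report`: `discrepancy` (tibble `variable,
#'   statistic, observed, replicated, p_value`) and `calibration` (tibble
#'   `bin, n, predicted, empirical`).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, bins = 10, seed = 1) {
  stopifnot(inherits(fit, "mediation_fit"))
  data <- fit$model$data
  coefs <- posterior_coefficients(fit)
  with_seed(seed, {
    pick <- sample(nrow(coefs), min(n_rep, nrow(coefs)))
    coefs <- coefs[pick, ]
    FE <- data$FE

    fct_obs_draws <- NULL
    if (fit$model$mode == "covariate") {
      fct_obs <- data$fct
    } else {
      sp_cols <- sprintf("fct_sp[%d]", fit$model$jags_data$sp)
      fct_mat <- as.matrix(fit$draws[pick, unique(sp_cols)])
      fct_obs_draws <- fct_mat[, match(sp_cols, unique(sp_cols)), drop = FALSE]
      fct_obs <- colMeans(fct_obs_draws)
    }

    check_gaussian <- function(y_obs, mean_fun, sigma_name, y_obs_draws = NULL) {
      ok <- !is.na(y_obs)
      stats_fun <- function(v) c(mean = mean(v), sd = sd(v), skewness = skewness(v))
      reps <- t(vapply(seq_len(nrow(coefs)), function(d) {
        cf <- coefs[d, ]
        mu <- mean_fun(cf)[ok]
        y_rep <- rnorm(sum(ok), mu, cf[[sigma_name]])
        obs <- if (is.null(y_obs_draws)) y_obs[ok] else y_obs_draws[d, ok]
        c(stats_fun(y_rep), obs = stats_fun(obs))
      }, numeric(6)))
      tibble::tibble(
        statistic = c("mean", "sd", "skewness"),
        observed = colMeans(reps[, 4:6, drop = FALSE]),
        replicated = colMeans(reps[, 1:3, drop = FALSE]),
        p_value = vapply(1:3, function(j) mean(reps[, j] >= reps[, j + 3]), 0)
      )
    }

    disc <- list()
    if (!all(is.na(data_col(data, "LD")))) {
      disc$LD <- check_gaussian(
        data_col(data, "LD"),
        function(cf) cf$alpha_L + cf$beta_L * FE, "sigma_L"
      )
    }
    if (!all(is.na(data_col(data, "TD")))) {
      LD <- data_col(data, "LD")
      disc$TD <- check_gaussian(
        ifelse(is.na(LD), NA, data_col(data, "TD")),
        function(cf) cf$alpha_T + cf$beta_T * FE + cf$gamma_T * LD, "sigma_T"
      )
    }
    disc$FCT <- check_gaussian(
      fct_obs,
      function(cf) cf$alpha_F + cf$beta_F * FE, "sigma_F",
      y_obs_draws = fct_obs_draws
    )
    discrepancy <- dplyr::bind_rows(disc, .id = "variable")

    cm <- colMeans(coefs)
    LD <- data_col(data, "LD")
    TD <- data_col(data, "TD")
    eta <- cm[["alpha_C"]] + cm[["beta_C"]] * FE + cm[["lambda"]] * LD +
      cm[["tau"]] * TD + cm[["phi"]] * fct_obs
    ok <- !is.na(eta)
    p_hat <- plogis(eta[ok])
    bin <- cut(p_hat, breaks = seq(0, 1, length.out = bins + 1), include.lowest = TRUE)
    calibration <- tibble::tibble(
      bin = bin, p = p_hat, CAN = data$CAN[ok]
    ) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        n = dplyr::n(),
        predicted = mean(.data$p),
        empirical = mean(.data$CAN),
        .groups = "drop"
      )
    structure(
      list(discrepancy = discrepancy, calibration = calibration),
      class = "ppc_report"
    )
  })
}

data_col <- function(data, col) {
  if (col %in% names(data)) data[[col]] else rep(NA_real_, nrow(data))
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("Posterior predictive checks\n\nDiscrepancy p-values:\n")
  print(x$discrepancy, ...)
  cat("\nCanopy calibration:\n")
  print(x$calibration, ...)
  invisible(x)
}
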