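# Low-level JAGS driver shared by the state-space and mediation fits.
# Deterministic given `seed`: per-chain RNG streams are derived from it.

#' Sampler configuration
#'
#' Settings for the Gibbs sampler backing every Bayesian fit in the package.
#' At least two chains are required so that split R-hat is defined; the
#' convergence gate declares a run converged when all monitored coefficients
#' have split R-hat at most `rhat_max` and effective sample size at least
#' `ess_min`.
#'
#' @param chains Number of chains (>= 2).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Retained draws per chain.
#' @param seed Master seed; all chain RNG streams derive from it.
#' @param rhat_max,ess_min Convergence gate thresholds.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 2, adapt = 500, warmup = 500, draws = 750,
                           seed = 1, rhat_max = 1.01, ess_min = 400) {
  if (chains < 2) abort("at least 2 chains are required to assess convergence")
  structure(
    list(
      chains = as.integer(chains), adapt = as.integer(adapt),
      warmup = as.integer(warmup), draws = as.integer(draws),
      seed = as.integer(seed), rhat_max = rhat_max, ess_min = ess_min
    ),
    class = "sampler_config"
  )
}

# glm_module: the backend's specialised GLM samplers give far better mixing
# for the plain regression form, but their adaptation does not scale to the
# latent-tendency graphs, which instead use the generic samplers.
run_jags <- function(code, data, monitors, config, glm_module = TRUE) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    abort("rjags is required for model fitting")
  }
  if (glm_module) {
    rjags::load.module("glm", quiet = TRUE)
  } else {
    try(rjags::unload.module("glm", quiet = TRUE), silent = TRUE)
  }
  seeds <- derive_seeds(config$seed, config$chains)
  inits <- lapply(seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  model <- rjags::jags.model(
    textConnection(code),
    data = data, inits = inits,
    n.chains = config$chains, n.adapt = config$adapt, quiet = TRUE
  )
  if (config$warmup > 0) update(model, config$warmup, progress.bar = "none")
  samples <- rjags::coda.samples(model, monitors, n.iter = config$draws,
    progress.bar = "none"
  )
  samples
}

# Split R-hat (each chain halved, classic between/within formula).
split_rhat <- function(samples) {
  params <- colnames(samples[[1]])
  vapply(params, function(p) {
    halves <- unlist(lapply(samples, function(ch) {
      x <- as.numeric(ch[, p])
      n <- length(x) %/% 2
      list(x[seq_len(n)], x[n + seq_len(n)])
    }), recursive = FALSE)
    n <- length(halves[[1]])
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, var, 0)
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

mcmc_diagnostics <- function(samples, terms = NULL) {
  terms <- terms %||% colnames(samples[[1]])
  sub <- samples[, terms, drop = FALSE]
  rhat <- split_rhat(sub)
  ess <- coda::effectiveSize(sub)
  tibble::tibble(
    term = terms,
    rhat = unname(rhat[terms]),
    ess = unname(ess[terms])
  )
}

draws_tibble <- function(samples) {
  per_chain <- lapply(seq_along(samples), function(c) {
    m <- as.matrix(samples[[c]])
    tibble::as_tibble(m) |>
      dplyr::mutate(.chain = c, .iteration = dplyr::row_number(), .before = 1)
  })
  dplyr::bind_rows(per_chain) |>
    dplyr::mutate(.draw = dplyr::row_number(), .before = 1)
}
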