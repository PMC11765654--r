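#' Pipeline configuration
#'
#' Bundles the tunable settings of the end-to-end pipeline. Can be built in
#' code or loaded from a YAML file with [read_pipeline_config()].
#'
#' @param offset Light log-transform offset.
#' @param default_hour Representative hour for date-only capture timestamps.
#' @param genera Understory genera removed by the G-test sensitivity filter.
#' @param min_per_habitat Minimum per-habitat count for the third G-test.
#' @param sampler A [sampler_config()]; its seed fans out to every stochastic
#'   stage.
#' @param K Mediator Monte Carlo draws per posterior draw in the effect
#'   stage.
#' @param joint Fit the joint model with the state-space block (`TRUE`), or
#'   attach observed abiotic contrasts and impute residual missingness from
#'   the regressions (`FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(offset = 1, default_hour = 12,
                            genera = c("Caligo", "Eryphanis", "Taygetis"),
                            min_per_habitat = 3,
                            sampler = sampler_config(),
                            K = 1000, joint = TRUE) {
  structure(
    list(
      offset = offset, default_hour = default_hour, genera = genera,
      min_per_habitat = min_per_habitat, sampler = sampler, K = K,
      joint = joint
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys match the arguments above
#'   (`sampler` given as a nested mapping).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sampler)) raw$sampler <- do.call(sampler_config, raw$sampler)
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in dependency order on a directory of input CSVs
#' (`captures.csv`, `loggers.csv`, `sites.csv`, optional `fct_priors.csv`):
#' hourly abiotic summaries; the delta-edge table and sign G-test suite; the
#' joint Bayesian mediation fit; the causal effect decomposition; and
#' posterior predictive checks. Every run writes a manifest with the package
#' version, seed, configuration, input checksums, stage timings and the
#' convergence flag, plus a JSON-lines log. Existing outputs are never
#' overwritten unless `force = TRUE` (their stages are skipped, making a
#' rerun of a completed directory a no-op); a failing stage leaves completed
#' artifacts in place and records the error in the manifest before raising
#' it.
#'
#' @param input_dir Directory with the input CSVs.
#' @param output_dir Output directory (created if needed).
#' @param stages Stages to run, a subset of
#'   `c("summaries", "gtest", "fit", "effects", "ppc")`.
#' @param config A [pipeline_config()].
#' @param force Overwrite existing stage outputs.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         stages = c("summaries", "gtest", "fit", "effects", "ppc"),
                         config = pipeline_config(), force = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "log.jsonl")
  log_line <- function(...) {
    entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), ...)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = ""
    )
  }
  inputs <- c(
    captures = file.path(input_dir, "captures.csv"),
    loggers = file.path(input_dir, "loggers.csv"),
    sites = file.path(input_dir, "sites.csv"),
    fct_priors = file.path(input_dir, "fct_priors.csv")
  )
  manifest <- list(
    package = "stratmed",
    version = as.character(utils::packageVersion("stratmed")),
    seed = config$sampler$seed,
    config = unclass_deep(config),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  sites <- read_sites(inputs["sites"])
  captures <- read_captures(inputs["captures"],
    sites = sites,
    default_hour = config$default_hour
  )
  loggers <- read_loggers(inputs["loggers"])
  fct_priors <- if (file.exists(inputs["fct_priors"])) {
    read_fct_priors(inputs["fct_priors"])
  } else {
    NULL
  }

  state <- new.env(parent = emptyenv())
  run_stage <- function(name, outputs, fun) {
    if (!name %in% stages) {
      return(invisible(NULL))
    }
    paths <- file.path(output_dir, outputs)
    if (all(file.exists(paths)) && !force) {
      log_line(stage = name, status = "skipped", reason = "outputs exist")
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    log_line(stage = name, status = "started")
    result <- tryCatch(fun(), error = function(e) e)
    if (inherits(result, "error")) {
      log_line(stage = name, status = "failed", error = conditionMessage(result))
      manifest$stages[[name]] <<- list(
        status = "failed", error = conditionMessage(result)
      )
      write_manifest()
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(result)))
    }
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    log_line(stage = name, status = "done", seconds = round(secs, 2))
    manifest$stages[[name]] <<- list(status = "done", seconds = round(secs, 2))
    invisible(NULL)
  }

  run_stage("summaries", "hourly_summary.csv", function() {
    hs <- hourly_summary(loggers, sites, offset = config$offset)
    readr::write_csv(hs, file.path(output_dir, "hourly_summary.csv"))
  })

  run_stage("gtest", c("delta_edge.csv", "gtest.json"), function() {
    counts <- aggregate_stratum_counts(captures)
    suite <- gtest_suite(counts,
      genera = config$genera,
      min_per_habitat = config$min_per_habitat
    )
    readr::write_csv(suite$delta, file.path(output_dir, "delta_edge.csv"))
    jsonlite::write_json(suite$tests, file.path(output_dir, "gtest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  run_stage("fit", c("posterior_draws.csv", "diagnostics.json"), function() {
    data <- prepare_mediation_data(captures)
    fit <- if (config$joint) {
      fit_mediation(data,
        config = config$sampler, fct_priors = fct_priors,
        loggers = loggers, sites = sites, offset = config$offset
      )
    } else {
      data <- prepare_mediation_data(captures, abiotic_series(loggers, sites, config$offset))
      fit_mediation(data, config = config$sampler, fct_priors = fct_priors)
    }
    state$fit <- fit
    readr::write_csv(fit$draws, file.path(output_dir, "posterior_draws.csv"))
    jsonlite::write_json(
      list(
        diagnostics = fit$diagnostics, converged = fit$converged,
        n_divergent = fit$n_divergent, identified = fit$identified
      ),
      file.path(output_dir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    manifest$converged <<- fit$converged
  })

  need_fit <- function() {
    if (is.null(state$fit)) {
      abort("the 'fit' stage must run (or have run) in this call first")
    }
    state$fit
  }

  run_stage("effects", "effects.json", function() {
    fit <- need_fit()
    eff <- effect_decomposition(fit,
      K = config$K,
      seed = derive_seeds(config$sampler$seed, 10)[10],
      population = captures, force = !fit$converged
    )
    jsonlite::write_json(
      list(
        estimates = tidy(eff),
        K = eff$K, seed = eff$seed, n_population = eff$n_population,
        identities = as.list(glance(eff))
      ),
      file.path(output_dir, "effects.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  run_stage("ppc", "ppc.json", function() {
    fit <- need_fit()
    ppc <- posterior_predictive_check(fit,
      seed = derive_seeds(config$sampler$seed, 11)[11]
    )
    jsonlite::write_json(
      list(discrepancy = ppc$discrepancy, calibration = ppc$calibration),
      file.path(output_dir, "ppc.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  write_manifest()
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.function(x)) {
    NULL
  } else {
    x
  }
}
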