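test_that("logit-normal quantile fit recovers exact normal quantiles", {
  fit <- fit_logit_normal_from_quantiles(
    c(0.025, 0.5, 0.975),
    plogis(c(-1.959964, 0, 1.959964))
  )
  expect_equal(fit$logit_mean, 0, tolerance = 1e-8)
  expect_equal(fit$logit_sd, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  fit2 <- fit_logit_normal_from_quantiles(
    c(0.25, 0.75),
    plogis(1 + 2 * qnorm(c(0.25, 0.75)))
  )
  expect_equal(fit2$logit_mean, 1, tolerance = 1e-8)
  expect_equal(fit2$logit_sd, 2, tolerance = 1e-8)
})

test_that("quantile fit recovers arbitrary logit-normals exactly", {
  set.seed(42)
  for (i in 1:20) {
    mu <- rnorm(1, 0, 2)
    sigma <- runif(1, 0.2, 3)
    probs <- sort(runif(sample(2:6, 1), 0.01, 0.99))
    while (any(diff(probs) <= 0)) probs <- sort(runif(3, 0.01, 0.99))
    fit <- fit_logit_normal_from_quantiles(probs, plogis(mu + sigma * qnorm(probs)))
    expect_equal(fit$logit_mean, mu, tolerance = 1e-8)
    expect_equal(fit$logit_sd, sigma, tolerance = 1e-8)
  }
})

test_that("skewed quantiles give the least-squares fit with nonzero residual", {
  probs <- c(0.1, 0.5, 0.9)
  values <- c(0.2, 0.3, 0.9) # not logit-normal
  fit <- fit_logit_normal_from_quantiles(probs, values)
  ref <- lm(qlogis(values) ~ qnorm(probs))
  expect_equal(fit$logit_mean, unname(coef(ref)[1]))
  expect_equal(fit$logit_sd, unname(coef(ref)[2]))
  expect_gt(fit$rss, 0)
})

test_that("quantile fit validates its inputs", {
  expect_error(fit_logit_normal_from_quantiles(0.5, 0.5), "two quantile")
  expect_error(fit_logit_normal_from_quantiles(c(0.5, 0.2), c(0.3, 0.4)), "increasing")
  expect_error(fit_logit_normal_from_quantiles(c(0.2, 0.8), c(0, 0.4)), "logit")
  expect_error(fit_logit_normal_from_quantiles(c(0.2, 0.8), c(0.4, 1)), "logit")
  expect_error(
    fit_logit_normal_from_quantiles(c(0.2, 0.8), c(0.8, 0.2)),
    "not positive|not increasing"
  )
})

test_that("fct_prior_table marks missing species imputed and checks tribes", {
  caps <- tibble::tibble(
    species = c("A a", "A a", "B b", "C c"),
    tribe = c("T1", "T1", "T1", "T2")
  )
  priors <- tibble::tibble(
    species = c("A a", "C c"), tribe = c("T1", "T2"),
    logit_mean = c(0.5, -1), logit_sd = c(0.4, 0.6)
  )
  tbl <- fct_prior_table(caps, priors)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$source[tbl$species == "B b"], "imputed")
  expect_equal(tbl$source[tbl$species == "A a"], "prior_study")
  expect_equal(sort(unique(tbl$source)), c("imputed", "prior_study"))

  expect_error(
    fct_prior_table(tibble::tibble(species = "A a", tribe = NA_character_)),
    "known tribe"
  )
  expect_error(
    fct_prior_table(tibble::tibble(
      species = c("A a", "A a"), tribe = c("T1", "T2")
    )),
    "more than one tribe"
  )
})

test_that("tribe hierarchy shrinks prior-less species toward tribe and data", {
  # Tribe T1 species have low tendencies (priors near -1); the prior-less
  # species X is captured mostly in the canopy, so its posterior tendency
  # must move above the tribe mean; the mirrored species Y (mostly
  # understory) must move below it.
  set.seed(31)
  n_each <- 40
  pinned_means <- c(`S1 a` = -1.5, `S2 a` = -0.5, `S3 a` = 0.5, `S4 a` = 1.5)
  sp <- rep(c(names(pinned_means), "X x", "Y y"), each = n_each)
  # canopy data consistent with phi = 1 for pinned species identifies the
  # tendency slope; X is overwhelmingly canopy, Y overwhelmingly understory
  canopy_p <- c(plogis(rep(pinned_means, each = n_each)),
    rep(0.9, n_each), rep(0.05, n_each))
  data <- tibble::tibble(
    species = sp, tribe = "T1",
    FE = rep(c(0L, 1L), length.out = length(sp)),
    CAN = rbinom(length(sp), 1, canopy_p),
    LD = rnorm(length(sp), 4, 1), TD = rnorm(length(sp), 1, 0.5)
  )
  priors <- tibble::tibble(
    species = names(pinned_means), tribe = "T1",
    logit_mean = unname(pinned_means), logit_sd = 0.3
  )
  fit <- quiet_fit(data,
    fct_priors = priors,
    config = sampler_config(seed = 8, adapt = 400, warmup = 400, draws = 800)
  )
  sp_tbl <- fit$model$meta$species
  idx <- function(s) which(sp_tbl$species == s)
  fct_mean <- function(s) mean(fit$draws[[sprintf("fct_sp[%d]", idx(s))]])
  # a single tribe monitors as a scalar node
  tribe_col <- intersect(c("mu_tribe", "mu_tribe[1]"), names(fit$draws))
  tribe_mean <- mean(fit$draws[[tribe_col]])
  expect_gt(fct_mean("X x"), tribe_mean)
  expect_lt(fct_mean("Y y"), tribe_mean)
})

test_that("informative tendency priors sharpen composition-effect recovery", {
  # Same data fitted with sharp prior-study tendencies versus deliberately
  # flat ones: the flat-prior fit must not recover the species composition
  # effect more accurately.
  cfg <- sim_config(n_days = 12, prior_noise = 0.1, prior_sd = 0.3,
    missingness = list(logger_mcar = 0, logger_mar_first_half = 0, fct_missing = 0.1))
  study <- sim_study(cfg, seed = 17)
  data <- suppressWarnings(
    prepare_mediation_data(study$captures, abiotic_series(study$loggers, study$sites))
  )
  sc <- sampler_config(seed = 9, adapt = 400, warmup = 400, draws = 800)
  fit_inf <- quiet_fit(data, fct_priors = study$fct_priors, config = sc)
  flat_priors <- dplyr::mutate(study$fct_priors, logit_mean = 0, logit_sd = 10)
  fit_flat <- quiet_fit(data, fct_priors = flat_priors, config = sc)
  truth <- study$truth$oracle_effects$sce
  err <- function(f) {
    eff <- effect_decomposition(f, K = 300, seed = 2, force = TRUE)
    abs(mean(eff$draws$sce) - truth)
  }
  expect_lt(err(fit_inf), err(fit_flat) + 0.01)
})
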