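make_captures_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("individual_id,timestamp,site_id,habitat,stratum,species,tribe", lines), path)
  path
}

test_that("well-formed capture CSVs round-trip through write and read", {
  study <- sim_study(sim_config(n_days = 4), seed = 7)
  paths <- list(
    captures = tempfile(fileext = ".csv"), loggers = tempfile(fileext = ".csv"),
    sites = tempfile(fileext = ".csv"), fct = tempfile(fileext = ".csv")
  )
  write_captures(study$captures, paths$captures)
  write_loggers(study$loggers, paths$loggers)
  write_sites(study$sites, paths$sites)
  write_fct_priors(study$fct_priors, paths$fct)
  caps <- read_captures(paths$captures, sites = read_sites(paths$sites))
  logs <- read_loggers(paths$loggers)
  expect_equal(
    dplyr::select(caps, names(study$captures)[1:7]),
    dplyr::select(study$captures, 1:7)
  )
  expect_equal(
    dplyr::select(logs, -"hour"),
    study$loggers,
    tolerance = 1e-12
  )
  expect_equal(read_sites(paths$sites), study$sites)
  expect_equal(
    dplyr::select(read_fct_priors(paths$fct), -"source"),
    study$fct_priors
  )
})

test_that("capture validation rejects bad enums, duplicates and bad timestamps", {
  ok <- make_captures_csv(c(
    "i1,2015-06-01T10:00:00Z,S01,edge,canopy,Nessaea aglaura,Biblidini",
    "i2,2015-06-01T11:00:00Z,S01,edge,understory,Nessaea aglaura,Biblidini",
    "i3,2015-06-02T10:00:00Z,S02,ridge,canopy,Morpho helenor,Morphini"
  ))
  expect_equal(nrow(read_captures(ok)), 3)

  bad_stratum <- make_captures_csv(
    "i1,2015-06-01T10:00:00Z,S01,edge,mid,Nessaea aglaura,Biblidini"
  )
  expect_error(read_captures(bad_stratum), "invalid stratum")

  dup <- make_captures_csv(c(
    "i1,2015-06-01T10:00:00Z,S01,edge,canopy,Nessaea aglaura,Biblidini",
    "i1,2015-06-02T10:00:00Z,S01,edge,canopy,Nessaea aglaura,Biblidini"
  ))
  expect_error(read_captures(dup), "duplicate individual_id")

  bad_ts <- make_captures_csv(c(
    "i1,2015-06-01T10:00:00Z,S01,edge,canopy,Nessaea aglaura,Biblidini",
    "i2,junk,S01,edge,canopy,Nessaea aglaura,Biblidini"
  ))
  expect_error(read_captures(bad_ts), "line\\(s\\): 3")
})

test_that("date-only timestamps get the representative hour, flagged", {
  path <- make_captures_csv("i1,2015-06-01,S01,edge,canopy,Nessaea aglaura,Biblidini")
  expect_message(caps <- read_captures(path, default_hour = 12), "representative hour")
  expect_true(caps$hour_assumed)
  expect_equal(caps$hour, 12)
  caps9 <- suppressMessages(read_captures(path, default_hour = 9))
  expect_equal(caps9$hour, 9)
})

test_that("log_light matches ln(lux + offset) and is strictly monotone", {
  expect_equal(log_light(0), 0)
  expect_equal(log_light(exp(1) - 1), 1)
  expect_equal(log_light(1000), log(1001), tolerance = 1e-12)
  expect_equal(round(log_light(1000), 4), 6.9088)
  expect_error(log_light(-1), "non-negative")
  expect_error(log_light(10, offset = 0), "positive")
  lux <- sort(runif(50, 0, 5000))
  expect_true(all(diff(log_light(lux)) > 0))
})

test_that("hourly_summary reproduces hand-computed means and CIs", {
  sites <- tibble::tibble(
    site_id = c("S01", "S02"), habitat = "ridge",
    canopy_height_m = 20, understory_height_m = 1
  )
  ts <- as.POSIXct("2015-06-01 10:00:00", tz = "UTC")
  loggers <- tibble::tibble(
    timestamp = c(ts, ts, ts + 86400),
    site_id = c("S01", "S02", "S01"),
    stratum = "canopy",
    variable = "temperature_C",
    value = c(24, 26, 30)
  )
  # two-record cell at hour 10 on day one plus a singleton from day two
  hs <- suppressMessages(hourly_summary(loggers[1:2, ], sites))
  expect_equal(hs$mean, 25)
  expect_equal(hs$ci_half_width, 1.96 * sqrt(2) / sqrt(2), tolerance = 1e-12)
  expect_equal(hs$n, 2L)
  one <- suppressMessages(hourly_summary(loggers[3, , drop = FALSE], sites))
  expect_equal(one$ci_half_width, 0)
  expect_message(hourly_summary(loggers[3, , drop = FALSE], sites), "single record")
})

test_that("hourly means recover the generator's diurnal curve", {
  cfg <- sim_config(n_days = 25, missingness = list(
    logger_mcar = 0.1, logger_mar_first_half = 0, fct_missing = 0
  ))
  ab <- sim_abiotic(cfg, seed = 13)
  hs <- suppressMessages(hourly_summary(ab$loggers, ab$sites))
  cell <- dplyr::filter(hs, .data$habitat == "ridge", .data$stratum == "canopy",
    .data$variable == "temperature_C", .data$hour == 12)
  truth <- stratmed:::diurnal_baseline(cfg$curves, "ridge", "canopy", "temperature_C", 12)
  # shared AR deviations decorrelate across days: ~n_days independent values
  expect_lt(abs(cell$mean - truth), 0.6)
  expect_gt(cell$n, 100)
})

test_that("attach_abiotic forms canopy-minus-understory contrasts, antisymmetric", {
  ts <- as.POSIXct("2015-06-01 10:00:00", tz = "UTC")
  abiotic <- tidyr::expand_grid(
    habitat = "edge", stratum = c("canopy", "understory"),
    variable = c("log_light", "temperature_C"), timestamp = ts
  ) |>
    dplyr::mutate(value = c(7, 26, 3, 24))
  caps <- tibble::tibble(
    individual_id = "i1", timestamp = ts, site_id = "S01",
    habitat = "edge", stratum = "canopy",
    species = "Nessaea aglaura", tribe = "Biblidini"
  )
  out <- attach_abiotic(caps, abiotic)
  expect_equal(out$LD, 4)
  expect_equal(out$TD, 2)

  swapped <- dplyr::mutate(abiotic,
    stratum = ifelse(.data$stratum == "canopy", "understory", "canopy")
  )
  out2 <- attach_abiotic(caps, swapped)
  expect_equal(out2$LD, -4)
  expect_equal(out2$TD, -2)

  equal <- dplyr::mutate(abiotic, value = 5)
  out3 <- attach_abiotic(caps, equal)
  expect_equal(out3$LD, 0)
  expect_equal(out3$TD, 0)

  # capture at an hour/habitat with no logger coverage: flagged missing
  late <- dplyr::mutate(caps, timestamp = ts + 3600)
  expect_warning(out4 <- attach_abiotic(late, abiotic), "flagged missing")
  expect_true(is.na(out4$LD) && is.na(out4$TD))
})

test_that("a capture table encoding the packaged counts re-aggregates to them", {
  counts <- nymphalid_counts()
  long <- counts |>
    tidyr::pivot_longer(c("EC", "EU", "FC", "FU"),
      names_to = "cell", values_to = "n"
    ) |>
    tidyr::uncount(.data$n) |>
    dplyr::mutate(
      habitat = ifelse(substr(.data$cell, 1, 1) == "E", "edge", "ridge"),
      stratum = ifelse(substr(.data$cell, 2, 2) == "C", "canopy", "understory"),
      individual_id = sprintf("i%04d", dplyr::row_number()),
      timestamp = as.POSIXct("2015-06-01 12:00:00", tz = "UTC"),
      site_id = ifelse(.data$habitat == "edge", "S01", "S11"),
      tribe = "unknown"
    )
  agg <- aggregate_stratum_counts(long)
  expect_equal(nrow(agg), 41)
  merged <- dplyr::left_join(counts, agg, by = "species")
  expect_equal(merged$EC.y, merged$EC.x)
  expect_equal(merged$EU.y, merged$EU.x)
  expect_equal(merged$FC.y, merged$FC.x)
  expect_equal(merged$FU.y, merged$FU.x)
  nes <- agg[agg$species == "Nessaea aglaura", ]
  expect_equal(unlist(nes[c("EC", "EU", "FC", "FU")], use.names = FALSE), c(0L, 5L, 7L, 29L))
})
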