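#' Read capture records
#'
#' Reads a CSV of uniquely marked individuals (one row per individual;
#' recaptures are assumed to have been excluded upstream) and validates it.
#' Expected columns: `individual_id,timestamp,site_id,habitat,stratum,species,tribe`.
#' Timestamps are ISO-8601; a date without a time-of-day is accepted (trap
#' checks have day resolution) and is assigned the representative hour
#' `default_hour`, with the assumption recorded in the `hour_assumed` column.
#'
#' @param path Path to a captures CSV.
#' @param sites Optional site table (see [read_sites()]); when supplied,
#'   `site_id` membership and habitat consistency are checked.
#' @param default_hour Hour-of-day (0-23) assigned to date-only timestamps.
#' @return A tibble with parsed, validated capture records and columns
#'   `hour` (0-23) and `hour_assumed` (logical).
#' @export
read_captures <- function(path, sites = NULL, default_hour = 12) {
  stopifnot(default_hour %in% 0:23)
  df <- read_checked_csv(
    path,
    cols = readr::cols(
      individual_id = readr::col_character(),
      timestamp = readr::col_character(),
      site_id = readr::col_character(),
      habitat = readr::col_character(),
      stratum = readr::col_character(),
      species = readr::col_character(),
      tribe = readr::col_character()
    ),
    what = "captures"
  )
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate individual_id (recaptures must be excluded upstream): ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  check_enum(df$habitat, HABITATS, "habitat")
  check_enum(df$stratum, STRATA, "stratum")

  ts <- parse_timestamp(df$timestamp, default_hour)
  if (any(ts$failed)) {
    abort(paste0(
      "unparseable timestamp at data line(s): ",
      paste(which(ts$failed) + 1L, collapse = ", ")
    ))
  }
  out <- dplyr::mutate(
    df,
    timestamp = ts$value,
    hour = hour_of(ts$value),
    hour_assumed = ts$assumed
  )
  if (any(out$hour_assumed)) {
    inform(paste0(
      sum(out$hour_assumed), " capture(s) had date-only timestamps; ",
      "assigned representative hour ", default_hour, ":00"
    ))
  }
  if (!is.null(sites)) {
    unknown <- setdiff(out$site_id, sites$site_id)
    if (length(unknown) > 0) {
      abort(paste0("capture site_id not in site table: ", paste(unknown, collapse = ", ")))
    }
    chk <- dplyr::left_join(out, dplyr::select(sites, "site_id", site_habitat = "habitat"),
      by = "site_id"
    )
    bad <- chk$habitat != chk$site_habitat
    if (any(bad)) {
      abort(paste0(
        "capture habitat disagrees with site table for site(s): ",
        paste(unique(chk$site_id[bad]), collapse = ", ")
      ))
    }
  }
  out
}

#' Read hourly logger records
#'
#' Reads temperature and light measurements from the trap-mounted loggers.
#' Expected columns: `timestamp,site_id,stratum,variable,value` with
#' `variable` one of `"temperature_C"` or `"light_lux"`. Measurements were
#' taken every hour or every other hour, so gaps are expected and permitted;
#' duplicate keys are not.
#'
#' @param path Path to a loggers CSV.
#' @return A tibble of validated logger records with an `hour` column.
#' @export
read_loggers <- function(path) {
  df <- read_checked_csv(
    path,
    cols = readr::cols(
      timestamp = readr::col_datetime(),
      site_id = readr::col_character(),
      stratum = readr::col_character(),
      variable = readr::col_character(),
      value = readr::col_double()
    ),
    what = "loggers"
  )
  check_enum(df$stratum, STRATA, "stratum")
  check_enum(df$variable, LOGGER_VARIABLES, "variable")
  neg <- df$variable == "light_lux" & df$value < 0
  if (any(neg)) {
    abort(paste0(
      "negative light_lux value at data line(s): ",
      paste(which(neg) + 1L, collapse = ", ")
    ))
  }
  key <- paste(df$timestamp, df$site_id, df$stratum, df$variable)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate (timestamp, site_id, stratum, variable) at data line(s): ",
      paste(which(duplicated(key)) + 1L, collapse = ", ")
    ))
  }
  dplyr::mutate(df, hour = hour_of(.data$timestamp))
}

#' Read the trap-site table
#'
#' Expected columns: `site_id,habitat,canopy_height_m,understory_height_m`.
#' Every site carries exactly one canopy and one understory trap; the two trap
#' heights are recorded per site.
#'
#' @param path Path to a sites CSV.
#' @return A tibble of validated sites.
#' @export
read_sites <- function(path) {
  df <- read_checked_csv(
    path,
    cols = readr::cols(
      site_id = readr::col_character(),
      habitat = readr::col_character(),
      canopy_height_m = readr::col_double(),
      understory_height_m = readr::col_double()
    ),
    what = "sites"
  )
  check_enum(df$habitat, HABITATS, "habitat")
  if (anyDuplicated(df$site_id)) {
    abort("duplicate site_id in site table")
  }
  df
}

#' Read species canopy-tendency priors
#'
#' Reads the species-level forest canopy tendency (FCT) prior table: normal
#' distributions on the logit scale summarising canopy-probability posteriors
#' from a previous study. Species absent from the table are imputed
#' hierarchically by tribe at model-fitting time.
#'
#' @param path Path to a CSV with columns `species,tribe,logit_mean,logit_sd`.
#' @return A tibble with a `source` column set to `"prior_study"`.
#' @export
read_fct_priors <- function(path) {
  df <- read_checked_csv(
    path,
    cols = readr::cols(
      species = readr::col_character(),
      tribe = readr::col_character(),
      logit_mean = readr::col_double(),
      logit_sd = readr::col_double()
    ),
    what = "fct_priors"
  )
  if (any(df$logit_sd <= 0)) {
    abort("logit_sd must be > 0 for every species prior")
  }
  if (anyDuplicated(df$species)) {
    abort("duplicate species in FCT prior table")
  }
  dplyr::mutate(df, source = "prior_study")
}

#' Write pipeline tables as CSV
#'
#' Thin wrappers around [readr::write_csv()] using the package's CSV dialect
#' (UTF-8, header row, ISO-8601 timestamps), chosen so that a write followed
#' by the matching reader is an identity.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @name write-tables
NULL

#' @rdname write-tables
#' @export
write_captures <- function(x, path) {
  out <- dplyr::mutate(x,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(
    dplyr::select(
      out, "individual_id", "timestamp", "site_id", "habitat",
      "stratum", "species", "tribe"
    ),
    path
  )
  invisible(x)
}

#' @rdname write-tables
#' @export
write_loggers <- function(x, path) {
  out <- dplyr::mutate(x,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(
    dplyr::select(out, "timestamp", "site_id", "stratum", "variable", "value"),
    path
  )
  invisible(x)
}

#' @rdname write-tables
#' @export
write_sites <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, "site_id", "habitat", "canopy_height_m", "understory_height_m"),
    path
  )
  invisible(x)
}

#' @rdname write-tables
#' @export
write_fct_priors <- function(x, path) {
  readr::write_csv(
    dplyr::select(x, "species", "tribe", "logit_mean", "logit_sd"),
    path
  )
  invisible(x)
}

#' Log transformation for light
#'
#' Light filtered through vegetation is the product of many attenuation events
#' and insect photoreceptors respond to multiplicative changes, so light is
#' analysed as `ln(lux + offset)`. The offset keeps night-time zeros defined;
#' the natural log with offset 1 is this package's convention.
#'
#' @param lux Non-negative light readings in lux.
#' @param offset Positive offset added before taking the log (default 1).
#' @return `ln(lux + offset)`, strictly increasing in `lux`.
#' @export
#' @examples
#' log_light(c(0, exp(1) - 1, 1000))
log_light <- function(lux, offset = 1) {
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0) {
    abort("offset must be a single positive number")
  }
  if (any(lux < 0, na.rm = TRUE)) {
    abort("lux must be non-negative")
  }
  log(lux + offset)
}

#' Hourly habitat/stratum summaries of temperature and light
#'
#' Collapses logger records to per-(habitat, stratum, variable, hour-of-day)
#' means with 95% confidence intervals, the standard way of displaying the
#' diurnal microclimate contrast between canopy and understory traps. Light is
#' log-transformed (variable renamed `log_light`) unless `transform_light` is
#' `FALSE`.
#'
#' @param loggers Logger records (see [read_loggers()]).
#' @param sites Site table used to map `site_id` to habitat.
#' @param transform_light Apply [log_light()] to `light_lux` records?
#' @param offset Offset passed to [log_light()].
#' @return A tibble `habitat, stratum, variable, hour, mean, ci_half_width, n`.
#'   Cells with a single record get `ci_half_width = 0` and are counted in a
#'   message; empty cells are simply absent.
#' @export
hourly_summary <- function(loggers, sites, transform_light = TRUE, offset = 1) {
  assert_columns(loggers, c("timestamp", "site_id", "stratum", "variable", "value"), "loggers")
  assert_columns(sites, c("site_id", "habitat"), "sites")
  df <- dplyr::inner_join(loggers, dplyr::select(sites, "site_id", "habitat"), by = "site_id")
  if (transform_light) {
    is_light <- df$variable == "light_lux"
    df$value[is_light] <- log_light(df$value[is_light], offset)
    df$variable[is_light] <- "log_light"
  }
  if (!"hour" %in% names(df)) df$hour <- hour_of(df$timestamp)
  out <- df |>
    dplyr::group_by(.data$habitat, .data$stratum, .data$variable, .data$hour) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_half_width = ifelse(dplyr::n() > 1,
        1.96 * stats::sd(.data$value) / sqrt(dplyr::n()), 0
      ),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$habitat, .data$stratum, .data$variable, .data$hour)
  singletons <- sum(out$n == 1)
  if (singletons > 0) {
    inform(paste0(
      singletons, " summary cell(s) have a single record; ",
      "their CI half-widths are reported as 0"
    ))
  }
  out
}

#' Observed abiotic series by habitat
#'
#' Builds the observed hourly abiotic series on the analysis scale
#' (temperature in degrees C, light as `log_light`), keyed by habitat rather
#' than site: all loggers of one habitat-stratum combination inform one shared
#' series, matching how the state-space model pools sites.
#'
#' @inheritParams hourly_summary
#' @return A tibble `habitat, stratum, variable, timestamp, hour, value, n_obs`
#'   with one row per observed series-hour.
#' @export
abiotic_series <- function(loggers, sites, offset = 1) {
  assert_columns(loggers, c("timestamp", "site_id", "stratum", "variable", "value"), "loggers")
  df <- dplyr::inner_join(loggers, dplyr::select(sites, "site_id", "habitat"), by = "site_id")
  is_light <- df$variable == "light_lux"
  df$value[is_light] <- log_light(df$value[is_light], offset)
  df$variable[is_light] <- "log_light"
  df$timestamp <- floor_hour(df$timestamp)
  df |>
    dplyr::group_by(.data$habitat, .data$stratum, .data$variable, .data$timestamp) |>
    dplyr::summarise(value = mean(.data$value), n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(hour = hour_of(.data$timestamp)) |>
    dplyr::arrange(.data$habitat, .data$stratum, .data$variable, .data$timestamp)
}

#' Attach abiotic contrasts to captures
#'
#' For each capture, computes the canopy-minus-understory contrasts of the
#' capture's habitat at the capture hour: `LD` (log-light difference) and `TD`
#' (temperature difference). Contrasts that cannot be resolved (no logger
#' record for either stratum at that habitat-hour) are flagged missing (`NA`)
#' rather than dropped; the joint model can impute them later.
#'
#' @param captures Capture records (see [read_captures()]).
#' @param abiotic Observed or posterior abiotic series as produced by
#'   [abiotic_series()] (columns `habitat, stratum, variable, timestamp, value`).
#' @return `captures` with columns `LD`, `TD` appended (possibly `NA`).
#' @export
attach_abiotic <- function(captures, abiotic) {
  assert_columns(captures, c("timestamp", "habitat"), "captures")
  assert_columns(abiotic, c("habitat", "stratum", "variable", "timestamp", "value"), "abiotic")
  contrasts <- abiotic |>
    dplyr::select("habitat", "stratum", "variable", "timestamp", "value") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "value") |>
    dplyr::mutate(contrast = .data$canopy - .data$understory) |>
    dplyr::select("habitat", "variable", "timestamp", "contrast") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "contrast")
  for (col in ABIOTIC_VARIABLES) {
    if (!col %in% names(contrasts)) contrasts[[col]] <- NA_real_
  }
  contrasts <- dplyr::rename(contrasts, LD = "log_light", TD = "temperature_C")
  out <- captures |>
    dplyr::mutate(.hour_ts = floor_hour(.data$timestamp)) |>
    dplyr::left_join(contrasts, by = c("habitat" = "habitat", ".hour_ts" = "timestamp")) |>
    dplyr::select(-".hour_ts")
  n_miss <- sum(is.na(out$LD) | is.na(out$TD))
  if (n_miss > 0) {
    warn(paste0(
      n_miss, " capture(s) could not be matched to both abiotic contrasts; ",
      "LD/TD flagged missing"
    ))
  }
  out
}

#' Prepare the mediation-model observation table
#'
#' Joins captures with abiotic contrasts and derives the model variables:
#' `FE` (forest-edge exposure; ridge and valley collapse to 0), `CAN`
#' (canopy-capture outcome), `LD` and `TD` (possibly missing).
#'
#' @param captures Capture records.
#' @param abiotic Optional abiotic series for [attach_abiotic()]; when `NULL`,
#'   `captures` must already carry `LD` and `TD` columns (or they are set
#'   entirely missing).
#' @return A tibble with columns `FE`, `CAN`, `LD`, `TD`, `species`, `tribe`
#'   plus the original capture identifiers.
#' @export
prepare_mediation_data <- function(captures, abiotic = NULL) {
  if (!is.null(abiotic)) {
    captures <- attach_abiotic(captures, abiotic)
  }
  if (!all(c("LD", "TD") %in% names(captures))) {
    captures$LD <- NA_real_
    captures$TD <- NA_real_
  }
  dplyr::mutate(
    captures,
    FE = fe_indicator(.data$habitat),
    CAN = can_indicator(.data$stratum)
  )
}

# ---- internal helpers -------------------------------------------------------

# ISO-8601 datetimes, with date-only entries assigned `default_hour`.
# Formats are tried element-wise so one bad row cannot poison the others.
parse_timestamp <- function(x, default_hour) {
  x <- stringr::str_trim(x)
  dt <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")) {
    need <- is.na(dt)
    if (!any(need)) break
    dt[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  date_only <- is.na(dt) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(date_only)) {
    dt[date_only] <- as.POSIXct(x[date_only], tz = "UTC") + default_hour * 3600
  }
  list(value = dt, assumed = date_only, failed = is.na(dt))
}

floor_hour <- function(timestamp) {
  as.POSIXct(trunc(as.POSIXct(timestamp, tz = "UTC"), units = "hours"), tz = "UTC")
}

read_checked_csv <- function(path, cols, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- readr::read_csv(path, col_types = cols, progress = FALSE)
  expected <- names(cols$cols)
  assert_columns(df, expected, what)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    # problems() rows are file lines (header included)
    abort(paste0(
      "malformed ", what, " row(s) at line(s): ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  tibble::as_tibble(df)
}

check_enum <- function(x, levels, name) {
  bad <- !(x %in% levels)
  if (any(bad)) {
    abort(paste0(
      "invalid ", name, " value(s) ",
      paste(unique(x[bad]), collapse = ", "),
      " at data line(s): ", paste(head(which(bad), 10) + 1L, collapse = ", ")
    ))
  }
  invisible(x)
}
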