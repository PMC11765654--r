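HABITATS <- c("edge", "ridge", "valley")
STRATA <- c("canopy", "understory")
LOGGER_VARIABLES <- c("temperature_C", "light_lux")

# Analysis-scale variable names: lux is log-transformed on ingestion.
ABIOTIC_VARIABLES <- c("temperature_C", "log_light")

#' Forest-edge indicator
#'
#' Maps the three-level habitat classification onto the binary exposure used by
#' the mediation model: edge sites are the exposed group (`1`), ridge and
#' valley sites together form the forest reference group (`0`).
#'
#' @param habitat Character or factor vector with values `"edge"`, `"ridge"`
#'   or `"valley"`.
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' fe_indicator(c("edge", "ridge", "valley"))
fe_indicator <- function(habitat) {
  habitat <- as.character(habitat)
  bad <- setdiff(unique(habitat), HABITATS)
  if (length(bad) > 0) {
    abort(paste0("unknown habitat value(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(habitat == "edge")
}

#' Canopy-capture indicator
#'
#' @param stratum Character or factor vector with values `"canopy"` or
#'   `"understory"`.
#' @return Integer vector: 1 for canopy captures, 0 for understory.
#' @export
can_indicator <- function(stratum) {
  stratum <- as.character(stratum)
  bad <- setdiff(unique(stratum), STRATA)
  if (length(bad) > 0) {
    abort(paste0("unknown stratum value(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(stratum == "canopy")
}

# Derive a stream of child seeds from one master seed, keeping them valid
# 32-bit R integers. Deterministic and collision-free for k <= 1000.
derive_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, k >= 1)
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(k)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# hour-of-day in 0..23 from a POSIXct, local-time convention
hour_of <- function(timestamp) {
  as.POSIXlt(timestamp, tz = "UTC")$hour
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

genus_of <- function(species) {
  stringr::str_split_i(stringr::str_trim(species), "\\s+", 1)
}
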