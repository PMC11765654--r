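#' Species-by-stratum capture counts
#'
#' Aggregates capture records into per-species counts by habitat class and
#' stratum: `EC` (edge canopy), `EU` (edge understory), `FC` (forest canopy),
#' `FU` (forest understory). Ridge and valley sites are combined as forest.
#'
#' @param captures Capture records (see [read_captures()]).
#' @return A tibble `species, EC, EU, FC, FU`, one row per species.
#' @export
aggregate_stratum_counts <- function(captures) {
  assert_columns(captures, c("species", "habitat", "stratum"), "captures")
  captures |>
    dplyr::mutate(
      cell = paste0(
        ifelse(fe_indicator(.data$habitat) == 1, "E", "F"),
        ifelse(can_indicator(.data$stratum) == 1, "C", "U")
      )
    ) |>
    dplyr::count(.data$species, .data$cell) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n", values_fill = 0L) |>
    add_missing_count_cols() |>
    dplyr::select("species", "EC", "EU", "FC", "FU") |>
    dplyr::arrange(.data$species)
}

#' Read a species-by-stratum counts table
#'
#' @param path CSV with columns `species,EC,EU,FC,FU`.
#' @return A validated counts tibble.
#' @export
read_stratum_counts <- function(path) {
  df <- read_checked_csv(
    path,
    cols = readr::cols(
      species = readr::col_character(),
      EC = readr::col_integer(),
      EU = readr::col_integer(),
      FC = readr::col_integer(),
      FU = readr::col_integer()
    ),
    what = "stratum_counts"
  )
  if (any(df[c("EC", "EU", "FC", "FU")] < 0)) abort("counts must be non-negative")
  if (anyDuplicated(df$species)) abort("duplicate species in counts table")
  df
}

#' Packaged nymphalid counts fixture
#'
#' Canopy/understory capture counts by habitat class for the 41 fruit-feeding
#' nymphalid species recorded at both edge and forest locations in a
#' mark-release trapping study at La Selva Biological Station, Costa Rica.
#' Ships with the package so the stratification analysis is reproducible
#' without any download.
#'
#' @return A counts tibble (see [read_stratum_counts()]).
#' @export
#' @examples
#' nymphalid_counts() |> delta_edge()
nymphalid_counts <- function() {
  read_stratum_counts(
    system.file("extdata", "nymphalid_stratum_counts.csv",
      package = "stratmed", mustWork = TRUE
    )
  )
}

#' Keep species common to edge and forest
#'
#' @param counts Counts tibble.
#' @return Rows with at least one capture at the edge and one in the forest.
#' @export
common_species <- function(counts) {
  assert_counts(counts)
  dplyr::filter(counts, (.data$EC + .data$EU) > 0, (.data$FC + .data$FU) > 0)
}

#' Canopy probability
#'
#' The probability that a capture of a species falls in the canopy trap:
#' canopy counts divided by total counts.
#'
#' @param canopy,understory Non-negative counts (vectorised).
#' @return `canopy / (canopy + understory)`.
#' @export
#' @examples
#' canopy_probability(14, 12)
canopy_probability <- function(canopy, understory) {
  if (any(canopy < 0) || any(understory < 0)) abort("counts must be non-negative")
  total <- canopy + understory
  if (any(total == 0)) {
    abort("canopy_probability undefined for zero total counts; filter those species first")
  }
  canopy / total
}

#' Delta-edge index
#'
#' For each species present in both habitats, computes the edge and forest
#' canopy probabilities and their difference, delta edge = forest canopy
#' probability minus edge canopy probability. Positive values indicate a
#' decreased canopy probability at the edge (the species descends). Ties
#' (delta edge exactly 0) are classed as `nonpositive`, the convention used in
#' the sign test.
#'
#' @param counts Counts tibble (`species, EC, EU, FC, FU`).
#' @return A tibble adding `genus, edge_canopy_prob, forest_canopy_prob,
#'   delta_edge, sign_class`.
#' @export
delta_edge <- function(counts) {
  assert_counts(counts)
  counts <- common_species(counts)
  if (nrow(counts) == 0) abort("no species present in both habitats")
  dplyr::mutate(
    counts,
    genus = genus_of(.data$species),
    edge_canopy_prob = canopy_probability(.data$EC, .data$EU),
    forest_canopy_prob = canopy_probability(.data$FC, .data$FU),
    delta_edge = .data$forest_canopy_prob - .data$edge_canopy_prob,
    sign_class = factor(
      ifelse(.data$delta_edge > 0, "positive", "nonpositive"),
      levels = c("positive", "nonpositive")
    )
  )
}

#' Remove understory-specialist genera
#'
#' Sensitivity filter: drops genera known to be strict understory residents,
#' whose inclusion cannot inform a canopy-to-understory shift.
#'
#' @param rows A tibble with a `species` column (counts or delta-edge rows).
#' @param genera Character vector of genera to drop.
#' @return `rows` without the listed genera.
#' @export
filter_understory_genera <- function(rows,
                                     genera = c("Caligo", "Eryphanis", "Taygetis")) {
  assert_columns(rows, "species", "rows")
  dplyr::filter(rows, !(genus_of(.data$species) %in% genera))
}

#' Minimum-count sensitivity filter
#'
#' Keeps species with at least `min_per_habitat` individuals observed at the
#' edge and at least `min_per_habitat` in the forest, removing species whose
#' canopy probabilities rest on very few captures.
#'
#' @param rows A tibble with `EC, EU, FC, FU` columns.
#' @param min_per_habitat Minimum per-habitat total (default 3).
#' @return Filtered rows.
#' @export
filter_min_counts <- function(rows, min_per_habitat = 3) {
  assert_counts(rows)
  dplyr::filter(
    rows,
    (.data$EC + .data$EU) >= min_per_habitat,
    (.data$FC + .data$FU) >= min_per_habitat
  )
}

#' Sign G-test for an excess of positive delta-edge species
#'
#' Likelihood-ratio goodness-of-fit test of the observed split of species into
#' positive versus nonpositive delta edge against the null 50:50 expectation:
#' `G = 2 * sum(O * ln(O/E))` over the two sign classes with `E = n/2`,
#' compared to a chi-square distribution with 1 degree of freedom. Zero cells
#' contribute 0 (the `x ln x` limit), so the statistic is defined for all
#' splits.
#'
#' @param n_positive Number of species with positive delta edge.
#' @param n_total Total number of species tested.
#' @return A one-row tibble `n_species, n_positive, G, df, p`.
#' @export
#' @examples
#' g_test_sign(28, 41)
g_test_sign <- function(n_positive, n_total) {
  if (length(n_positive) != 1 || length(n_total) != 1) {
    abort("n_positive and n_total must be single integers")
  }
  if (n_total < 1) abort("n_total must be at least 1")
  if (n_positive < 0 || n_positive > n_total) {
    abort("n_positive must lie in [0, n_total]")
  }
  observed <- c(n_positive, n_total - n_positive)
  expected <- rep(n_total / 2, 2)
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  G <- 2 * sum(terms)
  tibble::tibble(
    n_species = as.integer(n_total),
    n_positive = as.integer(n_positive),
    G = G,
    df = 1L,
    p = stats::pchisq(G, df = 1, lower.tail = FALSE)
  )
}

#' Full sign-test suite with sensitivity filters
#'
#' Runs the sign G-test three ways: on all species common to edge and forest;
#' after removing the understory-specialist genera; and after additionally
#' applying the minimum per-habitat count filter. Filters are applied
#' cumulatively, in that order.
#'
#' @param counts Counts tibble (defaults expect the packaged fixture layout).
#' @param genera Understory genera removed in the second test.
#' @param min_per_habitat Minimum per-habitat count for the third test.
#' @return A list with `delta` (the delta-edge table for all common species)
#'   and `tests` (a tibble with one row per test: `test, n_species,
#'   n_positive, G, df, p`).
#' @export
#' @examples
#' gtest_suite(nymphalid_counts())$tests
gtest_suite <- function(counts,
                        genera = c("Caligo", "Eryphanis", "Taygetis"),
                        min_per_habitat = 3) {
  rows_all <- delta_edge(counts)
  rows_genera <- filter_understory_genera(rows_all, genera)
  rows_min <- filter_min_counts(rows_genera, min_per_habitat)
  run <- function(rows, label) {
    dplyr::mutate(
      g_test_sign(sum(rows$sign_class == "positive"), nrow(rows)),
      test = label, .before = 1
    )
  }
  tests <- dplyr::bind_rows(
    run(rows_all, "all_common_species"),
    run(rows_genera, "understory_genera_removed"),
    run(rows_min, "min_count_filter")
  )
  list(delta = rows_all, tests = tests)
}

# ---- internal ---------------------------------------------------------------

assert_counts <- function(df) {
  assert_columns(df, c("species", "EC", "EU", "FC", "FU"), "counts")
  invisible(df)
}

add_missing_count_cols <- function(df) {
  for (col in c("EC", "EU", "FC", "FU")) {
    if (!col %in% names(df)) df[[col]] <- 0L
  }
  df
}
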