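#' Plot hourly abiotic summaries
#'
#' Mean temperature and log-light by hour of day, with 95% confidence
#' interval bars, coloured by stratum and facetted by habitat and variable —
#' the standard display of the diurnal canopy/understory contrast.
#'
#' @param summary Output of [hourly_summary()].
#' @return A ggplot object.
#' @export
plot_hourly_summary <- function(summary) {
  assert_columns(summary, c("habitat", "stratum", "variable", "hour", "mean", "ci_half_width"),
    "summary"
  )
  ggplot2::ggplot(
    summary,
    ggplot2::aes(
      x = .data$hour, y = .data$mean,
      colour = .data$stratum, group = .data$stratum
    )
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$ci_half_width,
        ymax = .data$mean + .data$ci_half_width
      ),
      width = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$variable),
      cols = ggplot2::vars(.data$habitat), scales = "free_y"
    ) +
    ggplot2::labs(x = "hour of day", y = NULL, colour = "stratum") +
    ggplot2::theme_minimal()
}

#' Plot the delta-edge distribution
#'
#' Dot plot of per-species delta-edge values (forest minus edge canopy
#' probability), sorted, coloured by sign class.
#'
#' @param delta Output of [delta_edge()].
#' @return A ggplot object.
#' @export
plot_delta_edge <- function(delta) {
  assert_columns(delta, c("species", "delta_edge", "sign_class"), "delta")
  ggplot2::ggplot(
    delta,
    ggplot2::aes(
      x = .data$delta_edge,
      y = stats::reorder(.data$species, .data$delta_edge),
      colour = .data$sign_class
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delta edge", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of the causal effect decomposition
#'
#' Posterior means with 50% (thick) and 95% (thin) credible intervals for the
#' six effects.
#'
#' @param object An [effect_decomposition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_estimates <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(EFFECT_NAMES))
  ggplot2::ggplot(td, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$conf.low.95, xend = .data$conf.high.95, yend = .data$term),
      linewidth = 0.4
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$conf.low.50, xend = .data$conf.high.50, yend = .data$term),
      linewidth = 1.4
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 2) +
    ggplot2::labs(x = "effect on canopy probability", y = NULL) +
    ggplot2::theme_minimal()
}
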