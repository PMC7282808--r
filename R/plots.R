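#' Plot a population remapping profile
#'
#' Beta density of rate-modulation extents with the classification
#' thresholds drawn as dotted lines.
#'
#' @param object a [remap_profile()].
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.remap_profile <- function(object, ...) {
  x <- seq(0.001, 0.999, length.out = 400)
  df <- tibble::tibble(extent = x, density = stats::dbeta(x, object$a, object$b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$extent, y = .data$density)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_vline(
      xintercept = c(object$t_low, object$t_high),
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = "rate-modulation extent",
      y = "density",
      title = sprintf(
        "Beta(%.3g, %.3g), evidence ratio %.3g",
        object$a, object$b, object$ratio
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a protocol result table
#'
#' A generic view of the tidy result schema: trajectories (value against
#' step) when steps are present, otherwise per-condition bars. Facetted
#' by quantity.
#'
#' @param object a result tibble from [run_protocol()].
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.statemap_result <- function(object, ...) {
  has_steps <- any(!is.na(object$step))
  base <- ggplot2::ggplot(object)
  p <- if (has_steps && length(unique(stats::na.omit(object$step))) > 1) {
    base +
      ggplot2::aes(
        x = .data$step, y = .data$value,
        colour = .data$condition, group = .data$condition
      ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  } else {
    base +
      ggplot2::aes(x = .data$condition, y = .data$value) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  }
  p +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(title = attr(object, "protocol")) +
    ggplot2::theme_minimal()
}

#' Plot the population heterogeneity curve
#'
#' @param curve output of [heterogeneity_curve()].
#' @return a ggplot object.
#' @export
plot_heterogeneity_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    curve[, c("ratio", "mean_extent", "complete_remap", "heterogeneity", "uncertainty")],
    -"ratio",
    names_to = "summary", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~summary, scales = "free_y") +
    ggplot2::labs(x = "evidence ratio") +
    ggplot2::theme_minimal()
}
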