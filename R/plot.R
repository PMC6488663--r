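#' Phase-plane plot of an evolutionary trajectory
#'
#' Mean mobility score against mean neighbourhood score, one point per
#' generation coloured by generation index - the phase-plane view in which
#' the coward/explorer/dodger succession appears as three transitions.
#'
#' @param object A `herd_evolution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot herd_evolution
#' @export
autoplot.herd_evolution <- function(object, ...) {
  g <- object$generations
  ggplot2::ggplot(g, ggplot2::aes(x = .data$mean_S_N, y = .data$mean_S_M,
                                  colour = .data$generation)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "mean neighbourhood score",
                  y = "mean mobility score", colour = "generation") +
    ggplot2::theme_minimal()
}

#' Conditional leave-probability profile plot
#'
#' @param profile A profile tibble from [conditional_profile()] or the
#'   `profile` element of a `herd_generation`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$n, y = .data$probability)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_x_continuous(breaks = profile$n) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "neighbourhood size n",
                  y = "P(leave cell | n)") +
    ggplot2::theme_minimal()
}

#' Final lattice occupancy plot
#'
#' @param object A `herd_generation`.
#' @param ... Unused.
#' @return A ggplot object (occupied cells as tiles; y increases downwards
#'   to match lattice row order).
#' @method autoplot herd_generation
#' @export
autoplot.herd_generation <- function(object, ...) {
  ag <- lattice_agents(object$final_lattice)
  ggplot2::ggplot(ag, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Squeeze-through scan summary plot
#'
#' Final-state score distributions per `p_transit` value: violins of the
#' replicate outcomes, revealing the bistable region where both collective
#' motion and stationary herds are reached.
#'
#' @param scan A tibble from [scan_ptransit()].
#' @param metric `"mean_S_N"` or `"mean_S_M"`.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, metric = c("mean_S_N", "mean_S_M")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(scan, ggplot2::aes(x = factor(.data$p_transit),
                                     y = .data[[metric]])) +
    ggplot2::geom_violin(scale = "width", fill = "grey80") +
    ggplot2::geom_jitter(width = 0.1, size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "p_transit", y = metric) +
    ggplot2::theme_minimal()
}
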