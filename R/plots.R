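#' @method autoplot utility_trajectory
#' @export
autoplot.utility_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$utility)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time (years)", y = "Utility weight") +
    ggplot2::coord_cartesian(xlim = c(0, attr(object, "horizon"))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of a sensitivity table
#'
#' Plots each scenario's (delta QALY, delta cost) point on the
#' cost-effectiveness plane, with the willingness-to-pay threshold as a
#' line through the origin; points below the line are acceptable at that
#' threshold.
#'
#' @param table A `sensitivity_table` from [run_sensitivity()] or
#'   [run_cua()].
#' @param wtp_threshold Euro per QALY (default 11,200).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(table, wtp_threshold = 11200) {
  stopifnot(inherits(table, "sensitivity_table") || is.data.frame(table))
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = wtp_threshold, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2.5, colour = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = .data$scenario),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = expression(Delta ~ "QALY"),
                  y = expression(Delta ~ "Cost (EUR)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot cua_report
#' @export
autoplot.cua_report <- function(object, ...) {
  if (!is.null(object$trajectories)) {
    ggplot2::ggplot(object$trajectories,
                    ggplot2::aes(x = .data$time, y = .data$utility,
                                 colour = .data$arm)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "Time (years)", y = "Mean utility weight",
                    colour = "Arm") +
      ggplot2::theme_minimal()
  } else {
    plot_ce_plane(object$sensitivity_table, object$meta$wtp_threshold)
  }
}
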