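#' Plot annual coverage
#'
#' Line plot of the proportion of the yearly population with at least one
#' harmonised entry, by branch. Requires ggplot2.
#'
#' @param coverage output of [annual_coverage()].
#' @return A ggplot object.
#' @export
plot_annual_coverage <- function(coverage) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "bmirrda_plot_error")
  }
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$year, y = .data$proportion,
                               colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, NA)) +
    ggplot2::labs(x = "year", y = "population with a BMI record",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot preservation-window coverage
#'
#' Bar chart of coverage under each look-back preservation window, by branch.
#'
#' @param preservation output of [preservation_coverage()].
#' @return A ggplot object.
#' @export
plot_preservation <- function(preservation) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "bmirrda_plot_error")
  }
  pres <- preservation
  pres$window_label <- factor(pres$window_label,
                              levels = unique(pres$window_label))
  ggplot2::ggplot(pres,
                  ggplot2::aes(x = .data$window_label, y = .data$proportion,
                               fill = .data$branch)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "preservation window", y = "coverage", fill = NULL) +
    ggplot2::theme_minimal()
}
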