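#' Plot a power table
#'
#' Rejection proportions per test, faceted by data format, with 95%
#' Monte-Carlo error bars and the nominal level marked when the table comes
#' from a null scenario.
#'
#' @param object A `power_table` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.power_table <- function(object, ...) {
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$test, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$proportion - 1.96 * .data$mc_se, 0),
                   ymax = pmin(.data$proportion + 1.96 * .data$mc_se, 1)),
      width = 0.3) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~format) +
    ggplot2::labs(x = NULL, y = "rejection proportion") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.power_table
#' @param x A `power_table`.
#' @param y Unused.
#' @export
plot.power_table <- function(x, y, ...) print(autoplot.power_table(x, ...))

#' Plot power curves across a scenario battery
#'
#' @param results Tibble binding [estimate_power()] outputs with an added
#'   `scenario` column (one value per battery entry).
#' @param x Name of the column giving the swept parameter (default
#'   `"scenario"`).
#' @return A ggplot object.
#' @export
plot_power_curves <- function(results, x = "scenario") {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data[[x]], y = .data$proportion,
                               colour = .data$test, group = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~format) +
    ggplot2::labs(y = "power") +
    ggplot2::theme_bw()
}
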