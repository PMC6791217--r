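#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a virotherapy trajectory
#'
#' Time courses of uninfected tumor cells, infected tumor cells and free
#' virus, faceted by compartment (free scales: the populations span very
#' different magnitudes).
#'
#' @param object a \code{virotherapy_trajectory}.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.virotherapy_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, c("x", "y", "v"),
                              names_to = "compartment", values_to = "value")
  long$compartment <- factor(long$compartment, levels = c("x", "y", "v"),
                             labels = c("uninfected tumor cells (x)",
                                        "infected tumor cells (y)",
                                        "free virus (v)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = expression("population (" * 10^6 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a delay scan
#'
#' Oscillation amplitude against the delay, colored by classification; the
#' amplitude rises from zero at the Hopf point.
#'
#' @param object a \code{delay_scan} tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.delay_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$tau, .data$amplitude,
                               color = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(tau ~ "(days)"),
                  y = "late peak-to-trough amplitude of x",
                  color = NULL) +
    ggplot2::theme_minimal()
}
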