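#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prediction envelope
#'
#' Ribbon of the per-time-point band, with the reference trajectory overlaid
#' when present, faceted by output component. Optionally overlays observed
#' data points with error bars.
#'
#' @param object A `predq_envelope` (or `predq_lca` band).
#' @param data Optional `predq_data` to overlay.
#' @param log_y Use a log10 y-axis (natural for positive concentrations)?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predq_envelope <- function(object, data = NULL, log_y = FALSE, ...) {
  center_col <- if ("center" %in% names(object)) "center" else "reference"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "goldenrod", alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time", y = "output",
                  title = paste0("Prediction envelope (alpha = ",
                                 attr(object, "alpha"), ")"))
  if (!all(is.na(object[[center_col]]))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data[[center_col]]),
                                linewidth = 0.4)
  }
  if (!is.null(data)) {
    d <- dplyr::mutate(tibble::as_tibble(data),
                       component = as.character(.data$component))
    p <- p + ggplot2::geom_pointrange(
      data = d,
      ggplot2::aes(y = .data$value, ymin = .data$value - .data$sigma,
                   ymax = .data$value + .data$sigma),
      size = 0.2)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname autoplot.predq_envelope
#' @export
autoplot.predq_lca <- autoplot.predq_envelope

#' Plot a Q distribution
#'
#' Histogram of per-draw Q values on a log10 axis with the tight/uncertain
#' threshold `Q = 1` and the `Q_alpha` summary marked.
#'
#' @param object A `predq_qresult`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predq_qresult <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$q)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "q_alpha"), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Q", y = "draws",
                  title = paste0("Q distribution",
                                 if (!is.null(attr(object, "scenario_id")))
                                   paste0(" - ", attr(object, "scenario_id")),
                                 " (Q_", attr(object, "alpha"), " = ",
                                 signif(attr(object, "q_alpha"), 3), ")"))
}

#' Plot a perturbation scan
#'
#' One point per perturbation (parameter x direction) at its `Q_alpha`, on a
#' log10 axis, coloured by the tight/uncertain classification with the
#' threshold `Q = 1` marked.
#'
#' @param object A `predq_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predq_scan <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     label = paste0(.data$parameter, " ",
                                    ifelse(.data$direction == "up", "x", "/"),
                                    signif(attr(object, "factor"), 3)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$q_alpha,
                                  colour = .data$flag)) +
    ggplot2::geom_point(size = 2, shape = 8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(tight = "blue", uncertain = "red"),
                                 na.value = "grey") +
    ggplot2::labs(x = "perturbation", y = bquote(Q[alpha]),
                  title = "Parameter-perturbation scan")
}
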