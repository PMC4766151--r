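method_labels <- c(method1 = "all nodes (1/N)",
                   method2 = "largest component",
                   method3 = "active nodes")

#' Plot an overlap series
#'
#' Per-pair average topological overlap under the three normalisations,
#' with a dashed reference line at 1 (the theoretical ceiling a
#' well-behaved normalisation should respect).
#'
#' @param object An [overlap_series()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tn_overlap_series
#' @export
autoplot.tn_overlap_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(overlap_methods()),
                              names_to = "method", values_to = "overlap")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$overlap,
                                     colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(labels = method_labels) +
    ggplot2::labs(x = "consecutive pair m", y = "average topological overlap",
                  colour = "normalisation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tn_overlap_series
#' @param series An [overlap_series()] result.
#' @export
plot_overlap_series <- function(series, ...) autoplot(series, ...)

#' Plot a convergence curve
#'
#' Temporal correlation coefficient against series length as identical
#' copies of the last snapshot are appended.
#'
#' @param object A [convergence_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tn_convergence
#' @export
autoplot.tn_convergence <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$C,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = method_labels) +
    ggplot2::labs(x = "series length (snapshots)",
                  y = "temporal correlation coefficient",
                  colour = "normalisation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tn_convergence
#' @param curve A [convergence_curve()] result.
#' @export
plot_convergence <- function(curve, ...) autoplot(curve, ...)

#' Plot a window-length sweep
#'
#' Temporal correlation coefficient per method against the time-window
#' length used for aggregation.
#'
#' @param object A [sweep_window_lengths()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tn_sweep
#' @export
autoplot.tn_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "window_length",
                  dplyr::all_of(paste0("c_", overlap_methods()))),
    cols = -"window_length", names_to = "method", values_to = "C",
    names_prefix = "c_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_length, y = .data$C,
                                     colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = method_labels) +
    ggplot2::labs(x = "time-window length (days)",
                  y = "temporal correlation coefficient",
                  colour = "normalisation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tn_sweep
#' @param sweep A [sweep_window_lengths()] result.
#' @export
plot_sweep <- function(sweep, ...) autoplot(sweep, ...)
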