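#' Plot empirical versus null metric distributions
#'
#' Dot-and-error summaries of the focal node's metric under the empirical
#' network against the surrogate null distribution, one panel per metric —
#' the visual form of the ensemble z-score comparison.
#'
#' @param object A `null_ensemble_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_ensemble_report <- function(object, ...) {
  draws <- dplyr::bind_rows(
    dplyr::mutate(object$empirical, ensemble = "empirical"),
    dplyr::mutate(object$null, ensemble = paste0("null (", object$kind, ")")))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$ensemble, y = .data$value,
                                      colour = .data$ensemble)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl, geom = "pointrange",
                          colour = "black", linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("Node %s vs %s surrogates",
                                  object$focal, object$kind)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the steady/jammed phase map
#'
#' @param object A `phase_map`.
#' @param ... Unused.
#' @return A ggplot object: mean total contents against arrival rate,
#'   coloured by regime.
#' @export
autoplot.phase_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lambda, y = .data$mean_contents,
                               colour = .data$regime)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::labs(x = expression(lambda), y = "mean total contents",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Communication metric against in-degree
#'
#' The outlier view: each node's metric plotted against its in-degree with
#' the least-squares fit; nodes attracting more traffic than their
#' in-degree predicts sit far above the line. Highlighted nodes are
#' labelled.
#'
#' @param table A `metric_table`.
#' @param degrees A [node_degrees()] table.
#' @param metric Metric column to plot.
#' @param highlight Character vector of node labels to emphasize.
#' @return A ggplot object.
#' @export
plot_metric_vs_degree <- function(table, degrees,
                                  metric = c("arrivals", "mean_contents",
                                             "utilization"),
                                  highlight = character()) {
  metric <- match.arg(metric)
  df <- dplyr::inner_join(table, degrees, by = "node") |>
    dplyr::mutate(highlighted = .data$node %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_in, y = .data[[metric]])) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted), size = 1.5) +
    ggplot2::geom_text(data = ~ dplyr::filter(.x, .data$highlighted),
                       ggplot2::aes(label = .data$node),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "in-degree", y = metric) +
    ggplot2::theme_minimal()
}

#' Most-traversed connections as a bar chart
#'
#' @param traffic An edge-traffic table or matrix (see [top_k_edges()]).
#' @param k Number of edges to show.
#' @return A ggplot object.
#' @export
plot_top_edges <- function(traffic, k = 10L) {
  top <- top_k_edges(traffic, k) |>
    dplyr::mutate(edge = paste(.data$from, "→", .data$to))
  ggplot2::ggplot(top, ggplot2::aes(x = stats::reorder(.data$edge, .data$count),
                                    y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "traversals") +
    ggplot2::theme_minimal()
}
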