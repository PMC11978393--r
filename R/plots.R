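#' Plot an empirical power curve
#'
#' @param object A [size_power_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.riht_power_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$kappa, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(x = expression(kappa), y = "Empirical rejection rate") +
    ggplot2::ylim(0, 1)
}

#' Plot the ADMM objective trace of a fused-graphical-lasso fit
#'
#' @param object An `fgl_fit` fitted with `keep_trace = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fgl_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ADMM iteration", y = "Penalized objective")
}

#' Heatmap of entrywise precision-change evidence
#'
#' @param object An `mpde_result`.
#' @param ... Unused.
#' @return A ggplot of -log10 p-values over the channel grid.
#' @export
autoplot.mpde_result <- function(object, ...) {
  p <- nrow(object$pvalues)
  df <- tidyr::expand_grid(i = seq_len(p), j = seq_len(p))
  df$neglog_p <- -log10(pmax(as.vector(t(object$pvalues)),
                             .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$neglog_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p")
}

#' Bar chart of channel-selection frequencies
#'
#' @param object A [selection_frequency()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.channel_frequency <- function(object, ...) {
  df <- dplyr::mutate(object,
                      label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Channel", y = "Selection count") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of network degree centrality
#'
#' @param object A `centrality_report`.
#' @param ... Unused.
#' @return A ggplot with the top-ranked channels highlighted.
#' @export
autoplot.centrality_report <- function(object, ...) {
  df <- dplyr::mutate(object$degrees,
                      top = .data$label %in% object$top_k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$degree,
                                   fill = .data$top)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Channel", y = "Degree") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of null statistics against the standard normal density
#'
#' @param object A [null_distribution_study()] tibble.
#' @param ... Unused.
#' @return A ggplot faceted by matrix location.
#' @export
autoplot.mpde_null_study <- function(object, ...) {
  grid <- seq(-4, 4, length.out = 201)
  ref <- tidyr::expand_grid(location = unique(object$location), x = grid)
  ref$density <- stats::dnorm(ref$x)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70") +
    ggplot2::geom_line(data = ref,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "Standardized statistic", y = "Density")
}
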