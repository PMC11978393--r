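#' Tidy a RIHT test result
#'
#' @param x A `riht_result`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, calibration terms and
#'   decision.
#' @export
tidy.riht_result <- function(x, ...) {
  tibble::tibble(
    riht = x$riht, lambda = x$lambda, statistic = x$statistic,
    p.value = x$p_value, reject = x$reject,
    tr1 = x$tr1, tr2 = x$tr2, e2 = x$e2, plug_in = x$plug_in
  )
}

#' @rdname tidy.riht_result
#' @export
glance.riht_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 reject = x$reject, alpha = x$alpha, p = x$p,
                 n = sum(x$sizes), G = length(x$sizes))
}

#' Tidy a multi-epoch change-validation report
#'
#' @param x A `riht_change_report`.
#' @param ... Unused.
#' @return Tibble with an `overall` row followed by one row per adjacent
#'   epoch boundary tested.
#' @export
tidy.riht_change_report <- function(x, ...) {
  overall <- tibble::tibble(term = "overall", boundary = NA_integer_,
                            statistic = x$overall$statistic,
                            p_value = x$overall$p_value,
                            reject = x$overall$reject)
  if (nrow(x$pairwise) == 0L) return(overall)
  pw <- dplyr::mutate(x$pairwise,
                      term = paste0("epoch", .data$boundary, "_vs_",
                                    .data$boundary + 1L),
                      .before = 1L)
  dplyr::bind_rows(overall, pw[names(pw) %in% names(overall) |
                                 names(pw) == "term"])
}

#' Tidy a fused-graphical-lasso fit
#'
#' @param x An `fgl_fit`.
#' @param threshold Support threshold for the edge count.
#' @param ... Unused.
#' @return Tibble with one row per group: sample size, edge count, edge
#'   density.
#' @export
tidy.fgl_fit <- function(x, threshold = 1e-6, ...) {
  p <- x$problem$p
  dplyr::bind_rows(lapply(seq_len(x$problem$G), function(g) {
    edges <- sum(fgl_support(x, g, threshold)) / 2
    tibble::tibble(group = g, n = x$problem$sample_sizes[g],
                   edges = edges,
                   density = edges / (p * (p - 1) / 2))
  }))
}

#' @rdname tidy.fgl_fit
#' @export
glance.fgl_fit <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$hyper$lambda1, lambda2 = x$hyper$lambda2,
    iterations = x$iterations, converged = x$converged,
    relative_change = x$relative_change,
    objective = if (length(x$objective_trace)) {
      x$objective_trace[length(x$objective_trace)]
    } else NA_real_
  )
}

#' Tidy an entrywise precision-change test
#'
#' @param x An `mpde_result`.
#' @param all If `TRUE`, return every upper-triangle location; default only
#'   the significant edges.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `statistic`, `p_value`.
#' @export
tidy.mpde_result <- function(x, all = FALSE, ...) {
  if (!all) return(x$edges)
  ut <- which(upper.tri(x$stat), arr.ind = TRUE)
  tibble::tibble(i = ut[, 1L], j = ut[, 2L],
                 statistic = x$stat[ut], p_value = x$pvalues[ut])
}

#' @rdname tidy.mpde_result
#' @export
glance.mpde_result <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x$edges), alpha_edge = x$alpha_edge,
                 n_eff = x$n_eff, p = nrow(x$stat))
}

#' Tidy a hyperparameter-tuning result
#'
#' @param x An `fgl_tune`.
#' @param ... Unused.
#' @return The score surface (AIC search) or the hyperparameter trajectory
#'   (data-driven rule).
#' @export
tidy.fgl_tune <- function(x, ...) {
  if (!is.null(x$score_surface)) x$score_surface else x$trajectory
}

#' @rdname tidy.fgl_tune
#' @export
glance.fgl_tune <- function(x, ...) {
  tibble::tibble(method = x$method, lambda1 = x$lambda1,
                 lambda2 = x$lambda2, rho1 = x$rho1, rho2 = x$rho2,
                 score = x$score, n_solves = x$n_solves)
}

#' Tidy a channel-selection result
#'
#' @param x A `channel_selection`.
#' @param ... Unused.
#' @return Tibble with one row per channel: coefficient and selection flag.
#' @export
tidy.channel_selection <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$coefficients), label = x$labels,
                 coefficient = unname(x$coefficients),
                 selected = seq_along(x$coefficients) %in% x$selected)
}

#' Tidy a degree-centrality report
#'
#' @param x A `centrality_report`.
#' @param ... Unused.
#' @return The per-channel degree tibble.
#' @export
tidy.centrality_report <- function(x, ...) x$degrees
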