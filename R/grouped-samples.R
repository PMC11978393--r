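#' Bundle several groups of multichannel observations
#'
#' Container for `G` groups of p-dimensional observations, e.g. the epochs of
#' a multichannel EEG recording, or the two sides of a pre/post-stimulus
#' comparison. Rows are observations (time points), columns are channels.
#'
#' @param groups A list of numeric matrices, all with the same number of
#'   columns `p` and at least two rows each. A single matrix is promoted to a
#'   one-group list.
#' @param labels Optional character vector of channel names, length `p`.
#'   Defaults to the column names of the first group when present.
#' @return An object of class `grouped_samples`: a list with elements
#'   `groups`, `labels`, `sizes` (the per-group row counts), `n`, `p` and `G`.
#' @examples
#' gs <- grouped_samples(list(matrix(rnorm(20), 10, 2), matrix(rnorm(12), 6, 2)))
#' gs$sizes
#' @export
grouped_samples <- function(groups, labels = NULL) {
  if (is.matrix(groups)) groups <- list(groups)
  if (!is.list(groups) || length(groups) == 0L) {
    stop("`groups` must be a non-empty list of numeric matrices.", call. = FALSE)
  }
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  p <- ncol(groups[[1L]])
  if (p < 1L) stop("Groups must have at least one column.", call. = FALSE)
  widths <- vapply(groups, ncol, integer(1))
  if (any(widths != p)) {
    stop("All groups must share the same number of columns; got widths ",
         paste(widths, collapse = ", "), ".", call. = FALSE)
  }
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes < 2L)) {
    stop("Every group needs at least 2 observations (rows).", call. = FALSE)
  }
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    stop("Non-finite entries found in the observation matrices.", call. = FALSE)
  }
  if (is.null(labels)) labels <- colnames(groups[[1L]])
  if (!is.null(labels) && length(labels) != p) {
    stop("`labels` must have length p = ", p, ".", call. = FALSE)
  }
  structure(
    list(groups = groups, labels = labels, sizes = sizes,
         n = sum(sizes), p = p, G = length(groups)),
    class = "grouped_samples"
  )
}

#' @export
print.grouped_samples <- function(x, ...) {
  cat("<grouped_samples> G =", x$G, "groups, p =", x$p,
      "channels, sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

as_grouped_samples <- function(x) {
  if (inherits(x, "grouped_samples")) x else grouped_samples(x)
}

#' Pooled first- and second-moment summaries of grouped samples
#'
#' Computes the grand mean, the per-group means, and the pooled within-group
#' covariance \eqn{S_n = e_1^{-1} \sum_g \sum_j (x_j^{(g)} - \bar X_g)
#' (x_j^{(g)} - \bar X_g)'} with \eqn{e_1 = n - G} degrees of freedom, the
#' ingredients of the ridge-regularized Hotelling statistic.
#'
#' The stored aspect ratio `gamma_n` is \eqn{p/e_1}: the pooled covariance
#' averages \eqn{e_1} independent centred contributions, so \eqn{p/e_1} is the
#' ratio at which its spectrum concentrates, and it is the ratio used by
#' [trace_functionals()].
#'
#' @param samples A [grouped_samples()] object (or a bare list of matrices).
#' @return An object of class `pooled_stats`: list with `grand_mean`,
#'   `group_means`, `pooled_cov`, `e1` (= n - G), `e2` (= G - 1), `gamma_n`,
#'   `sizes`, `n`, `p`.
#' @examples
#' gs <- grouped_samples(list(matrix(c(0, 2)), matrix(c(1, 3))))
#' pooled_stats(gs)$pooled_cov # 2
#' @export
pooled_stats <- function(samples) {
  samples <- as_grouped_samples(samples)
  n <- samples$n
  G <- samples$G
  if (n - G < 1L) {
    stop("Degenerate input: need n - G >= 1 pooled degrees of freedom ",
         "(n = ", n, ", G = ", G, ").", call. = FALSE)
  }
  p <- samples$p
  group_means <- lapply(samples$groups, colMeans)
  grand_mean <- colSums(do.call(rbind, samples$groups)) / n
  e1 <- n - G
  S <- matrix(0, p, p)
  for (g in seq_len(G)) {
    Xc <- sweep(samples$groups[[g]], 2L, group_means[[g]], "-")
    S <- S + crossprod(Xc)
  }
  S <- sym_part(S / e1)
  structure(
    list(grand_mean = grand_mean, group_means = group_means,
         pooled_cov = S, e1 = e1, e2 = G - 1L, gamma_n = p / e1,
         sizes = samples$sizes, n = n, p = p),
    class = "pooled_stats"
  )
}
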