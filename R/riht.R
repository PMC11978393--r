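#' Ridge-regularized Hotelling T-squared (RIHT) statistic
#'
#' Evaluates \eqn{\mathrm{RIHT} = \sum_g n_g (\bar X_g - \hat\mu)' (S_n +
#' \lambda I)^{-1} (\bar X_g - \hat\mu)}, the multi-group Hotelling form with
#' the singular sample covariance replaced by its ridge regularization, so the
#' statistic is defined for any `p`, including p > n.
#'
#' @param stats A [pooled_stats()] object.
#' @param samples The [grouped_samples()] the statistics were computed from
#'   (only the group sizes are used).
#' @param lambda Ridge parameter, a positive scalar.
#' @return A nonnegative scalar.
#' @examples
#' gs <- grouped_samples(list(matrix(c(0, 2)), matrix(c(2, 4))))
#' riht_statistic(pooled_stats(gs), gs, lambda = 1) # 4/3
#' @export
riht_statistic <- function(stats, samples, lambda) {
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(stats, "pooled_stats"))
  samples <- as_grouped_samples(samples)
  A <- stats$pooled_cov + diag(lambda, stats$p)
  total <- 0
  for (g in seq_along(stats$group_means)) {
    v <- stats$group_means[[g]] - stats$grand_mean
    total <- total + samples$sizes[g] * sum(v * solve(A, v))
  }
  total
}

.trace_functionals_from_eigen <- function(d, lambda, gamma_n) {
  inv_d <- 1 / (d + lambda)
  m <- mean(inv_d)
  m_prime <- mean(inv_d^2)
  D <- 1 - gamma_n * (1 - lambda * m)
  if (D <= 0) {
    stop("Standardization is singular: 1 - gamma_n (1 - lambda m) <= 0. ",
         "lambda = ", signif(lambda, 4), " is too small for aspect ratio ",
         signif(gamma_n, 4), ".", call. = FALSE)
  }
  theta1 <- (1 - lambda * m) / D
  theta2 <- (1 - lambda * m) / D^3 -
    lambda * (m - lambda * m_prime) / D^4
  list(m = m, m_prime = m_prime, theta1 = theta1, theta2 = theta2)
}

#' Stieltjes-transform trace functionals of the ridge resolvent
#'
#' Computes \eqn{m = p^{-1}\mathrm{tr}(S_n + \lambda I)^{-1}} and its
#' derivative analogue \eqn{m' = p^{-1}\mathrm{tr}(S_n + \lambda I)^{-2}},
#' then the plug-in estimators
#' \deqn{\Theta_n^{(1)} = \frac{1 - \lambda m}{D}, \qquad
#'       \Theta_n^{(2)} = \frac{1 - \lambda m}{D^3} -
#'       \frac{\lambda(m - \lambda m')}{D^4},}
#' with \eqn{D = 1 - \gamma_n (1 - \lambda m)}. These estimate
#' \eqn{p^{-1}\mathrm{tr}\{(S_n+\lambda I)^{-1}\Sigma\}} and
#' \eqn{p^{-1}\mathrm{tr}\{((S_n+\lambda I)^{-1}\Sigma)^2\}} without knowing
#' \eqn{\Sigma}, and standardize the RIHT statistic.
#'
#' @param pooled_cov Symmetric p x p pooled covariance matrix.
#' @param lambda Positive ridge parameter.
#' @param gamma_n Positive aspect ratio; [pooled_stats()] supplies
#'   \eqn{p/e_1}, the ratio matching the degrees of freedom of `pooled_cov`.
#' @return A list with elements `m`, `m_prime`, `theta1`, `theta2`.
#' @examples
#' trace_functionals(diag(4), lambda = 1, gamma_n = 0.5)$theta1 # 2/3
#' @export
trace_functionals <- function(pooled_cov, lambda, gamma_n) {
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  check_scalar(gamma_n, "gamma_n", lower = 0, strict_lower = TRUE)
  check_symmetric(pooled_cov, "pooled_cov")
  d <- eigen(sym_part(pooled_cov), symmetric = TRUE, only.values = TRUE)$values
  .trace_functionals_from_eigen(d, lambda, gamma_n)
}

#' RIHT test for equality of several high-dimensional mean vectors
#'
#' Tests \eqn{H_0: \mu_1 = \dots = \mu_G} via the standardized statistic
#' \deqn{T = \frac{\mathrm{RIHT} - e_2\,\widehat{\mathrm{tr}}_1}
#'                {\sqrt{2 e_2\, \widehat{\mathrm{tr}}_2}},}
#' where \eqn{e_2 = G - 1} and the trace terms are either computed exactly
#' from a supplied covariance `sigma` or estimated by the random-matrix
#' plug-ins of [trace_functionals()]. Under the null and mild moment
#' conditions, `T` is asymptotically standard normal.
#'
#' @param samples A [grouped_samples()] object or list of matrices.
#' @param lambda Positive ridge parameter; defaults to 1. Any positive value
#'   gives a valid test, the choice only affects power.
#' @param alpha Two-sided significance level in (0, 1).
#' @param sigma Optional known p x p population covariance. When supplied the
#'   trace terms use it directly instead of the plug-in estimators.
#' @return Object of class `riht_result`: list with `riht`, `lambda`, `m`,
#'   `m_prime`, `theta1`, `theta2`, `tr1`, `tr2`, `statistic`, `p_value`,
#'   `reject`, `alpha`, `z_crit`, `e1`, `e2`, `p`, `sizes`, `plug_in`.
#' @examples
#' set.seed(1)
#' gs <- grouped_samples(list(matrix(rnorm(200), 20), matrix(rnorm(200), 20)))
#' riht_test(gs)$p_value
#' @export
riht_test <- function(samples, lambda = 1, alpha = 0.05, sigma = NULL) {
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  samples <- as_grouped_samples(samples)
  st <- pooled_stats(samples)
  .riht_covariance_diagnostic(samples)
  p <- st$p

  eg <- eigen(st$pooled_cov, symmetric = TRUE)
  inv_d <- 1 / (eg$values + lambda)

  # RIHT via the shared eigendecomposition
  riht <- 0
  for (g in seq_len(samples$G)) {
    w <- crossprod(eg$vectors, st$group_means[[g]] - st$grand_mean)
    riht <- riht + samples$sizes[g] * sum(w^2 * inv_d)
  }

  tf <- .trace_functionals_from_eigen(eg$values, lambda, st$gamma_n)
  if (is.null(sigma)) {
    tr1 <- p * tf$theta1
    tr2 <- p * tf$theta2
    plug_in <- TRUE
  } else {
    check_symmetric(sigma, "sigma")
    if (nrow(sigma) != p) {
      stop("`sigma` must be ", p, " x ", p, ".", call. = FALSE)
    }
    # (S + lambda I)^{-1} Sigma through the eigenbasis
    B <- eg$vectors %*% (inv_d * crossprod(eg$vectors, sigma))
    tr1 <- sum(diag(B))
    tr2 <- sum(B * t(B))
    plug_in <- FALSE
  }

  e2 <- st$e2
  statistic <- (riht - e2 * tr1) / sqrt(2 * e2 * tr2)
  z_crit <- qnorm(1 - alpha / 2)
  structure(
    list(riht = riht, lambda = lambda, m = tf$m, m_prime = tf$m_prime,
         theta1 = tf$theta1, theta2 = tf$theta2, tr1 = tr1, tr2 = tr2,
         statistic = statistic, p_value = 2 * pnorm(-abs(statistic)),
         reject = abs(statistic) > z_crit, alpha = alpha, z_crit = z_crit,
         e1 = st$e1, e2 = e2, p = p, sizes = samples$sizes,
         plug_in = plug_in),
    class = "riht_result"
  )
}

# The test assumes a common covariance across groups; warn when group-wise
# covariance traces disagree by more than a factor of 4.
.riht_covariance_diagnostic <- function(samples) {
  tr <- vapply(samples$groups, function(X) {
    Xc <- sweep(X, 2L, colMeans(X), "-")
    sum(Xc^2) / (nrow(X) - 1L)
  }, numeric(1))
  if (max(tr) > 4 * max(min(tr), .Machine$double.eps)) {
    warning("Group-wise covariance traces differ by more than a factor of 4; ",
            "the equal-covariance assumption looks doubtful.", call. = FALSE)
  }
  invisible(tr)
}

#' @export
print.riht_result <- function(x, ...) {
  cat("RIHT test: T =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$reject) " (reject)" else " (no rejection)", "\n")
  cat("  RIHT =", format(x$riht, digits = 6), " lambda =", x$lambda,
      " groups:", paste(x$sizes, collapse = ", "),
      if (x$plug_in) " [plug-in calibration]" else " [known-sigma]", "\n")
  invisible(x)
}

#' Two-step change validation across consecutive epochs
#'
#' First runs the G-interval RIHT test for an overall mean change across all
#' epochs; only if that test rejects (or `gate = FALSE`) does it test each
#' adjacent pair of epochs to localize the change points.
#'
#' @param epochs List of observation matrices (consecutive intervals), each
#'   with at least 2 rows and a common number of columns.
#' @param lambda,alpha As in [riht_test()].
#' @param z_crit Pairwise rejection threshold for |T|; default 1.96.
#' @param gate If `TRUE` (default) pairwise tests run only after the overall
#'   test rejects.
#' @param p_adjust Either "none" (default; each pairwise test at `z_crit`) or
#'   "BH" for a Benjamini-Hochberg correction of the pairwise p-values at
#'   level `alpha`.
#' @return Object of class `riht_change_report`: list with `overall` (a
#'   `riht_result`), `pairwise` (a tibble with one row per adjacent boundary),
#'   and `change_points` (boundary indices g where epoch g vs g+1 rejects).
#' @examples
#' set.seed(1)
#' ep <- list(matrix(rnorm(60), 20), matrix(rnorm(60), 20),
#'            matrix(rnorm(60, mean = 3), 20))
#' validate_changes(ep)$change_points
#' @export
validate_changes <- function(epochs, lambda = 1, alpha = 0.05, z_crit = 1.96,
                             gate = TRUE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(epochs) || length(epochs) < 2L) {
    stop("Need at least two epochs.", call. = FALSE)
  }
  samples <- grouped_samples(epochs)
  overall <- riht_test(samples, lambda = lambda, alpha = alpha)

  pairwise <- tibble::tibble(
    boundary = integer(), statistic = numeric(), p_value = numeric(),
    reject = logical()
  )
  results <- list()
  if (overall$reject || !gate) {
    G <- length(epochs)
    rows <- vector("list", G - 1L)
    for (g in seq_len(G - 1L)) {
      res <- riht_test(grouped_samples(epochs[c(g, g + 1L)]),
                       lambda = lambda, alpha = alpha)
      results[[g]] <- res
      rows[[g]] <- tibble::tibble(
        boundary = g, statistic = res$statistic, p_value = res$p_value,
        reject = abs(res$statistic) > z_crit
      )
    }
    pairwise <- dplyr::bind_rows(rows)
    if (p_adjust == "BH") {
      pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "BH")
      pairwise$reject <- pairwise$p_adjusted < alpha
    }
  }
  structure(
    list(overall = overall, pairwise = pairwise,
         pairwise_results = results,
         change_points = pairwise$boundary[pairwise$reject],
         gate = gate, z_crit = z_crit),
    class = "riht_change_report"
  )
}

#' @export
print.riht_change_report <- function(x, ...) {
  cat("Multi-interval RIHT change validation\n")
  print(x$overall)
  if (nrow(x$pairwise) == 0L) {
    cat("  No pairwise tests run",
        if (x$gate) "(overall test did not reject).\n" else ".\n")
  } else {
    cat("  Change points at boundaries:",
        if (length(x$change_points)) paste(x$change_points, collapse = ", ")
        else "none", "\n")
  }
  invisible(x)
}
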