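#' Hyperparameter grid for the fused graphical lasso
#'
#' Default grid: 30 equally spaced values from 0.05 to 0.3 on each axis
#' (step 0.0034), the grid used by the AIC comparator in the simulation
#' studies.
#'
#' @param from,to Range endpoints (positive).
#' @param n Number of grid points per axis.
#' @param lambda1_values,lambda2_values Optional explicit ascending positive
#'   sequences, overriding the regular grid.
#' @return Object of class `fgl_grid`.
#' @export
fgl_grid <- function(from = 0.05, to = 0.3, n = 30,
                     lambda1_values = NULL, lambda2_values = NULL) {
  if (is.null(lambda1_values)) lambda1_values <- seq(from, to, length.out = n)
  if (is.null(lambda2_values)) lambda2_values <- seq(from, to, length.out = n)
  for (v in list(lambda1_values, lambda2_values)) {
    if (length(v) == 0L || any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
      stop("Grid values must be non-empty, strictly positive and ascending.",
           call. = FALSE)
    }
  }
  structure(list(lambda1_values = lambda1_values,
                 lambda2_values = lambda2_values),
            class = "fgl_grid")
}

#' AIC of a fused-graphical-lasso fit
#'
#' Likelihood-plus-complexity score
#' \deqn{\sum_g \{ w_g [\mathrm{tr}(S_{n_g}\hat\Theta_g) -
#'   \log\det\hat\Theta_g] + 2 k_g \},}
#' where \eqn{k_g} counts the free parameters of group g (the p diagonal
#' entries plus the upper-triangle off-diagonal entries with magnitude above
#' `support_threshold`). Two conventions for the likelihood weight \eqn{w_g}
#' are in circulation: the per-observation form \eqn{w_g = 1} (the fitted
#' objective itself plus the complexity penalty; the default) and the
#' total-likelihood form \eqn{w_g = n_g}. The per-observation form puts the
#' complexity penalty on the same footing as the averaged loss and selects
#' markedly sparser models at these sample sizes; the total-likelihood form
#' is dominated by the fit term and selects near the dense end of the usual
#' penalty grids.
#'
#' @param fit An [fit_fgl()] result.
#' @param problem The [fgl_problem()]; defaults to the one stored in `fit`.
#' @param support_threshold Magnitude below which an entry is not counted as
#'   a parameter (default 1e-6).
#' @param likelihood_weight `"obs"` (default, \eqn{w_g = 1}) or `"n"`
#'   (\eqn{w_g = n_g}).
#' @return Scalar score (smaller is better).
#' @export
aic_score <- function(fit, problem = fit$problem, support_threshold = 1e-6,
                      likelihood_weight = c("obs", "n")) {
  stopifnot(inherits(fit, "fgl_fit"))
  likelihood_weight <- match.arg(likelihood_weight)
  total <- 0
  for (g in seq_len(problem$G)) {
    Th <- fit$Theta_hat[[g]]
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) {
      stop("Fitted Theta[[", g, "]] is not positive definite.", call. = FALSE)
    }
    loglik_term <- sum(problem$covariances[[g]] * Th) - as.numeric(ld$modulus)
    w <- if (likelihood_weight == "n") problem$sample_sizes[g] else 1
    k <- sum(abs(Th[upper.tri(Th)]) > support_threshold) + problem$p
    total <- total + w * loglik_term + 2 * k
  }
  total
}

#' Select fused-graphical-lasso penalties by AIC grid search
#'
#' Fits the model at every (lambda1, lambda2) pair of the grid and returns
#' the AIC minimizer; ties are broken toward the larger (sparser) penalty
#' pair. Successive fits along the grid are warm-started from the previous
#' solution, and grid cells are scored at a relaxed ADMM tolerance
#' (`epsilon`); the winning pair is refit at `refit_epsilon`.
#'
#' @param problem An [fgl_problem()].
#' @param grid An [fgl_grid()].
#' @param rho1,rho2 ADMM penalty parameters (not searched; default 1).
#' @param max_iter,epsilon ADMM controls for the grid-cell fits.
#' @param refit_epsilon Tolerance for the final fit at the selected pair.
#' @param warm_start Reuse the previous cell's solution as the next cell's
#'   starting point, with zero-initialized duals (default TRUE).
#' @param support_threshold,likelihood_weight Passed to [aic_score()].
#' @return Object of class `fgl_tune`: list with `lambda1`, `lambda2`,
#'   `rho1`, `rho2`, `score_surface` (tibble of the whole grid), `fit`,
#'   `method = "aic"`, `n_solves`.
#' @export
aic_grid_search <- function(problem, grid = fgl_grid(), rho1 = 1, rho2 = 1,
                            max_iter = 500, epsilon = 1e-5,
                            refit_epsilon = 1e-9, warm_start = TRUE,
                            support_threshold = 1e-6,
                            likelihood_weight = c("obs", "n")) {
  stopifnot(inherits(problem, "fgl_problem"), inherits(grid, "fgl_grid"))
  likelihood_weight <- match.arg(likelihood_weight)
  rows <- list()
  n_solves <- 0L
  warm <- NULL
  for (l2 in grid$lambda2_values) {
    warm_row <- warm # restart each lambda1 sweep from the row entry point
    for (l1 in grid$lambda1_values) {
      hy <- fgl_hyper(l1, l2, rho1, rho2)
      score <- tryCatch({
        fit <- suppressWarnings(fit_fgl(
          problem, hy, max_iter = max_iter, epsilon = epsilon,
          init = if (warm_start && !is.null(warm_row)) "zeros" else "ones",
          init_theta = if (warm_start) warm_row else NULL,
          keep_trace = FALSE))
        if (warm_start) warm_row <- fit$Theta_hat
        if (is.null(warm)) warm <- fit$Theta_hat
        n_solves <- n_solves + 1L
        aic_score(fit, problem, support_threshold, likelihood_weight)
      }, error = function(e) {
        warning("Grid cell (", signif(l1, 3), ", ", signif(l2, 3),
                ") failed: ", conditionMessage(e), call. = FALSE)
        Inf
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lambda1 = l1, lambda2 = l2, score = score)
    }
    warm <- warm_row
  }
  surface <- dplyr::bind_rows(rows)
  best <- dplyr::slice(
    dplyr::arrange(surface, .data$score,
                   dplyr::desc(.data$lambda1), dplyr::desc(.data$lambda2)),
    1L)
  fit <- suppressWarnings(fit_fgl(
    problem, fgl_hyper(best$lambda1, best$lambda2, rho1, rho2),
    max_iter = max_iter, epsilon = refit_epsilon))
  structure(
    list(lambda1 = best$lambda1, lambda2 = best$lambda2,
         rho1 = rho1, rho2 = rho2, score = best$score,
         score_surface = surface, fit = fit, method = "aic",
         n_solves = n_solves + 1L),
    class = "fgl_tune"
  )
}

#' @export
print.fgl_tune <- function(x, ...) {
  cat("<fgl_tune> method =", x$method,
      " lambda1 =", signif(x$lambda1, 4),
      " lambda2 =", signif(x$lambda2, 4),
      " rho1 =", signif(x$rho1, 4), " rho2 =", signif(x$rho2, 4),
      " (", x$n_solves, "ADMM solves )\n")
  invisible(x)
}
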