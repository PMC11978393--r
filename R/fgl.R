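#' Per-group empirical covariance matrices
#'
#' Forms \eqn{S_{n_g} = n_g^{-1} X_g' X_g} after centering each group's
#' columns by the group mean. The Gaussian likelihood the fused graphical
#' lasso minimizes presumes mean-zero data, so centering is applied up front;
#' for mean-zero simulation designs this is immaterial, for raw recordings it
#' removes the per-channel offsets.
#'
#' @param groups A [grouped_samples()] object or list of matrices.
#' @return An object of class `fgl_problem`.
#' @examples
#' empirical_covariances(list(matrix(c(1, -1, 0, 0), 2)))$covariances[[1]]
#' @export
empirical_covariances <- function(groups) {
  groups <- as_grouped_samples(groups)
  covs <- lapply(groups$groups, function(X) {
    Xc <- sweep(X, 2L, colMeans(X), "-")
    sym_part(crossprod(Xc) / nrow(X))
  })
  fgl_problem(covs, groups$sizes)
}

#' Bundle covariance matrices into a fused-graphical-lasso problem
#'
#' @param covariances List of G symmetric p x p covariance matrices.
#' @param sample_sizes Integer vector of per-group sample sizes.
#' @return An object of class `fgl_problem`: list with `covariances`,
#'   `sample_sizes`, `p`, `G`.
#' @export
fgl_problem <- function(covariances, sample_sizes) {
  if (is.matrix(covariances)) covariances <- list(covariances)
  G <- length(covariances)
  if (G < 1L) stop("Need at least one covariance matrix.", call. = FALSE)
  p <- nrow(covariances[[1L]])
  for (g in seq_len(G)) {
    check_symmetric(covariances[[g]], paste0("covariances[[", g, "]]"))
    if (nrow(covariances[[g]]) != p) {
      stop("All covariance matrices must share the same dimension.",
           call. = FALSE)
    }
    covariances[[g]] <- sym_part(covariances[[g]])
  }
  if (length(sample_sizes) != G || any(sample_sizes < 2)) {
    stop("`sample_sizes` must give one size >= 2 per group.", call. = FALSE)
  }
  structure(list(covariances = covariances,
                 sample_sizes = as.integer(sample_sizes), p = p, G = G),
            class = "fgl_problem")
}

#' Hyperparameters of the fused graphical lasso
#'
#' @param lambda1 Sparsity penalty (>= 0) on the off-diagonal entries of each
#'   precision matrix.
#' @param lambda2 Fusion penalty (>= 0) on off-diagonal differences between
#'   the precision matrices of successive groups.
#' @param rho1,rho2 Positive ADMM penalty parameters for the sparsity and
#'   fusion consensus constraints (`rho2` may be 0 when G = 1).
#' @return An object of class `fgl_hyper`.
#' @export
fgl_hyper <- function(lambda1, lambda2 = 0, rho1 = 1, rho2 = 1) {
  check_scalar(lambda1, "lambda1", lower = 0)
  check_scalar(lambda2, "lambda2", lower = 0)
  check_scalar(rho1, "rho1", lower = 0, strict_lower = TRUE)
  check_scalar(rho2, "rho2", lower = 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 rho1 = rho1, rho2 = rho2),
            class = "fgl_hyper")
}

#' Elementwise soft-threshold operator
#'
#' The proximal map of the l1 penalty: shrinks each entry toward zero by
#' `alpha`, mapping anything with |z| <= alpha exactly to 0.
#'
#' @param z Numeric scalar, vector or matrix.
#' @param alpha Nonnegative threshold.
#' @param offdiag If `TRUE` and `z` is a square matrix, the diagonal of the
#'   result is set to zero (the off-diagonal restriction of the penalties).
#' @return Same shape as `z`.
#' @examples
#' soft_threshold(c(1.2, -1.2, 0.3), 0.5)
#' @export
soft_threshold <- function(z, alpha, offdiag = FALSE) {
  check_scalar(alpha, "alpha", lower = 0)
  out <- sign(z) * pmax(abs(z) - alpha, 0)
  if (offdiag) {
    if (!is.matrix(out) || nrow(out) != ncol(out)) {
      stop("`offdiag = TRUE` requires a square matrix.", call. = FALSE)
    }
    diag(out) <- 0
  }
  out
}

# Off-diagonal soft threshold that carries the unpenalized diagonal through:
# the consensus slacks must track Theta's diagonal for the closed-form
# Theta update to have the correct fixed point.
.soft_keepdiag <- function(M, alpha) {
  R <- sign(M) * pmax(abs(M) - alpha, 0)
  diag(R) <- diag(M)
  R
}

#' Initialize the ADMM state
#'
#' Default initialization: \eqn{\Theta^{(0)}_g = (S_{n_g} + 0.1 I)^{-1}},
#' slack copies \eqn{Z = \Theta^{(0)}}, \eqn{\Delta_g = \Theta^{(0)}_g -
#' \Theta^{(0)}_{g+1}}, and all-ones scaled duals (`init = "ones"`); the
#' conventional all-zeros duals are available as `init = "zeros"`.
#'
#' @param problem An [fgl_problem()].
#' @param hyper An [fgl_hyper()].
#' @param init `"ones"` (all-ones duals, the default) or `"zeros"`.
#' @param init_theta Optional list of G positive-definite matrices used as a
#'   warm start for the precision iterates.
#' @return An object of class `admm_state`.
#' @export
admm_initialize <- function(problem, hyper, init = c("ones", "zeros"),
                            init_theta = NULL) {
  init <- match.arg(init)
  p <- problem$p
  G <- problem$G
  Theta <- if (is.null(init_theta)) {
    lapply(problem$covariances, function(S) sym_part(solve(S + diag(0.1, p))))
  } else {
    stopifnot(length(init_theta) == G)
    lapply(init_theta, sym_part)
  }
  dual0 <- if (init == "ones") matrix(1, p, p) else matrix(0, p, p)
  state <- list(
    Theta = Theta,
    Z = Theta,
    Delta = if (G > 1) {
      lapply(seq_len(G - 1L), function(g) Theta[[g]] - Theta[[g + 1L]])
    } else list(),
    V = replicate(G, dual0, simplify = FALSE),
    U = replicate(max(G - 1L, 0L), dual0, simplify = FALSE),
    iteration = 0L
  )
  class(state) <- "admm_state"
  state
}

#' Assemble the linearized target matrix for one precision update
#'
#' Combines the group's covariance with the sparsity consensus residual and
#' the boundary-aware fusion terms: group 1 and group G touch one fusion
#' constraint, interior groups touch two (with opposite signs). The result is
#' symmetrized before use.
#'
#' @param g Group index in 1..G.
#' @param state An `admm_state`.
#' @param problem An [fgl_problem()].
#' @param hyper An [fgl_hyper()].
#' @return A symmetric p x p matrix.
#' @export
assemble_y <- function(g, state, problem, hyper) {
  G <- problem$G
  if (g < 1 || g > G) stop("Group index out of range.", call. = FALSE)
  Y <- problem$covariances[[g]] +
    hyper$rho1 * (state$V[[g]] - state$Z[[g]])
  if (G > 1) {
    r2 <- hyper$rho2
    if (g == 1) {
      Y <- Y + r2 * (state$U[[1]] - state$Delta[[1]] - state$Theta[[2]])
    } else if (g == G) {
      Y <- Y - r2 * (state$U[[G - 1]] - state$Delta[[G - 1]] +
                       state$Theta[[G - 1]])
    } else {
      Y <- Y - r2 * (state$U[[g - 1]] - state$Delta[[g - 1]] +
                       state$Theta[[g - 1]]) +
        r2 * (state$U[[g]] - state$Delta[[g]] - state$Theta[[g + 1]])
    }
  }
  sym_part(Y)
}

# Number of fusion constraints incident to group g (0 when G = 1).
.n_fusion <- function(g, G) {
  if (G == 1L) 0L else if (g == 1L || g == G) 1L else 2L
}

#' Closed-form positive-definite precision update
#'
#' Solves \eqn{\rho \Theta^2 + Y \Theta - I = 0} for symmetric `Y`
#' spectrally: each eigenvalue d of Y maps to \eqn{(-d + \sqrt{d^2 + 4\rho})
#' / (2\rho)}, which is strictly positive, so every iterate is positive
#' definite by construction.
#'
#' @param Y Symmetric p x p matrix.
#' @param rho_total Positive scalar: `rho1` plus `rho2` times the number of
#'   incident fusion constraints.
#' @return A symmetric positive definite p x p matrix.
#' @examples
#' update_theta(matrix(0, 2, 2), 1) # identity
#' @export
update_theta <- function(Y, rho_total) {
  check_scalar(rho_total, "rho_total", lower = 0, strict_lower = TRUE)
  check_symmetric(Y, "Y")
  e <- eigen(sym_part(Y), symmetric = TRUE)
  dv <- (-e$values + sqrt(e$values^2 + 4 * rho_total)) / (2 * rho_total)
  sym_part(e$vectors %*% (dv * t(e$vectors)))
}

#' One full ADMM sweep
#'
#' Updates every precision matrix in turn (later groups see the refreshed
#' neighbours), then the sparsity slacks `Z`, the fusion slacks `Delta`, and
#' finally the scaled duals `V`, `U` whose diagonals are zeroed (the
#' consensus constraints bind off-diagonal only, the diagonal residual is
#' identically zero at the fixed point).
#'
#' @inheritParams assemble_y
#' @return The updated `admm_state`.
#' @export
admm_step <- function(state, problem, hyper) {
  state <- .admm_theta_sweep(state, problem, hyper)
  state <- .admm_slack_dual(state, problem, hyper)
  state$iteration <- state$iteration + 1L
  state
}

.admm_theta_sweep <- function(state, problem, hyper) {
  G <- problem$G
  for (g in seq_len(G)) {
    Y <- assemble_y(g, state, problem, hyper)
    rt <- hyper$rho1 + .n_fusion(g, G) * hyper$rho2
    state$Theta[[g]] <- update_theta(Y, rt)
  }
  state
}

.admm_slack_dual <- function(state, problem, hyper) {
  G <- problem$G
  for (g in seq_len(G)) {
    state$Z[[g]] <- .soft_keepdiag(state$Theta[[g]] + state$V[[g]],
                                   hyper$lambda1 / hyper$rho1)
  }
  if (G > 1) {
    for (g in seq_len(G - 1L)) {
      state$Delta[[g]] <- .soft_keepdiag(
        state$Theta[[g]] - state$Theta[[g + 1L]] + state$U[[g]],
        hyper$lambda2 / hyper$rho2)
    }
  }
  for (g in seq_len(G)) {
    state$V[[g]] <- off_diagonal(state$V[[g]] + state$Theta[[g]] -
                                   state$Z[[g]])
  }
  if (G > 1) {
    for (g in seq_len(G - 1L)) {
      state$U[[g]] <- off_diagonal(state$U[[g]] + state$Theta[[g]] -
                                     state$Theta[[g + 1L]] -
                                     state$Delta[[g]])
    }
  }
  state
}

#' Fused graphical lasso objective
#'
#' \deqn{\sum_g \{\mathrm{tr}(S_{n_g}\Theta_g) - \log\det\Theta_g\}
#'  + \lambda_1 \sum_g \|(\Theta_g)^-\|_1
#'  + \lambda_2 \sum_{g<g'} \|(\Theta_g - \Theta_{g'})^-\|_1,}
#' where the superscript minus restricts to off-diagonal entries. The fusion
#' sum runs over all pairs; the ADMM constrains only adjacent pairs, and the
#' two coincide for G = 2 (every design here).
#'
#' @param Thetas List of G positive definite matrices.
#' @param problem An [fgl_problem()].
#' @param lambda1,lambda2 Nonnegative penalties.
#' @return Scalar objective value.
#' @export
fgl_objective <- function(Thetas, problem, lambda1, lambda2) {
  if (is.matrix(Thetas)) Thetas <- list(Thetas)
  G <- problem$G
  stopifnot(length(Thetas) == G)
  val <- 0
  for (g in seq_len(G)) {
    ld <- determinant(Thetas[[g]], logarithm = TRUE)
    if (ld$sign <= 0) {
      stop("Theta[[", g, "]] is not positive definite.", call. = FALSE)
    }
    val <- val + sum(problem$covariances[[g]] * Thetas[[g]]) -
      as.numeric(ld$modulus) +
      lambda1 * sum(abs(off_diagonal(Thetas[[g]])))
  }
  if (G > 1) {
    for (g in seq_len(G - 1L)) {
      for (h in seq(g + 1L, G)) {
        val <- val + lambda2 *
          sum(abs(off_diagonal(Thetas[[g]] - Thetas[[h]])))
      }
    }
  }
  val
}

#' Fit the fused graphical lasso by ADMM
#'
#' Jointly estimates G sparse precision matrices by minimizing
#' [fgl_objective()]. Iterates [admm_step()] until the relative l1 change
#' \eqn{\sum_g \|\Theta_g^{(t)} - \Theta_g^{(t-1)}\|_1 / \sum_g
#' \|\Theta_g^{(t-1)}\|_1} drops to `epsilon` or `max_iter` is reached.
#'
#' @param problem An [fgl_problem()] (or a [grouped_samples()] object, which
#'   is passed through [empirical_covariances()]).
#' @param hyper An [fgl_hyper()].
#' @param max_iter Iteration cap (default 500); hitting it yields a warning
#'   and `converged = FALSE`, never an error.
#' @param epsilon Relative-change stopping tolerance (default 1e-9).
#' @param engine `"cpp"` (default, compiled loop) or `"r"` (the step-by-step
#'   [admm_step()] path; identical arithmetic, kept for inspection).
#' @param init Dual initialization passed to [admm_initialize()].
#' @param init_theta Optional warm-start precision matrices.
#' @param keep_trace Record the objective at every iteration (default TRUE).
#' @return Object of class `fgl_fit`: list with `Theta_hat`,
#'   `objective_trace`, `converged`, `iterations`, `relative_change`,
#'   `hyper`, `problem`.
#' @examples
#' S <- diag(3) + 0.3
#' fit <- fit_fgl(fgl_problem(list(S, S), c(50, 50)), fgl_hyper(0.1, 0.1))
#' fit$converged
#' @export
fit_fgl <- function(problem, hyper, max_iter = 500, epsilon = 1e-9,
                    engine = c("cpp", "r"), init = c("ones", "zeros"),
                    init_theta = NULL, keep_trace = TRUE) {
  engine <- match.arg(engine)
  init <- match.arg(init)
  if (inherits(problem, "grouped_samples") ||
      (is.list(problem) && !inherits(problem, "fgl_problem"))) {
    problem <- empirical_covariances(problem)
  }
  stopifnot(inherits(problem, "fgl_problem"), inherits(hyper, "fgl_hyper"))
  if (problem$G > 1 && hyper$rho2 <= 0) {
    stop("`rho2` must be positive when G > 1.", call. = FALSE)
  }

  if (engine == "cpp") {
    out <- fgl_admm_cpp(problem$covariances, hyper$lambda1, hyper$lambda2,
                        hyper$rho1, hyper$rho2, as.integer(max_iter),
                        epsilon, init == "ones", init_theta, keep_trace)
    Theta <- out$Theta
    trace <- out$objective_trace
    iterations <- out$iterations
    rel <- out$relative_change
    converged <- out$converged
  } else {
    state <- admm_initialize(problem, hyper, init = init,
                             init_theta = init_theta)
    trace <- numeric(0)
    rel <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      denom <- sum(vapply(state$Theta, function(M) sum(abs(M)), numeric(1)))
      old <- state$Theta
      state <- admm_step(state, problem, hyper)
      if (keep_trace) {
        trace <- c(trace, fgl_objective(state$Theta, problem,
                                        hyper$lambda1, hyper$lambda2))
      }
      num <- sum(vapply(seq_along(old), function(g) {
        sum(abs(state$Theta[[g]] - old[[g]]))
      }, numeric(1)))
      rel <- num / denom
      if (rel <= epsilon) {
        converged <- TRUE
        break
      }
    }
    Theta <- state$Theta
    iterations <- state$iteration
  }

  if (!converged) {
    warning("ADMM did not reach epsilon = ", epsilon, " within ", max_iter,
            " iterations (relative change ", signif(rel, 3), ").",
            call. = FALSE)
  }
  structure(
    list(Theta_hat = Theta, objective_trace = as.numeric(trace),
         converged = converged, iterations = iterations,
         relative_change = rel, hyper = hyper, problem = problem),
    class = "fgl_fit"
  )
}

#' @export
print.fgl_fit <- function(x, ...) {
  cat("<fgl_fit> G =", x$problem$G, " p =", x$problem$p,
      " lambda1 =", x$hyper$lambda1, " lambda2 =", x$hyper$lambda2, "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)",
      " relative change:", signif(x$relative_change, 3), "\n")
  invisible(x)
}

#' Estimated edge support of a fitted precision matrix
#'
#' Off-diagonal entries with magnitude above `threshold` are treated as
#' edges. The ADMM drives the penalized entries of the precision iterates to
#' the slack values, so thresholding at 1e-6 recovers the exact-zero pattern.
#'
#' @param fit An `fgl_fit`.
#' @param group Which group's support (default 1).
#' @param threshold Magnitude below which an entry counts as zero.
#' @return Logical p x p matrix (diagonal `FALSE`).
#' @export
fgl_support <- function(fit, group = 1, threshold = 1e-6) {
  stopifnot(inherits(fit, "fgl_fit"))
  M <- abs(fit$Theta_hat[[group]]) > threshold
  diag(M) <- FALSE
  M
}
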