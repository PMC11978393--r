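#' Data-driven hyperparameter networks
#'
#' Small learned update rules that replace the grid search: each
#' hyperparameter is refreshed during the ADMM run by a single-layer affine
#' map acting in log space on a few scalar features of the current iterates,
#' followed by an exponential, so outputs are strictly positive for any
#' input. At the identity initialization (`dd_networks()` with no training)
#' every map returns its input hyperparameter unchanged, and the procedure
#' reduces to a plain fused-graphical-lasso fit at the starting values.
#'
#' The feature sets follow the update signatures of the tuning algorithm:
#' `lambda1` sees the sparsity-consensus residual \eqn{\sum_g \|Z_g -
#' \Theta_g\|_F^2}; `lambda2` the fusion residual \eqn{\sum_g \|\Delta_g -
#' (\Theta_g - \Theta_{g+1})\|_F^2}; `rho1` scalar summaries (Frobenius
#' norms) of the S, Theta and Z iterates; `rho2` summaries of the successive
#' differences and of Delta.
#'
#' @param lambda1,lambda2 Weight vectors `(w_feature, w_log_prev, bias)`.
#' @param rho1 Weights `(w_S, w_Theta, w_Z, w_log_prev, bias)`.
#' @param rho2 Weights `(w_diff, w_Delta, w_log_prev, bias)`.
#' @return Object of class `dd_networks`.
#' @export
dd_networks <- function(lambda1 = c(0, 1, 0), lambda2 = c(0, 1, 0),
                        rho1 = c(0, 0, 0, 1, 0), rho2 = c(0, 0, 1, 0)) {
  stopifnot(length(lambda1) == 3L, length(lambda2) == 3L,
            length(rho1) == 5L, length(rho2) == 4L)
  structure(list(lambda1 = as.numeric(lambda1),
                 lambda2 = as.numeric(lambda2),
                 rho1 = as.numeric(rho1), rho2 = as.numeric(rho2),
                 trained = FALSE, training_loss = NULL),
            class = "dd_networks")
}

#' @export
print.dd_networks <- function(x, ...) {
  cat("<dd_networks>", if (x$trained) "trained" else "untrained (identity)",
      "\n")
  invisible(x)
}

# log-space affine map with positivity transform; the clamp keeps the
# hyperparameters inside a numerically sane range.
.dd_forward <- function(weights, features, prev) {
  z <- sum(weights[seq_along(features)] * features) +
    weights[length(weights) - 1L] * log(prev) +
    weights[length(weights)]
  exp(min(max(z, -10), 10))
}

.dd_pack <- function(nets) c(nets$lambda1, nets$lambda2, nets$rho1, nets$rho2)

.dd_unpack <- function(par, template = dd_networks()) {
  template$lambda1 <- par[1:3]
  template$lambda2 <- par[4:6]
  template$rho1 <- par[7:11]
  template$rho2 <- par[12:15]
  template
}

.frob <- function(M) sqrt(sum(M^2))

#' Tune fused-graphical-lasso hyperparameters by the data-driven rule
#'
#' Interleaves hyperparameter refreshes with the ADMM iterations: in each
#' sweep, lambda1 and lambda2 are updated from the current consensus
#' residuals, the precision matrices are updated, rho1 and rho2 are updated
#' from iterate summaries, and then the slack and dual variables advance.
#' One trajectory replaces the whole grid search (a single ADMM-cost solve
#' versus one solve per grid cell). The final hyperparameters are then fixed
#' and the model refit to convergence.
#'
#' @param problem An [fgl_problem()].
#' @param nets A [dd_networks()] object; `NULL` uses the identity
#'   initialization (with a message), under which the result equals a plain
#'   [fit_fgl()] at the initial hyperparameters.
#' @param init Named list of starting values `lambda1`, `lambda2`, `rho1`,
#'   `rho2`. The default anchors both penalties at 0.05, the light end of
#'   the standard search range, which favours the de-biased entrywise
#'   inference; trained networks adapt from there.
#' @param max_iter Sweep cap for the interleaved phase.
#' @param epsilon Relative-change tolerance for the interleaved phase.
#' @param refit_epsilon Tolerance of the final fixed-hyperparameter fit.
#' @return An object of class `fgl_tune` (see [aic_grid_search()]) with
#'   `method = "dd"` and a `trajectory` tibble of hyperparameter values per
#'   sweep.
#' @export
dd_tune <- function(problem, nets = dd_networks(),
                    init = list(lambda1 = 0.05, lambda2 = 0.05,
                                rho1 = 1, rho2 = 1),
                    max_iter = 200, epsilon = 1e-6, refit_epsilon = 1e-9) {
  stopifnot(inherits(problem, "fgl_problem"))
  if (is.null(nets)) {
    message("No networks supplied; using the identity initialization ",
            "(reduces to a plain FGL fit at the starting values).")
    nets <- dd_networks()
  }
  stopifnot(inherits(nets, "dd_networks"))
  G <- problem$G
  l1 <- init$lambda1
  l2 <- init$lambda2
  r1 <- init$rho1
  r2 <- init$rho2
  hyper <- fgl_hyper(l1, l2, r1, r2)
  state <- admm_initialize(problem, hyper)
  s_norm <- mean(vapply(problem$covariances, .frob, numeric(1)))

  traj <- vector("list", max_iter)
  rel <- Inf
  for (it in seq_len(max_iter)) {
    z_resid <- sum(vapply(seq_len(G), function(g) {
      sum((state$Z[[g]] - state$Theta[[g]])^2)
    }, numeric(1)))
    l1 <- .dd_forward(nets$lambda1, log1p(z_resid), l1)
    if (G > 1) {
      d_resid <- sum(vapply(seq_len(G - 1L), function(g) {
        sum((state$Delta[[g]] - (state$Theta[[g]] -
                                   state$Theta[[g + 1L]]))^2)
      }, numeric(1)))
      l2 <- .dd_forward(nets$lambda2, log1p(d_resid), l2)
    }
    hyper <- fgl_hyper(l1, l2, r1, r2)

    old <- state$Theta
    state <- .admm_theta_sweep(state, problem, hyper)

    th_norm <- mean(vapply(state$Theta, .frob, numeric(1)))
    z_norm <- mean(vapply(state$Z, .frob, numeric(1)))
    r1 <- .dd_forward(nets$rho1,
                      c(log1p(s_norm), log1p(th_norm), log1p(z_norm)), r1)
    if (G > 1) {
      diff_norm <- mean(vapply(seq_len(G - 1L), function(g) {
        .frob(state$Theta[[g]] - state$Theta[[g + 1L]])
      }, numeric(1)))
      del_norm <- mean(vapply(state$Delta, .frob, numeric(1)))
      r2 <- .dd_forward(nets$rho2, c(log1p(diff_norm), log1p(del_norm)), r2)
    }
    hyper <- fgl_hyper(l1, l2, r1, r2)
    state <- .admm_slack_dual(state, problem, hyper)
    state$iteration <- state$iteration + 1L

    traj[[it]] <- tibble::tibble(sweep = it, lambda1 = l1, lambda2 = l2,
                                 rho1 = r1, rho2 = r2)
    rel <- sum(vapply(seq_len(G), function(g) {
      sum(abs(state$Theta[[g]] - old[[g]]))
    }, numeric(1))) / sum(vapply(old, function(M) sum(abs(M)), numeric(1)))
    if (rel <= epsilon) break
  }

  fit <- suppressWarnings(fit_fgl(problem, fgl_hyper(l1, l2, r1, r2),
                                  epsilon = refit_epsilon))
  structure(
    list(lambda1 = l1, lambda2 = l2, rho1 = r1, rho2 = r2,
         score = NA_real_, score_surface = NULL, fit = fit, method = "dd",
         n_solves = 2L, trajectory = dplyr::bind_rows(traj),
         sweeps = state$iteration, relative_change = rel),
    class = "fgl_tune"
  )
}

#' Train the data-driven hyperparameter networks on synthetic problems
#'
#' Generates joint-estimation problems with known precision support from the
#' supplied scenario specifications and searches the network weights
#' (derivative-free Nelder-Mead over the 15 weights) to maximize the average
#' off-diagonal support-recovery accuracy of the tuned fits. The best
#' weights seen are returned even if the search degrades late (best
#' -checkpoint rule); `epochs = 0` returns the initialization unchanged.
#'
#' @param training_scenarios List of [precision_sim_spec()] objects (or
#'   scenario id strings understood by [gen_scenario()]).
#' @param epochs Number of Nelder-Mead iterations (default 60).
#' @param seed Integer seed controlling problem generation; training is
#'   deterministic given it.
#' @param nets Starting networks (default identity).
#' @param admm_iter Sweep cap used inside each tuning evaluation.
#' @return A trained [dd_networks()] object with `training_loss` history.
#' @export
train_dd_networks <- function(training_scenarios, epochs = 60, seed = 1,
                              nets = dd_networks(), admm_iter = 100) {
  stopifnot(length(training_scenarios) >= 1L)
  set.seed(seed)
  problems <- lapply(training_scenarios, function(sc) {
    dat <- if (is.character(sc) || is.numeric(sc)) {
      gen_scenario(sc)
    } else {
      stopifnot(inherits(sc, "precision_sim_spec"))
      x <- gen_precision(sc)
      list(
        X1 = .rmvnorm_chol(sc$n1, x$Sigma0),
        X2 = .rmvnorm_chol(sc$n2, x$Sigma0),
        Theta0 = x$Theta0
      )
    }
    list(problem = empirical_covariances(list(dat$X1, dat$X2)),
         Theta0 = dat$Theta0)
  })

  loss_fn <- function(par) {
    cand <- .dd_unpack(par)
    acc <- vapply(problems, function(pb) {
      tn <- tryCatch(
        dd_tune(pb$problem, cand, max_iter = admm_iter,
                refit_epsilon = 1e-6),
        error = function(e) NULL)
      if (is.null(tn)) return(0)
      est <- fgl_support(tn$fit)
      support_metrics(est, pb$Theta0)$accuracy
    }, numeric(1))
    100 - mean(acc)
  }

  par0 <- .dd_pack(nets)
  best_par <- par0
  best_loss <- loss_fn(par0)
  history <- best_loss
  if (epochs > 0) {
    tracker <- function(par) {
      l <- loss_fn(par)
      history <<- c(history, l)
      if (l < best_loss) {
        best_loss <<- l
        best_par <<- par
      }
      l
    }
    stats::optim(par0, tracker, method = "Nelder-Mead",
                 control = list(maxit = epochs, reltol = 1e-4))
  }
  out <- .dd_unpack(best_par)
  out$trained <- epochs > 0
  out$training_loss <- history
  out$best_loss <- best_loss
  out
}

#' Serialize data-driven networks to JSON
#'
#' Weights are written at full double precision so that a round trip through
#' [read_dd_networks()] is bit-exact.
#'
#' @param nets A [dd_networks()] object.
#' @param path Output file path.
#' @export
write_dd_networks <- function(nets, path) {
  stopifnot(inherits(nets, "dd_networks"))
  payload <- list(
    lambda1 = format(nets$lambda1, digits = 17),
    lambda2 = format(nets$lambda2, digits = 17),
    rho1 = format(nets$rho1, digits = 17),
    rho2 = format(nets$rho2, digits = 17),
    trained = nets$trained
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_dd_networks
#' @export
read_dd_networks <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- dd_networks(
    lambda1 = as.numeric(payload$lambda1),
    lambda2 = as.numeric(payload$lambda2),
    rho1 = as.numeric(payload$rho1),
    rho2 = as.numeric(payload$rho2)
  )
  nets$trained <- isTRUE(payload$trained)
  nets
}
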