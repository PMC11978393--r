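# Constants of the mixed-linear component model: the mixture weights of the
# uniform and Laplace parts. With z1 uniform on (-sqrt(3), sqrt(3)) and z2
# standard Laplace (rate sqrt(2)), the component m~ z1 + m^ z2 has mean 0,
# variance m~^2 + m^^2 = 1.0000 and fourth moment 1.8 m~^4 + 6 m~^2 m^^2 +
# 6 m^^4 = 3.00, matching the Gaussian moment conditions.
MIXED_M_TILDE <- 0.7827
MIXED_M_HAT <- 0.6224

#' Draw iid standardized components for the mean-test designs
#'
#' Model `"gaussian"`: standard normal draws. Model `"mixed_linear"`: the
#' two-part mixture \eqn{\tilde m z_1 + \hat m z_2} with \eqn{z_1} uniform on
#' \eqn{(-\sqrt3, \sqrt3)} and \eqn{z_2} double-exponential with density
#' \eqn{(\sqrt2/2) e^{-\sqrt2 |z|}}, standardized so its first four moments
#' match the standard normal (a non-Gaussian model satisfying the moment
#' conditions of the RIHT limit theory).
#'
#' @param model `"gaussian"`/`"I"` or `"mixed_linear"`/`"II"`.
#' @param count Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `count`.
#' @export
gen_model_component <- function(model, count, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(count >= 1)
  model <- .match_model(model)
  if (model == "gaussian") {
    rnorm(count)
  } else {
    z1 <- runif(count, -sqrt(3), sqrt(3))
    z2 <- rexp(count, rate = sqrt(2)) * sample(c(-1, 1), count, replace = TRUE)
    MIXED_M_TILDE * z1 + MIXED_M_HAT * z2
  }
}

.match_model <- function(model) {
  switch(as.character(model),
         "gaussian" = , "I" = , "1" = "gaussian",
         "mixed_linear" = , "II" = , "2" = "mixed_linear",
         stop("Unknown model '", model,
              "'; use \"gaussian\" or \"mixed_linear\".", call. = FALSE))
}

.match_covariance <- function(covariance) {
  switch(as.character(covariance),
         "independent" = , "ind" = "independent",
         "spike" = "spike",
         stop("Unknown covariance '", covariance,
              "'; use \"independent\" or \"spike\".", call. = FALSE))
}

#' Specification of a two-group mean-test simulation
#'
#' @param model Component model, `"gaussian"` or `"mixed_linear"`.
#' @param covariance `"independent"` (identity) or `"spike"`
#'   (\eqn{0.3 I + 0.7 \mathbf{1}\mathbf{1}'}, one spiked eigenvalue
#'   \eqn{0.3 + 0.7p}).
#' @param p Dimension (number of channels); default 63.
#' @param n1,n2 Group sample sizes.
#' @param kappa Alternative strength in \[0, 20\]; 0 is the null design.
#' @param s_star Step size of the alternative mean. Defaults to 3e-3 for
#'   (n1, n2) = (100, 20) and 3e-2 for (20, 20); required otherwise when
#'   `kappa > 0`.
#' @param seed Optional integer seed stored in the specification object.
#' @return Object of class `mean_sim_spec`.
#' @export
mean_sim_spec <- function(model, covariance, p = 63, n1, n2, kappa = 0,
                          s_star = NULL, seed = NULL) {
  model <- .match_model(model)
  covariance <- .match_covariance(covariance)
  check_scalar(p, "p", lower = 1)
  check_scalar(kappa, "kappa", lower = 0)
  if (is.null(s_star)) {
    s_star <- if (n1 == 100 && n2 == 20) 3e-3
    else if (n1 == 20 && n2 == 20) 3e-2
    else if (kappa == 0) 1 # unused under the null
    else stop("`s_star` has defaults only for (n1, n2) = (100, 20) and ",
              "(20, 20); supply it explicitly.", call. = FALSE)
  }
  check_scalar(s_star, "s_star", lower = 0, strict_lower = TRUE)
  structure(list(model = model, covariance = covariance, p = p,
                 n1 = n1, n2 = n2, kappa = kappa, s_star = s_star,
                 seed = seed),
            class = "mean_sim_spec")
}

# Symmetric square root of the spike covariance 0.3 I + 0.7 11': closed form
# sqrt(0.3) I + (sqrt(0.3 + 0.7 p) - sqrt(0.3)) / p * 11'.
.spike_sqrt <- function(p) {
  a <- sqrt(0.3)
  b <- (sqrt(0.3 + 0.7 * p) - a) / p
  M <- matrix(b, p, p)
  diag(M) <- diag(M) + a
  M
}

#' Generate one two-group dataset from the independent-component model
#'
#' Observations are \eqn{x = T\xi + \mu_g} with \eqn{TT' = \Sigma} (T the
#' symmetric square root) and iid standardized components \eqn{\xi}. Group 1
#' has mean zero; group 2's jth mean component is \eqn{(-1)^j \kappa s^*
#' \nu_j} with \eqn{\nu_j \sim N(0,1)} drawn fresh per call, so `kappa = 0`
#' reproduces the null.
#'
#' @param spec A [mean_sim_spec()].
#' @return A [grouped_samples()] with two groups.
#' @export
gen_mean_groups <- function(spec) {
  stopifnot(inherits(spec, "mean_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- spec$p
  Tm <- if (spec$covariance == "spike") .spike_sqrt(p) else NULL
  draw <- function(ng, mu) {
    X <- matrix(gen_model_component(spec$model, ng * p), ng, p)
    if (!is.null(Tm)) X <- X %*% Tm
    if (!is.null(mu)) X <- sweep(X, 2L, mu, "+")
    X
  }
  mu2 <- if (spec$kappa > 0) {
    (-1)^(seq_len(p)) * spec$kappa * spec$s_star * rnorm(p)
  } else NULL
  grouped_samples(list(draw(spec$n1, NULL), draw(spec$n2, mu2)))
}

#' Specification of a sparse precision-matrix simulation
#'
#' @param p Dimension; default 50.
#' @param s Off-diagonal sparsity level in (0, 1): the fraction of the
#'   p(p-1) off-diagonal slots carrying an edge.
#' @param u_range Interval the nonzero edge weights are drawn from
#'   (uniformly); default c(0.5, 1).
#' @param n1,n2 Group sample sizes.
#' @param seed Optional integer seed stored in the specification object.
#' @return Object of class `precision_sim_spec`.
#' @export
precision_sim_spec <- function(p = 50, s, u_range = c(0.5, 1), n1, n2,
                               seed = NULL) {
  check_scalar(p, "p", lower = 2)
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  if (s >= 1) stop("`s` must be in (0, 1).", call. = FALSE)
  if (length(u_range) != 2L || u_range[1] <= 0 || u_range[2] <= u_range[1]) {
    stop("`u_range` must be (u_min, u_max) with 0 < u_min < u_max.",
         call. = FALSE)
  }
  structure(list(p = p, s = s, u_range = u_range, n1 = n1, n2 = n2,
                 seed = seed),
            class = "precision_sim_spec")
}

#' Generate a sparse precision matrix and its covariance
#'
#' Builds a symmetric 0/1 adjacency with exactly `round(s p (p-1) / 2)`
#' upper-triangle edges, masks a matrix of uniform weights with it,
#' symmetrizes, and adds \eqn{\epsilon I} with \eqn{\epsilon} chosen so the
#' smallest eigenvalue is at least 0.1, guaranteeing positive definiteness
#' for every seed.
#'
#' @param spec A [precision_sim_spec()].
#' @return List with `Theta0` (precision), `Sigma0` (its inverse),
#'   `support` (logical adjacency), `epsilon`.
#' @export
gen_precision <- function(spec) {
  stopifnot(inherits(spec, "precision_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- spec$p
  n_slots <- p * (p - 1) / 2
  n_edges <- round(spec$s * p * (p - 1) / 2)
  if (n_edges > n_slots) {
    stop("Infeasible sparsity: ", n_edges, " edges requested but only ",
         n_slots, " upper-triangle slots exist.", call. = FALSE)
  }
  Ds <- matrix(0, p, p)
  ut <- which(upper.tri(Ds))
  picked <- sample(ut, n_edges)
  Ds[picked] <- 1
  Ds <- Ds + t(Ds)
  U <- matrix(runif(p * p, spec$u_range[1], spec$u_range[2]), p, p)
  M <- Ds * U
  A <- (M + t(M)) / 2
  eps <- max(0, -min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) +
    0.1
  Theta0 <- A + diag(eps, p)
  list(Theta0 = Theta0, Sigma0 = solve(Theta0), support = Ds > 0,
       epsilon = eps)
}

# Multivariate normal draws through the Cholesky factor.
.rmvnorm_chol <- function(n, Sigma) {
  p <- nrow(Sigma)
  matrix(rnorm(n * p), n, p) %*% chol(Sigma)
}

.scenario_table <- list(
  I = list(s = 0.1, n = 200), II = list(s = 0.1, n = 500),
  III = list(s = 0.3, n = 200), IV = list(s = 0.3, n = 500),
  V = list(s = 0.5, n = 200), VI = list(s = 0.5, n = 500)
)

#' Generate one replicate of a named precision-matrix scenario
#'
#' Scenarios I-VI share p = 50 and cross sparsity s in \{0.1, 0.3, 0.5\}
#' with per-group sample size n in \{200, 500\}. Both groups are drawn under
#' the null (a common precision matrix), mean zero.
#'
#' @param id Scenario id: "I".."VI" (or 1..6).
#' @param seed Optional integer seed.
#' @return List with `X1`, `X2` (n x 50 matrices), `Theta0`, `Sigma0`,
#'   `support`, `spec`.
#' @export
gen_scenario <- function(id, seed = NULL) {
  if (is.numeric(id)) id <- c("I", "II", "III", "IV", "V", "VI")[id]
  id <- match.arg(as.character(id), names(.scenario_table))
  cfg <- .scenario_table[[id]]
  if (!is.null(seed)) set.seed(seed)
  spec <- precision_sim_spec(p = 50, s = cfg$s, n1 = cfg$n, n2 = cfg$n)
  truth <- gen_precision(spec)
  list(X1 = .rmvnorm_chol(cfg$n, truth$Sigma0),
       X2 = .rmvnorm_chol(cfg$n, truth$Sigma0),
       Theta0 = truth$Theta0, Sigma0 = truth$Sigma0,
       support = truth$support, spec = spec, id = id)
}

#' Support-recovery metrics for an estimated precision pattern
#'
#' Off-diagonal recall of true edges (R1), of true non-edges (R0), and the
#' overall fraction of correctly classified off-diagonal slots (accuracy),
#' all as percentages of the p(p-1) ordered off-diagonal pairs.
#'
#' @param estimated_support Logical p x p matrix (or numeric, nonzero =
#'   edge); the diagonal is ignored.
#' @param Theta0 True precision matrix (or logical support matrix).
#' @return A one-row tibble with columns `R1`, `R0`, `accuracy`.
#' @export
support_metrics <- function(estimated_support, Theta0) {
  est <- estimated_support != 0
  truth <- Theta0 != 0
  if (!all(dim(est) == dim(truth))) {
    stop("Dimension mismatch between estimate and truth.", call. = FALSE)
  }
  p <- nrow(truth)
  off <- !diag(p)
  n_true <- sum(truth & off)
  n_false <- sum(!truth & off)
  s1 <- sum(est & truth & off)
  s0 <- sum(!est & !truth & off)
  tibble::tibble(
    R1 = if (n_true == 0) NA_real_ else 100 * s1 / n_true,
    R0 = if (n_false == 0) NA_real_ else 100 * s0 / n_false,
    accuracy = 100 * (s1 + s0) / (p * (p - 1))
  )
}

#' Empirical size and power of the RIHT test over a kappa grid
#'
#' For each alternative strength `kappa`, repeatedly generates two-group
#' data from [gen_mean_groups()] and records the rejection fraction of the
#' plug-in [riht_test()]. The `kappa = 0` row is the empirical size.
#'
#' @param model,covariance,p,n1,n2,s_star Passed to [mean_sim_spec()].
#' @param kappas Vector of alternative strengths (default 0, the null).
#' @param reps Replicates per kappa.
#' @param lambda,alpha Passed to [riht_test()].
#' @param seed Integer seed; results are bit-reproducible given it.
#' @return A tibble of class `riht_power_study` with columns `kappa`,
#'   `rejections`, `reps`, `rate`.
#' @export
size_power_study <- function(model, covariance, n1, n2, p = 63,
                             kappas = 0, reps = 1000, s_star = NULL,
                             lambda = 1, alpha = 0.05, seed = 1) {
  stopifnot(reps >= 1)
  set.seed(seed)
  rows <- lapply(kappas, function(k) {
    spec <- mean_sim_spec(model, covariance, p = p, n1 = n1, n2 = n2,
                          kappa = k, s_star = s_star)
    rej <- 0L
    for (r in seq_len(reps)) {
      res <- riht_test(gen_mean_groups(spec), lambda = lambda, alpha = alpha)
      rej <- rej + res$reject
    }
    tibble::tibble(kappa = k, rejections = rej, reps = reps,
                   rate = rej / reps)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("riht_power_study", class(out))
  out
}

.default_locations <- list(
  V = list(c(1, 3), c(2, 2), c(2, 4), c(6, 6)),
  VI = list(c(1, 9), c(3, 10), c(4, 10), c(15, 12))
)

#' Null sampling distribution of the entrywise precision-change statistic
#'
#' Draws the true precision matrix once per scenario (the study locations
#' are specific entries of one realized matrix, so the truth is held fixed),
#' then for each replicate: generate fresh X1, X2 under the null (shared
#' precision), select hyperparameters, fit the fused graphical lasso,
#' de-bias, and record the standardized two-sample statistic (coefficients
#' 1, -1) at the requested matrix locations. Pooled over replicates these
#' samples should look standard normal if the test is calibrated.
#'
#' @param scenario Scenario id passed to [gen_scenario()].
#' @param reps Number of replicates.
#' @param locations List of `c(i, j)` pairs; defaults are provided for
#'   scenarios V and VI.
#' @param tune `"dd"` (default: one data-driven trajectory per replicate),
#'   `"aic"` (grid search with `grid`), or `"none"` (fixed `hyper`).
#' @param grid [fgl_grid()] used when `tune = "aic"`; default is a 5 x 5
#'   coarsening of the standard grid.
#' @param nets [dd_networks()] used when `tune = "dd"`.
#' @param hyper [fgl_hyper()] used when `tune = "none"`.
#' @param seed Integer seed.
#' @return A tibble of class `mpde_null_study` with columns `rep`, `i`, `j`,
#'   `location`, `statistic`.
#' @export
null_distribution_study <- function(scenario, reps = 200, locations = NULL,
                                    tune = c("dd", "aic", "none"),
                                    grid = fgl_grid(n = 5),
                                    nets = dd_networks(),
                                    hyper = fgl_hyper(0.1, 0.1),
                                    seed = 1) {
  tune <- match.arg(tune)
  if (is.numeric(scenario)) {
    scenario <- c("I", "II", "III", "IV", "V", "VI")[scenario]
  }
  if (is.null(locations)) {
    locations <- .default_locations[[scenario]]
    if (is.null(locations)) {
      stop("No default locations for scenario ", scenario,
           "; supply `locations`.", call. = FALSE)
    }
  }
  set.seed(seed)
  truth <- gen_scenario(scenario)
  cfg <- .scenario_table[[scenario]]
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    X1 <- .rmvnorm_chol(cfg$n, truth$Sigma0)
    X2 <- .rmvnorm_chol(cfg$n, truth$Sigma0)
    problem <- empirical_covariances(list(X1, X2))
    fit <- switch(tune,
      dd = dd_tune(problem, nets)$fit,
      aic = aic_grid_search(problem, grid)$fit,
      none = suppressWarnings(fit_fgl(problem, hyper))
    )
    res <- mpde_test(debias_fit(fit), a = c(1, -1))
    rows[[r]] <- dplyr::bind_rows(lapply(locations, function(loc) {
      tibble::tibble(rep = r, i = loc[1], j = loc[2],
                     location = paste0("(", loc[1], ",", loc[2], ")"),
                     statistic = res$stat[loc[1], loc[2]])
    }))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mpde_null_study", class(out))
  out
}
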