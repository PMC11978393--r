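#' De-bias a penalized precision-matrix estimate
#'
#' Applies the correction \eqn{\tilde\Theta = 2\hat\Theta - \hat\Theta S
#' \hat\Theta}, which removes the first-order bias introduced by the l1
#' penalties so that entrywise asymptotic normality holds. An exact inverse
#' is a fixed point: \eqn{\hat\Theta = S^{-1}} gives \eqn{\tilde\Theta =
#' S^{-1}}.
#'
#' @param Theta_hat Positive definite p x p estimate.
#' @param S The p x p empirical covariance used in the fit.
#' @return A symmetric p x p matrix.
#' @examples
#' debias(diag(2), diag(2)) # identity
#' @export
debias <- function(Theta_hat, S) {
  if (!is.matrix(Theta_hat) || !is.matrix(S) ||
      any(dim(Theta_hat) != dim(S)) || nrow(S) != ncol(S)) {
    stop("`Theta_hat` and `S` must be square matrices of equal dimension.",
         call. = FALSE)
  }
  sym_part(2 * Theta_hat - Theta_hat %*% S %*% Theta_hat)
}

#' Bundle de-biased precision matrices across groups
#'
#' @param Theta_tilde List of G symmetric p x p de-biased matrices, e.g. from
#'   applying [debias()] to each group of an [fit_fgl()] result.
#' @param sample_sizes Per-group sample sizes.
#' @return Object of class `debiased_set`.
#' @export
debiased_set <- function(Theta_tilde, sample_sizes) {
  if (is.matrix(Theta_tilde)) Theta_tilde <- list(Theta_tilde)
  G <- length(Theta_tilde)
  p <- nrow(Theta_tilde[[1L]])
  for (g in seq_len(G)) {
    check_symmetric(Theta_tilde[[g]], paste0("Theta_tilde[[", g, "]]"),
                    tol = 1e-6)
    Theta_tilde[[g]] <- sym_part(Theta_tilde[[g]])
  }
  if (length(sample_sizes) != G) {
    stop("Need one sample size per group.", call. = FALSE)
  }
  structure(list(Theta_tilde = Theta_tilde,
                 sample_sizes = as.integer(sample_sizes), p = p, G = G),
            class = "debiased_set")
}

#' De-bias every group of a fused-graphical-lasso fit
#'
#' @param fit An [fit_fgl()] result.
#' @return A [debiased_set()].
#' @export
debias_fit <- function(fit) {
  stopifnot(inherits(fit, "fgl_fit"))
  debiased_set(
    lapply(seq_len(fit$problem$G), function(g) {
      debias(fit$Theta_hat[[g]], fit$problem$covariances[[g]])
    }),
    fit$problem$sample_sizes
  )
}

#' Entrywise z-test of a linear combination of precision matrices
#'
#' Tests \eqn{H_0: a_1\Theta^0_{1;ij} + \dots + a_G\Theta^0_{G;ij} =
#' \Theta^0_{ij}} at every location (i, j), using the de-biased estimates:
#' \deqn{T_{ij} = \sum_g a_g \tilde\Theta_{g;ij}, \qquad
#'  \hat\sigma^2_{ij} = \sum_g a_g^2 (\tilde\Theta_{g;ii}
#'  \tilde\Theta_{g;jj} + \tilde\Theta_{g;ij}^2),}
#' and the standardized statistic \eqn{\sqrt{n}\,(T_{ij} - \Theta^0_{ij}) /
#' \hat\sigma_{ij}}, asymptotically standard normal under the null. With
#' `a = c(1, -1)` and G = 2 this tests whether each conditional dependence
#' changed between the two populations.
#'
#' @param debiased A [debiased_set()] (or an `fgl_fit`, de-biased on the fly).
#' @param a Numeric coefficient vector of length G.
#' @param null_value Null matrix \eqn{\Theta^0} (scalar or p x p; default 0).
#' @param n_eff Sample size used in the \eqn{\sqrt{n}} standardization.
#'   Defaults to the total `sum(sample_sizes)`, the convention under which
#'   `n` denotes the pooled sample size across populations; pass
#'   `min(sample_sizes)` (or any positive value) for a per-group scaling.
#' @param alpha_edge Significance threshold used to declare an edge changed
#'   (default 0.01).
#' @param p_adjust "none" (default) or "BH" for a Benjamini-Hochberg
#'   correction over the upper-triangle p-values.
#' @return Object of class `mpde_result`: list with `coefficients`, `stat`
#'   and `pvalues` (symmetric p x p matrices), `edges` (tibble of retained
#'   pairs i < j), `n_eff`, `alpha_edge`.
#' @examples
#' ds <- debiased_set(list(diag(3), diag(3)), c(50, 50))
#' mpde_test(ds, a = c(1, -1))$edges
#' @export
mpde_test <- function(debiased, a, null_value = 0, n_eff = NULL,
                      alpha_edge = 0.01, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (inherits(debiased, "fgl_fit")) debiased <- debias_fit(debiased)
  stopifnot(inherits(debiased, "debiased_set"))
  G <- debiased$G
  p <- debiased$p
  if (length(a) != G) {
    stop("`a` must have length G = ", G, ".", call. = FALSE)
  }
  if (is.null(n_eff)) {
    n_eff <- sum(debiased$sample_sizes)
  }
  check_scalar(n_eff, "n_eff", lower = 0, strict_lower = TRUE)
  if (length(null_value) == 1L) {
    null_value <- matrix(null_value, p, p)
  }

  Tm <- matrix(0, p, p)
  Vm <- matrix(0, p, p)
  for (g in seq_len(G)) {
    Th <- debiased$Theta_tilde[[g]]
    Tm <- Tm + a[g] * Th
    Vm <- Vm + a[g]^2 * (diag(Th) %o% diag(Th) + Th^2)
  }
  sigma <- sqrt(Vm)
  stat <- sqrt(n_eff) * (Tm - null_value) / sigma
  if (any(Vm <= 0)) {
    warning(sum(Vm <= 0), " entr",
            if (sum(Vm <= 0) == 1) "y has" else "ies have",
            " zero estimated variance; statistic set to NaN there.",
            call. = FALSE)
    stat[Vm <= 0] <- NaN
  }
  stat <- sym_part(stat)
  pvals <- 2 * pnorm(-abs(stat))

  ut <- which(upper.tri(pvals), arr.ind = TRUE)
  pv <- pvals[ut]
  crit <- if (p_adjust == "BH") {
    stats::p.adjust(pv, method = "BH") < alpha_edge
  } else {
    pv < alpha_edge
  }
  crit[is.na(crit)] <- FALSE
  edges <- tibble::tibble(
    i = ut[crit, 1L], j = ut[crit, 2L],
    statistic = stat[ut][crit], p_value = pv[crit]
  )
  edges <- dplyr::arrange(edges, .data$p_value)

  structure(
    list(coefficients = a, stat = stat, pvalues = pvals, edges = edges,
         n_eff = n_eff, alpha_edge = alpha_edge, p_adjust = p_adjust),
    class = "mpde_result"
  )
}

#' @export
print.mpde_result <- function(x, ...) {
  cat("<mpde_result> p =", nrow(x$stat), " coefficients:",
      paste(x$coefficients, collapse = ", "),
      " n_eff =", x$n_eff, "\n")
  cat("  ", nrow(x$edges), "significant edge(s) at p <", x$alpha_edge, "\n")
  invisible(x)
}

#' Labelled network of significantly changed conditional dependencies
#'
#' @param result An [mpde_test()] result.
#' @param labels Character vector of channel names, length p.
#' @return A tibble with columns `from`, `to` (labels), `i`, `j`,
#'   `statistic`, `p_value`; one row per retained undirected edge.
#' @export
significant_network <- function(result, labels) {
  stopifnot(inherits(result, "mpde_result"))
  p <- nrow(result$stat)
  if (length(labels) != p) {
    stop("`labels` must have length p = ", p, ".", call. = FALSE)
  }
  dplyr::mutate(result$edges,
                from = labels[.data$i], to = labels[.data$j],
                .before = 1L)
}
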