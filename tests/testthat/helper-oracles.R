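# Independent oracles and small fixture builders used across the suite.

rand_spd <- function(p, jitter = 0.5) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(jitter, p)
}

off_zero <- function(M) {
  diag(M) <- 0
  M
}

# Generic convex oracle for the fused-graphical-lasso objective: smooth the
# l1 terms (|x| ~ sqrt(x^2 + mu^2)), parametrize each precision matrix by
# its Cholesky factor with log-diagonal, and minimize by BFGS. Entirely
# independent of the ADMM path; accurate to O(mu * #terms) in the optimum.
fgl_oracle_value <- function(Ss, lambda1, lambda2, mu = 1e-7,
                             maxit = 5000) {
  G <- length(Ss)
  p <- nrow(Ss[[1]])
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE))
  npar <- length(idx)
  par2theta <- function(par) {
    lapply(seq_len(G), function(g) {
      L <- matrix(0, p, p)
      L[idx] <- par[((g - 1) * npar + 1):(g * npar)]
      diag(L) <- exp(diag(L))
      L %*% t(L)
    })
  }
  smooth_l1 <- function(M) sum(sqrt(off_zero(M)^2 + mu^2) - mu)
  fn <- function(par) {
    Th <- par2theta(par)
    val <- 0
    for (g in seq_len(G)) {
      val <- val + sum(Ss[[g]] * Th[[g]]) -
        as.numeric(determinant(Th[[g]])$modulus) +
        lambda1 * smooth_l1(Th[[g]])
    }
    if (G > 1) {
      for (g in seq_len(G - 1)) {
        for (h in seq(g + 1, G)) {
          val <- val + lambda2 * smooth_l1(Th[[g]] - Th[[h]])
        }
      }
    }
    val
  }
  o <- stats::optim(rep(0, G * npar), fn, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-15))
  o$value
}

# Proximal-gradient (ISTA) oracle for the standardized lasso objective
# (1/n) ||y - X b||^2 + lambda ||b||_1.
lasso_oracle <- function(X, y, lambda, iters = 20000) {
  n <- nrow(X)
  L <- 2 * max(eigen(crossprod(X) / n, symmetric = TRUE,
                     only.values = TRUE)$values)
  b <- numeric(ncol(X))
  for (k in seq_len(iters)) {
    grad <- -2 * crossprod(X, y - X %*% b) / n
    z <- b - grad / L
    b_new <- sign(z) * pmax(abs(z) - lambda / L, 0)
    if (max(abs(b_new - b)) < 1e-12) {
      b <- b_new
      break
    }
    b <- b_new
  }
  b
}

lasso_objective <- function(X, y, b, lambda) {
  sum((y - X %*% b)^2) / nrow(X) + lambda * sum(abs(b))
}

# Direct scalar computation of the standardized ridge-regularized statistic
# for p = 1, written independently of the package internals.
riht_scalar_oracle <- function(g1, g2, lambda) {
  n1 <- length(g1)
  n2 <- length(g2)
  n <- n1 + n2
  e1 <- n - 2
  mu <- mean(c(g1, g2))
  s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / e1
  r <- n1 * (mean(g1) - mu)^2 / (s2 + lambda) +
    n2 * (mean(g2) - mu)^2 / (s2 + lambda)
  m <- 1 / (s2 + lambda)
  mp <- m^2
  gam <- 1 / e1
  D <- 1 - gam * (1 - lambda * m)
  th1 <- (1 - lambda * m) / D
  th2 <- (1 - lambda * m) / D^3 - lambda * (m - lambda * mp) / D^4
  (r - th1) / sqrt(2 * th2)
}

# Two-group samples with a planted difference in one precision matrix.
planted_precision_pair <- function(p = 20, n = 400, edges_changed = 2,
                                   strength = 0.6) {
  base <- matrix(0, p, p)
  for (k in seq_len(p - 1)) {
    base[k, k + 1] <- base[k + 1, k] <- 0.4
  }
  diag(base) <- 2
  Theta1 <- base
  Theta2 <- base
  planted <- list()
  for (e in seq_len(edges_changed)) {
    i <- 2 * e
    j <- 2 * e + 5
    Theta2[i, j] <- Theta2[j, i] <- strength
    planted[[e]] <- c(i, j)
  }
  X1 <- matrix(rnorm(n * p), n) %*% chol(solve(Theta1))
  X2 <- matrix(rnorm(n * p), n) %*% chol(solve(Theta2))
  list(X1 = X1, X2 = X2, Theta1 = Theta1, Theta2 = Theta2,
       planted = planted)
}

# Pre/post design with one shifted channel, used by the channel tests.
make_design <- function(n = 80, p = 6, shift = 1.5, seed = 90) {
  set.seed(seed)
  Y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 3] <- X[, 3] + shift * Y
  list(X = X, Y = Y)
}
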