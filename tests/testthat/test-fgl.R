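test_that("soft_threshold implements the piecewise map", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-1.2, 0.5), -0.7)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(0.5, 0.5), 0) # boundary maps to zero
  M <- matrix(c(5, 1.2, -1.2, 5), 2)
  out <- soft_threshold(M, 0.5, offdiag = TRUE)
  expect_equal(out, matrix(c(0, 0.7, -0.7, 0), 2))
  expect_error(soft_threshold(1:3, 0.5, offdiag = TRUE), "square")
})

test_that("soft_threshold is a contraction", {
  set.seed(30)
  a <- rnorm(200, sd = 3)
  b <- rnorm(200, sd = 3)
  for (alpha in c(0, 0.3, 2)) {
    expect_true(all(abs(soft_threshold(a, alpha) - soft_threshold(b, alpha))
                    <= abs(a - b) + 1e-12))
  }
})

test_that("empirical covariances center by group and keep shape", {
  expect_equal(
    empirical_covariances(list(matrix(c(1, -1, 0, 0), 2)))$covariances[[1]],
    matrix(c(1, 0, 0, 0), 2))
  row <- c(2, -1, 3)
  pr <- empirical_covariances(list(rbind(row, row, row)))
  expect_equal(pr$covariances[[1]], matrix(0, 3, 3))
  set.seed(31)
  pr2 <- empirical_covariances(list(matrix(rnorm(40), 10),
                                    matrix(rnorm(20), 5)))
  expect_equal(dim(pr2$covariances[[2]]), c(4L, 4L))
  expect_error(empirical_covariances(list(matrix(1, 1, 2))),
               "at least 2")
})

test_that("update_theta solves its stationarity equation", {
  expect_equal(update_theta(matrix(0, 2, 2), 1), diag(2))
  out <- update_theta(diag(c(2, -2)), 1)
  expect_equal(diag(out), c((-2 + sqrt(8)) / 2, (2 + sqrt(8)) / 2))
  set.seed(32)
  Y <- sym_Y <- matrix(rnorm(25), 5)
  Y <- (Y + t(Y)) / 2
  for (rho in c(0.5, 1, 3)) {
    Th <- update_theta(Y, rho)
    expect_true(all(eigen(Th, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
    resid <- rho * Th %*% Th + Y %*% Th - diag(5)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("assemble_y handles the three boundary cases", {
  set.seed(33)
  make_problem <- function(G, p = 3) {
    fgl_problem(replicate(G, rand_spd(p), simplify = FALSE), rep(10, G))
  }
  hy <- fgl_hyper(0.1, 0.1, rho1 = 2, rho2 = 3)

  # G = 1: no fusion terms at all
  pr1 <- make_problem(1)
  st1 <- admm_initialize(pr1, hy)
  expect_equal(assemble_y(1, st1, pr1, hy),
               pr1$covariances[[1]] + 2 * (st1$V[[1]] - st1$Z[[1]]))

  # G = 2, g = 1 with zeroed slack/dual and Theta2 = 0 reduces to S
  pr2 <- make_problem(2)
  st2 <- admm_initialize(pr2, hy, init = "zeros")
  st2$Z[[1]] <- matrix(0, 3, 3)
  st2$Delta[[1]] <- matrix(0, 3, 3)
  st2$Theta[[2]] <- matrix(0, 3, 3)
  expect_equal(assemble_y(1, st2, pr2, hy), pr2$covariances[[1]])

  # interior group: the two fusion terms enter with opposite signs
  pr3 <- make_problem(3)
  st3 <- admm_initialize(pr3, hy, init = "zeros")
  Y <- assemble_y(2, st3, pr3, hy)
  manual <- pr3$covariances[[2]] +
    hy$rho1 * (st3$V[[2]] - st3$Z[[2]]) -
    hy$rho2 * (st3$U[[1]] - st3$Delta[[1]] + st3$Theta[[1]]) +
    hy$rho2 * (st3$U[[2]] - st3$Delta[[2]] - st3$Theta[[3]])
  expect_equal(Y, (manual + t(manual)) / 2)
  expect_error(assemble_y(4, st3, pr3, hy), "out of range")
})

test_that("a huge sparsity penalty zeroes the slack off-diagonals", {
  set.seed(34)
  pr <- fgl_problem(list(rand_spd(4)), 10)
  hy <- fgl_hyper(lambda1 = 1e6, lambda2 = 0)
  st <- admm_step(admm_initialize(pr, hy), pr, hy)
  expect_equal(off_zero(st$Z[[1]]), matrix(0, 4, 4))
})

test_that("one step preserves an ADMM fixed point", {
  set.seed(35)
  pr <- fgl_problem(list(rand_spd(4), rand_spd(4)), c(20, 20))
  hy <- fgl_hyper(0.2, 0.1)
  fit <- suppressWarnings(fit_fgl(pr, hy, epsilon = 1e-12, max_iter = 3000,
                                  engine = "r"))
  # reconstruct the converged state by replaying the R engine
  st <- admm_initialize(pr, hy)
  for (k in seq_len(fit$iterations)) st <- admm_step(st, pr, hy)
  st2 <- admm_step(st, pr, hy)
  expect_lt(max(abs(st2$Z[[1]] - st$Z[[1]])), 1e-8)
  expect_lt(max(abs(st2$Delta[[1]] - st$Delta[[1]])), 1e-8)
  expect_lt(max(abs(st2$Theta[[1]] - st$Theta[[1]])), 1e-8)
})

test_that("unpenalized single-group fit recovers the inverse covariance", {
  set.seed(36)
  S <- rand_spd(5)
  fit <- fit_fgl(fgl_problem(list(S), 20), fgl_hyper(0, 0))
  expect_true(fit$converged)
  expect_lt(norm(fit$Theta_hat[[1]] - solve(S), "F"), 1e-4)
})

test_that("compiled and pure-R engines produce identical iterates", {
  set.seed(37)
  pr <- fgl_problem(list(rand_spd(4), rand_spd(4), rand_spd(4)),
                    c(15, 15, 15))
  hy <- fgl_hyper(0.15, 0.08, rho1 = 1.5, rho2 = 0.7)
  a <- suppressWarnings(fit_fgl(pr, hy, max_iter = 40, epsilon = 0,
                                engine = "cpp"))
  b <- suppressWarnings(fit_fgl(pr, hy, max_iter = 40, epsilon = 0,
                                engine = "r"))
  for (g in 1:3) {
    expect_lt(max(abs(a$Theta_hat[[g]] - b$Theta_hat[[g]])), 1e-10)
  }
  expect_equal(a$objective_trace, b$objective_trace, tolerance = 1e-10)
})

test_that("every precision iterate stays positive definite", {
  set.seed(38)
  pr <- fgl_problem(list(rand_spd(4, jitter = 0.05),
                         rand_spd(4, jitter = 0.05)), c(10, 10))
  hy <- fgl_hyper(0.3, 0.3, rho1 = 0.5, rho2 = 2)
  st <- admm_initialize(pr, hy)
  for (k in 1:30) {
    st <- admm_step(st, pr, hy)
    for (g in 1:2) {
      expect_gt(min(eigen(st$Theta[[g]], symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
})

test_that("the ADMM reaches the convex optimum on tiny instances", {
  set.seed(39)
  for (p in c(4, 6)) {
    Ss <- list(rand_spd(p), rand_spd(p))
    pr <- fgl_problem(Ss, c(25, 25))
    fit <- suppressWarnings(fit_fgl(pr, fgl_hyper(0.1, 0.1),
                                    epsilon = 1e-11, max_iter = 3000))
    admm_obj <- fgl_objective(fit$Theta_hat, pr, 0.1, 0.1)
    oracle_obj <- fgl_oracle_value(Ss, 0.1, 0.1)
    expect_lt(abs(admm_obj - oracle_obj), 1e-3)
  }
})

test_that("a huge fusion penalty equalizes the off-diagonals", {
  set.seed(40)
  pr <- fgl_problem(list(rand_spd(4), rand_spd(4)), c(20, 20))
  fit <- suppressWarnings(fit_fgl(pr, fgl_hyper(0.05, 500),
                                  epsilon = 1e-11, max_iter = 3000))
  d <- off_zero(fit$Theta_hat[[1]] - fit$Theta_hat[[2]])
  expect_lt(max(abs(d)), 1e-4)
})

test_that("with no fusion the joint fit decouples into single-group fits", {
  set.seed(41)
  Ss <- list(rand_spd(4), rand_spd(4))
  pr <- fgl_problem(Ss, c(20, 20))
  joint <- suppressWarnings(fit_fgl(pr, fgl_hyper(0.1, 0),
                                    epsilon = 1e-11, max_iter = 4000))
  solo <- lapply(Ss, function(S) {
    suppressWarnings(fit_fgl(fgl_problem(list(S), 20), fgl_hyper(0.1, 0),
                             epsilon = 1e-11, max_iter = 4000))
  })
  obj_joint <- fgl_objective(joint$Theta_hat, pr, 0.1, 0)
  obj_solo <- fgl_objective(list(solo[[1]]$Theta_hat[[1]],
                                 solo[[2]]$Theta_hat[[1]]), pr, 0.1, 0)
  expect_lt(abs(obj_joint - obj_solo), 1e-4)
})

test_that("the objective matches hand values and penalty identities", {
  p <- 3
  pr <- fgl_problem(list(diag(p), diag(p)), c(10, 10))
  expect_equal(fgl_objective(list(diag(p), diag(p)), pr, 0, 0), 2 * p)
  # off-diagonals zero: the sparsity penalty contributes nothing
  expect_equal(fgl_objective(list(diag(p), diag(p)), pr, 1, 0), 2 * p)
  # identical matrices: the fusion term is exactly zero for any lambda2
  Th <- rand_spd(p)
  expect_equal(fgl_objective(list(Th, Th), pr, 0, 100),
               fgl_objective(list(Th, Th), pr, 0, 0))
  expect_error(fgl_objective(list(diag(p), -diag(p)), pr, 0, 0),
               "positive definite")
})

test_that("fusion terms pair all groups while the chain couples neighbours", {
  # Eq-16-style penalty sums over G(G-1)/2 pairs; the ADMM carries G-1
  # fusion slacks. Both counts are asserted for G = 4.
  set.seed(42)
  G <- 4
  pr <- fgl_problem(replicate(G, rand_spd(3), simplify = FALSE), rep(10, G))
  st <- admm_initialize(pr, fgl_hyper(0.1, 0.1))
  expect_length(st$Delta, G - 1)
  expect_length(st$U, G - 1)
  # objective: G*(G-1)/2 fusion contributions, each 2*|eps| here
  base <- replicate(G, diag(3), simplify = FALSE)
  bumped <- base
  bumped[[1]][1, 2] <- bumped[[1]][2, 1] <- 0.5
  diff_obj <- fgl_objective(bumped, pr, 0, 1) -
    fgl_objective(base, pr, 0, 1) -
    (sum(pr$covariances[[1]] * (bumped[[1]] - base[[1]]))) -
    (as.numeric(determinant(base[[1]])$modulus) -
       as.numeric(determinant(bumped[[1]])$modulus))
  # group 1 differs from the other G-1 groups at two symmetric entries
  expect_equal(diff_obj, (G - 1) * 2 * 0.5, tolerance = 1e-10)
})

test_that("non-convergence is a warning with converged = FALSE", {
  set.seed(43)
  pr <- fgl_problem(list(rand_spd(4)), 10)
  expect_warning(
    fit <- fit_fgl(pr, fgl_hyper(0.1, 0), max_iter = 3),
    "did not reach")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3L)
})

test_that("fgl_support thresholds the off-diagonal pattern", {
  set.seed(44)
  pr <- fgl_problem(list(rand_spd(4)), 50)
  fit <- suppressWarnings(fit_fgl(pr, fgl_hyper(5, 0)))
  sup <- fgl_support(fit)
  expect_false(any(diag(sup)))
  expect_false(any(sup)) # huge penalty: empty support
})
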