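test_that("the ridge statistic matches scalar hand computations", {
  gs <- grouped_samples(list(matrix(c(0, 2)), matrix(c(2, 4))))
  st <- pooled_stats(gs)
  expect_equal(riht_statistic(st, gs, lambda = 1), 4 / 3)
  expect_error(riht_statistic(st, gs, lambda = 0), "lambda")
  expect_error(riht_statistic(st, gs, lambda = -1), "lambda")
})

test_that("equal group means give a zero statistic", {
  set.seed(7)
  g1 <- matrix(rnorm(30), 10, 3)
  g2 <- matrix(rnorm(24), 8, 3)
  g1 <- sweep(g1, 2, colMeans(g1))
  g2 <- sweep(g2, 2, colMeans(g2))
  gs <- grouped_samples(list(g1, g2))
  expect_equal(riht_statistic(pooled_stats(gs), gs, 0.5), 0)
})

test_that("the statistic decreases monotonically in lambda", {
  set.seed(8)
  gs <- grouped_samples(list(matrix(rnorm(40, 0), 10),
                             matrix(rnorm(40, 1), 10)))
  st <- pooled_stats(gs)
  vals <- vapply(c(0.1, 0.5, 1, 5, 50, 5000), function(l) {
    riht_statistic(st, gs, l)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 0.01)
})

test_that("trace functionals match the identity-covariance closed form", {
  tf <- trace_functionals(diag(6), lambda = 1, gamma_n = 0.5)
  expect_equal(tf$m, 0.5)
  expect_equal(tf$m_prime, 0.25)
  expect_equal(tf$theta1, 2 / 3)
  expect_equal(tf$theta2, 0.5 / 0.75^3 - 1 * (0.5 - 0.25) / 0.75^4)
  expect_equal(tf$theta2, 0.3950617, tolerance = 1e-6)
})

test_that("trace functionals report a singular standardization", {
  expect_error(trace_functionals(diag(100, 4), lambda = 0.01, gamma_n = 10),
               "too small for aspect ratio")
})

test_that("trace functional plug-ins estimate the true trace terms", {
  # Monte-Carlo check of the consistency claim at p = 400, n = 800, Sigma = I
  set.seed(11)
  p <- 400
  n <- 800
  gs <- grouped_samples(list(matrix(rnorm(n / 2 * p), n / 2),
                             matrix(rnorm(n / 2 * p), n / 2)))
  st <- pooled_stats(gs)
  d <- eigen(st$pooled_cov, symmetric = TRUE, only.values = TRUE)$values
  tf <- trace_functionals(st$pooled_cov, 1, st$gamma_n)
  true_tr1 <- mean(1 / (d + 1)) # (1/p) tr((S+I)^{-1} Sigma), Sigma = I
  true_tr2 <- mean(1 / (d + 1)^2)
  expect_lt(abs(true_tr1 - tf$theta1), 0.02)
  expect_lt(abs(true_tr2 - tf$theta2), 0.02)
})

test_that("riht_test is exactly invariant to permutations within groups", {
  set.seed(12)
  g1 <- matrix(rnorm(60), 12, 5)
  g2 <- matrix(rnorm(40), 8, 5)
  r1 <- riht_test(grouped_samples(list(g1, g2)))
  r2 <- riht_test(grouped_samples(list(g1[sample(12), ], g2[sample(8), ])))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$riht, r2$riht)
})

test_that("the p = 1 statistic matches an independent scalar oracle", {
  set.seed(13)
  for (k in 1:10) {
    g1 <- rnorm(sample(5:15, 1), sd = runif(1, 0.5, 2))
    g2 <- rnorm(sample(5:15, 1), mean = runif(1, -1, 1))
    lam <- runif(1, 0.2, 2)
    res <- suppressWarnings(
      riht_test(grouped_samples(list(matrix(g1), matrix(g2))),
                lambda = lam))
    expect_equal(res$statistic, riht_scalar_oracle(g1, g2, lam),
                 tolerance = 1e-10)
  }
})

test_that("plug-in and known-sigma statistics agree for Gaussian data", {
  # o(1) difference; asserted at p = 400, n = 800 over 20 seeds
  set.seed(14)
  p <- 400
  diffs <- replicate(20, {
    gs <- grouped_samples(list(matrix(rnorm(400 * p), 400),
                               matrix(rnorm(400 * p), 400)))
    a <- riht_test(gs, lambda = 1)
    b <- riht_test(gs, lambda = 1, sigma = diag(p))
    abs(a$statistic - b$statistic)
  })
  expect_lt(max(diffs), 0.2)
})

test_that("known-sigma standardization handles a zero statistic", {
  set.seed(15)
  g1 <- matrix(rnorm(50), 10, 5)
  g2 <- matrix(rnorm(50), 10, 5)
  g1 <- sweep(g1, 2, colMeans(g1))
  g2 <- sweep(g2, 2, colMeans(g2))
  res <- riht_test(grouped_samples(list(g1, g2)), sigma = diag(5))
  expect_equal(res$riht, 0)
  expect_equal(res$statistic, -res$e2 * res$tr1 / sqrt(2 * res$e2 * res$tr2))
  expect_true(is.finite(res$statistic))
})

test_that("input validation covers alpha, sigma shape and the cov warning", {
  set.seed(16)
  gs <- grouped_samples(list(matrix(rnorm(20), 10), matrix(rnorm(20), 10)))
  expect_error(riht_test(gs, alpha = 0), "alpha")
  expect_error(riht_test(gs, alpha = 1), "alpha")
  expect_error(riht_test(gs, sigma = diag(3)), "sigma")
  noisy <- grouped_samples(list(matrix(rnorm(20), 10),
                                matrix(rnorm(20, sd = 10), 10)))
  expect_warning(riht_test(noisy), "factor of 4")
})

test_that("reject flag is consistent with the critical value", {
  set.seed(17)
  gs <- grouped_samples(list(matrix(rnorm(100), 20),
                             matrix(rnorm(100, 3), 20)))
  res <- riht_test(gs, alpha = 0.05)
  expect_identical(res$reject, abs(res$statistic) > qnorm(0.975))
  expect_equal(res$p_value, 2 * pnorm(-abs(res$statistic)))
})

test_that("change validation gates pairwise tests on the overall test", {
  set.seed(18)
  # same distribution everywhere: find that the overall test does not
  # reject, and that the gate then suppresses pairwise testing
  reports <- lapply(1:20, function(k) {
    ep <- replicate(3, matrix(rnorm(80), 20), simplify = FALSE)
    validate_changes(ep)
  })
  non_rejecting <- Filter(function(r) !r$overall$reject, reports)
  expect_gt(length(non_rejecting), 10) # ~95% expected
  for (r in non_rejecting) {
    expect_equal(nrow(r$pairwise), 0L)
    expect_length(r$change_points, 0L)
  }
})

test_that("a large shift in the last epoch is localized at its boundary", {
  set.seed(19)
  ep <- list(matrix(rnorm(100), 25), matrix(rnorm(100), 25),
             matrix(rnorm(100, mean = 3), 25))
  rep <- validate_changes(ep)
  expect_true(rep$overall$reject)
  expect_true(2 %in% rep$change_points)
  expect_false(1 %in% rep$change_points)
  expect_equal(rep$z_crit, 1.96)
})

test_that("gating can be disabled and BH correction applied", {
  set.seed(20)
  ep <- replicate(3, matrix(rnorm(60), 15), simplify = FALSE)
  rep <- validate_changes(ep, gate = FALSE, p_adjust = "BH")
  expect_equal(nrow(rep$pairwise), 2L)
  expect_true("p_adjusted" %in% names(rep$pairwise))
})
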