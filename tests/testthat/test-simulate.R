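test_that("mixed-linear constants satisfy the moment conditions analytically", {
  mt <- 0.7827
  mh <- 0.6224
  # variance of mt*z1 + mh*z2 with var(z1) = var(z2) = 1
  expect_equal(mt^2 + mh^2, 1, tolerance = 1e-4)
  # fourth moment: E z1^4 = 9/5 for uniform(-sqrt3, sqrt3); E z2^4 = 6 for
  # the unit-variance double exponential
  m4 <- mt^4 * (9 / 5) + 6 * mt^2 * mh^2 + 6 * mh^4
  expect_equal(m4, 3, tolerance = 1e-3)
})

test_that("component draws match their analytic moments empirically", {
  n <- 1e6
  x <- gen_model_component("mixed_linear", n, seed = 70)
  se_mean <- 1 / sqrt(n)
  se_var <- sqrt(2 / n) # approx, fourth moment 3
  se_kurt <- sqrt(24 / n)
  expect_lt(abs(mean(x)), 3 * se_mean)
  expect_lt(abs(var(x) - 1), 3 * se_var * 2)
  m4 <- mean((x - mean(x))^4)
  expect_lt(abs(m4 - 3), 5 * se_kurt * 3)

  g <- gen_model_component("gaussian", n, seed = 71)
  expect_lt(abs(mean(g^4) - 3), 3 * se_kurt * 3)
  expect_error(gen_model_component("weibull", 5), "Unknown model")
})

test_that("the spike covariance has one spiked eigenvalue", {
  p <- 17
  Tm <- hdeeg:::.spike_sqrt(p)
  S <- Tm %*% Tm
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(ev[1], 0.3 + 0.7 * p)
  expect_equal(ev[-1], rep(0.3, p - 1))
})

test_that("mean-group generation honours the null and the documented step defaults", {
  spec <- mean_sim_spec("I", "independent", p = 10, n1 = 100, n2 = 20)
  expect_equal(spec$s_star, 3e-3)
  spec2 <- mean_sim_spec("II", "spike", p = 10, n1 = 20, n2 = 20)
  expect_equal(spec2$s_star, 3e-2)
  expect_error(mean_sim_spec("I", "independent", p = 5, n1 = 30, n2 = 40,
                             kappa = 2), "s_star")
  gs <- gen_mean_groups(mean_sim_spec("I", "independent", p = 10,
                                      n1 = 30, n2 = 20, seed = 72))
  expect_s3_class(gs, "grouped_samples")
  expect_equal(gs$sizes, c(30L, 20L))
  expect_equal(gs$p, 10L)
})

test_that("seeded generation is bit-reproducible", {
  spec <- mean_sim_spec("II", "spike", p = 8, n1 = 15, n2 = 15,
                        kappa = 5, s_star = 0.03, seed = 73)
  a <- gen_mean_groups(spec)
  b <- gen_mean_groups(spec)
  expect_identical(a$groups, b$groups)
  s1 <- gen_scenario("I", seed = 74)
  s2 <- gen_scenario("I", seed = 74)
  expect_identical(s1$X1, s2$X1)
  expect_identical(s1$Theta0, s2$Theta0)
})

test_that("precision generation has exact sparsity and bounded spectrum", {
  spec <- precision_sim_spec(p = 30, s = 0.2, n1 = 50, n2 = 50, seed = 75)
  truth <- gen_precision(spec)
  expect_equal(sum(truth$support[upper.tri(truth$support)]),
               round(0.2 * 30 * 29 / 2))
  expect_false(any(diag(truth$support)))
  ev <- eigen(truth$Theta0, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.1 - 1e-10)
  expect_equal(truth$Theta0 %*% truth$Sigma0, diag(30), tolerance = 1e-8)
  # default weight range
  expect_equal(precision_sim_spec(p = 10, s = 0.1, n1 = 5,
                                  n2 = 5)$u_range, c(0.5, 1))
  expect_error(precision_sim_spec(p = 10, s = 1.2, n1 = 5, n2 = 5), "s")
})

test_that("scenario table matches the standard scenario designs", {
  s1 <- gen_scenario(1, seed = 76)
  expect_equal(dim(s1$X1), c(200L, 50L))
  expect_equal(dim(s1$X2), c(200L, 50L))
  expect_equal(s1$spec$s, 0.1)
  s6 <- gen_scenario("VI", seed = 77)
  expect_equal(dim(s6$X1), c(500L, 50L))
  expect_equal(s6$spec$s, 0.5)
  expect_equal(s6$spec$p, 50)
  expect_error(gen_scenario("IX"), "arg")
})

test_that("support metrics follow their counting definitions", {
  p <- 4
  truth <- matrix(0, p, p)
  truth[1, 2] <- truth[2, 1] <- 1 # one true edge, s = 2/12
  perfect <- support_metrics(truth != 0, truth)
  expect_equal(perfect$R1, 100)
  expect_equal(perfect$R0, 100)
  expect_equal(perfect$accuracy, 100)

  none <- support_metrics(matrix(FALSE, p, p), truth)
  expect_equal(none$R1, 0)
  expect_equal(none$R0, 100)
  expect_equal(none$accuracy, (1 - 2 / 12) * 100)

  est <- matrix(0, p, p)
  est[1, 2] <- est[2, 1] <- 1
  expect_equal(support_metrics(est, truth)$R1, 100)
  expect_error(support_metrics(matrix(FALSE, 3, 3), truth), "mismatch")
})

test_that("size_power_study returns a deterministic rate table", {
  a <- size_power_study("I", "independent", n1 = 20, n2 = 20, p = 10,
                        kappas = c(0, 20), reps = 50, seed = 78)
  b <- size_power_study("I", "independent", n1 = 20, n2 = 20, p = 10,
                        kappas = c(0, 20), reps = 50, seed = 78)
  expect_identical(a$rate, b$rate)
  expect_equal(a$kappa, c(0, 20))
  expect_true(all(a$rate >= 0 & a$rate <= 1))
  expect_s3_class(a, "riht_power_study")
})

test_that("larger samples improve precision estimation", {
  # Frobenius error on the larger-sample design is smaller, seed-averaged
  set.seed(79)
  err <- function(id) {
    mean(replicate(5, {
      dat <- gen_scenario(id)
      pr <- empirical_covariances(list(dat$X1, dat$X2))
      fit <- suppressWarnings(fit_fgl(pr, fgl_hyper(0.1, 0.1),
                                      epsilon = 1e-6))
      norm(fit$Theta_hat[[1]] - dat$Theta0, "F")
    }))
  }
  expect_lt(err("II"), err("I"))
})

test_that("null-distribution study has the documented default locations", {
  st <- null_distribution_study("V", reps = 2, tune = "none",
                                hyper = fgl_hyper(0.1, 0.1), seed = 80)
  expect_setequal(unique(st$location),
                  c("(1,3)", "(2,2)", "(2,4)", "(6,6)"))
  expect_equal(nrow(st), 8L)
  expect_error(null_distribution_study("I", reps = 1), "locations")
  st6 <- null_distribution_study("VI", reps = 1, tune = "none",
                                 hyper = fgl_hyper(0.1, 0.1), seed = 81)
  expect_setequal(unique(st6$location),
                  c("(1,9)", "(3,10)", "(4,10)", "(15,12)"))
})
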