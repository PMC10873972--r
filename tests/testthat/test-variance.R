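test_that("slope matrix is the Jacobian of the smoothed estimating function", {
  dat <- simulate_setup1(80, seed = 17)
  b <- fp_basis()
  G <- fit_censoring_km(dat)
  H <- diag(1 / dat$n, 12)
  set.seed(1)
  gam <- rnorm(12, sd = 0.5)
  A <- slope_matrix(gam, dat, 0.25, b, G, H)
  eps <- 1e-6
  J <- vapply(1:12, function(k) {
    e <- rep(0, 12); e[k] <- eps
    (smoothed_estimating_function(gam + e, dat, 0.25, b, G, H) -
       smoothed_estimating_function(gam - e, dat, 0.25, b, G, H)) / (2 * eps)
  }, numeric(12))
  expect_lt(max(abs(A - J)) / max(abs(J)), 1e-5)
  # symmetric positive semidefinite
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("slope matrix in one dimension matches a finite difference", {
  b <- fp_basis("1")
  n <- 25
  set.seed(33)
  Y <- rexp(n) + 0.4
  dat <- study_data(1:n, Y, rbinom(n, 1, 0.8), NULL, 0.3,
                    matrix(1, n, 1), NULL)
  G <- fit_censoring_km(dat)
  H <- matrix(0.02, 1, 1)
  gam <- 0.2
  A <- slope_matrix(gam, dat, 0.5, b, G, H)
  eps <- 1e-6
  fd <- (smoothed_estimating_function(gam + eps, dat, 0.5, b, G, H) -
           smoothed_estimating_function(gam - eps, dat, 0.5, b, G, H)) / (2 * eps)
  expect_equal(as.numeric(A), fd, tolerance = 1e-6)
})

test_that("a fully censored sample gives a zero slope matrix", {
  n <- 10
  dat <- study_data(1:n, rep(2, n) + (1:n) / 100, rep(0, n), NULL, 0.5,
                    matrix(1, n, 1), NULL)
  A <- slope_matrix(0, dat, 0.5, fp_basis("1"), H = matrix(0.1, 1, 1))
  expect_equal(as.numeric(A), 0)
})

test_that("unit multipliers reproduce the smoothed estimating function", {
  dat <- simulate_setup2(150, 0.5, seed = 21)
  fit <- induced_smoothing_estimate(dat, 0.5)
  expect_equal(perturbed_estimating_function(fit, rep(1, dat$n)),
               smoothed_estimating_function(fit$gamma, dat, 0.5, fit$basis,
                                            fit$G, fit$H),
               tolerance = 1e-12)
  expect_error(perturbed_estimating_function(fit, rep(-1, dat$n)), "positive")
})

test_that("perturbed estimating function equals loop oracle with perturbed KM", {
  dat <- simulate_setup1(30, seed = 71)
  b <- fp_basis()
  fit <- induced_smoothing_estimate(dat, 0.3, b)
  set.seed(10)
  for (r in 1:3) {
    theta <- rexp(dat$n) + 0.05
    Gstar <- fit_censoring_km(dat, multipliers = theta)
    expect_equal(
      perturbed_estimating_function(fit, theta),
      loop_smoothed_ef(fit$gamma, dat, 0.3, b, fit$G, fit$H,
                       theta = theta, Gstar = Gstar),
      tolerance = 1e-12)
  }
})

test_that("the mean perturbed estimating function is near zero at the root", {
  dat <- simulate_setup1(150, seed = 52)
  fit <- induced_smoothing_estimate(dat, 0.5)
  V <- resampling_covariance(fit, K = 1500, seed = 3)
  reps <- attr(V, "replicates")
  mu <- colMeans(reps)
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  expect_true(all(abs(mu) <= 4 * se + 1e-4))
})

test_that("resampling covariance is the sample covariance of its replicates,
           deterministic in the seed, and PSD", {
  dat <- simulate_setup1(100, seed = 6)
  fit <- induced_smoothing_estimate(dat, 0.25)
  V <- resampling_covariance(fit, K = 5, seed = 99)
  reps <- attr(V, "replicates")
  expect_equal(dim(reps), c(5L, 12L))
  Vm <- V; attr(Vm, "replicates") <- NULL
  expect_equal(unname(cov(reps)), unname(Vm), tolerance = 1e-14)
  V2 <- resampling_covariance(fit, K = 5, seed = 99)
  attr(V2, "replicates") <- NULL
  expect_identical(unname(Vm), unname(V2))
  V3 <- resampling_covariance(fit, K = 200, seed = 1)
  ev <- eigen(V3, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_error(resampling_covariance(fit, K = 1), "at least 2")
})

test_that("sandwich assembly has the expected special cases", {
  V <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(sandwich_covariance(diag(2), V), V)
  expect_equal(as.numeric(sandwich_covariance(matrix(4, 1, 1),
                                              matrix(8, 1, 1))), 8 / 16)
  expect_error(sandwich_covariance(matrix(0, 1, 1), matrix(1, 1, 1)),
               "singular")
})

test_that("delta-method standard errors follow the block quadratic form", {
  dat <- simulate_setup1(200, seed = 64)
  fit <- qrl_variance(induced_smoothing_estimate(dat, 0.5), K = 50, seed = 5)
  tbl <- summary(fit, times = 0.4)
  xi <- as.numeric(evaluate_basis(fit$basis, 0.4))
  for (bidx in 1:3) {
    idx <- fit$layout$block(bidx)
    se <- sqrt(sum(xi * (fit$covariance[idx, idx] %*% xi)))
    expect_equal(tbl$se[bidx], se, tolerance = 1e-12)
    expect_equal(tbl$upper[bidx] - tbl$estimate[bidx], qnorm(0.975) * se,
                 tolerance = 1e-10)
  }
})

test_that("sandwich variance is cheaper than the full multiplier bootstrap", {
  dat <- simulate_setup2(400, 0.5, seed = 31)
  ns <- nonsmooth_estimate(dat, 0.5)
  is <- induced_smoothing_estimate(dat, 0.5)
  t_sand <- system.time(qrl_variance(is, K = 60, seed = 1))["elapsed"]
  t_boot <- system.time(nonsmooth_bootstrap_covariance(ns, K = 60,
                                                       seed = 1))["elapsed"]
  expect_lt(t_sand, t_boot)
})
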