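test_that("nonsmooth estimating function equals its loop transcription", {
  dat <- toy3()
  b <- fp_basis()
  G <- fit_censoring_km(dat)
  set.seed(14)
  for (r in 1:4) {
    gam <- rnorm(12, sd = 0.7)
    expect_equal(nonsmooth_estimating_function(gam, dat, 0.3, b, G),
                 loop_nonsmooth_ef(gam, dat, 0.3, b, G), tolerance = 1e-12)
  }
})

test_that("censored subjects contribute only the -tau term", {
  b <- fp_basis("1")
  d1 <- study_data("a", time = 2, status = 0, W = NULL,
                   visit_schedule = 0.5, attended = matrix(1, 1, 1), Z = NULL)
  tau <- 0.35
  expect_equal(nonsmooth_estimating_function(5, d1, tau, b),
               -tau)  # U = 1, n = 1, indicator term killed by delta = 0
  # single uncensored subject, indicator = 1, no censoring: U (1 - tau)
  d2 <- study_data("a", time = 2, status = 1, W = NULL,
                   visit_schedule = 0.5, attended = matrix(1, 1, 1), Z = NULL)
  expect_equal(nonsmooth_estimating_function(50, d2, tau, b), 1 - tau)
})

test_that("smoothed estimating function equals its loop transcription and
           collapses to the nonsmooth one as H -> 0", {
  dat <- toy3()
  b <- fp_basis()
  G <- fit_censoring_km(dat)
  H <- diag(0.01, 12) + 0.001
  set.seed(15)
  for (r in 1:4) {
    gam <- rnorm(12, sd = 0.7)
    expect_equal(smoothed_estimating_function(gam, dat, 0.3, b, G, H),
                 loop_smoothed_ef(gam, dat, 0.3, b, G, H), tolerance = 1e-12)
  }
  gam <- rnorm(12)
  expect_equal(
    smoothed_estimating_function(gam, dat, 0.3, b, G, H = diag(1e-12, 12)),
    nonsmooth_estimating_function(gam, dat, 0.3, b, G), tolerance = 1e-9)
  expect_error(
    smoothed_estimating_function(gam, dat, 0.3, b, G, H = diag(0, 12)),
    "positive")
})

test_that("single-term smoothed equation has its closed-form root", {
  b <- fp_basis("1")
  d1 <- study_data("a", time = 2, status = 1, W = NULL,
                   visit_schedule = 0.25, attended = matrix(1, 1, 1), Z = NULL)
  for (tau in c(0.3, 0.5, 0.8)) {
    f <- induced_smoothing_estimate(d1, tau, b, H = matrix(0.04, 1, 1))
    expect_true(f$converged)
    expect_equal(unname(f$gamma), log(2 - 0.25) + 0.2 * qnorm(tau),
                 tolerance = 1e-7)
  }
})

test_that("intercept-only L1 fit is the weighted quantile of log residuals", {
  set.seed(5)
  b <- fp_basis("1")
  n <- 41; Y <- rexp(n) + 0.6
  dm <- study_data(1:n, Y, rep(1, n), NULL, 0.5, matrix(1, n, 1), NULL)
  r <- sort(log(Y - 0.5))
  fm <- nonsmooth_estimate(dm, 0.5, b)
  expect_equal(unname(fm$gamma), median(log(Y - 0.5)), tolerance = 1e-5)
  fq <- nonsmooth_estimate(dm, 0.25, b)
  expect_equal(unname(fq$gamma), r[ceiling(n * 0.25)], tolerance = 1e-5)
})

test_that("the L1 objective's gradient is twice the estimating function", {
  dat <- simulate_setup1(60, seed = 23)
  b <- fp_basis()
  G <- fit_censoring_km(dat)
  tau <- 0.25
  M <- 1e6
  # transcribe the objective directly
  obj <- function(gam) {
    tot <- 0; v2 <- 0; v3 <- 0
    for (i in seq_len(dat$n)) for (j in seq_len(dat$D)) {
      tj <- dat$visit_schedule[j]
      if (dat$attended[i, j] != 1 || dat$time[i] <= tj) next
      U <- build_design_row(dat, i, j, b)
      w <- if (dat$status[i] == 1)
        evaluate_G(G, tj) / evaluate_G(G, dat$time[i]) else 0
      tot <- tot + w * abs(log(dat$time[i] - tj) - sum(gam * U))
      v2 <- v2 - U * w
      v3 <- v3 + 2 * tau * U
    }
    tot / dat$n + abs(M - sum(gam * v2 / dat$n)) + abs(M - sum(gam * v3 / dat$n))
  }
  set.seed(3)
  gam <- rnorm(12, sd = 0.3)   # generic point: no residual exactly at a kink
  eps <- 1e-6
  num <- vapply(1:12, function(k) {
    e <- rep(0, 12); e[k] <- eps
    (obj(gam + e) - obj(gam - e)) / (2 * eps)
  }, 0)
  expect_equal(num, 2 * nonsmooth_estimating_function(gam, dat, tau, b, G),
               tolerance = 1e-4)
})

test_that("the LP minimizer satisfies the subgradient condition", {
  for (sd in c(29, 57)) {
    dat <- simulate_setup1(150, seed = sd)
    b <- fp_basis()
    G <- fit_censoring_km(dat)
    fit <- nonsmooth_estimate(dat, 0.25, b)
    ef <- nonsmooth_estimating_function(fit$gamma, dat, 0.25, b, G)
    # the summed jumps of the residuals at the vertex (the active kink
    # terms) bound every component of the estimating function
    jump <- rep(0, 12)
    for (i in seq_len(dat$n)) for (j in seq_len(dat$D)) {
      tj <- dat$visit_schedule[j]
      if (dat$attended[i, j] != 1 || dat$time[i] <= tj) next
      U <- build_design_row(dat, i, j, b)
      w <- if (dat$status[i] == 1)
        evaluate_G(G, tj) / evaluate_G(G, dat$time[i]) else 0
      r <- log(dat$time[i] - tj) - sum(fit$gamma * U)
      if (abs(r) <= 1e-7 * (1 + abs(log(dat$time[i] - tj))))
        jump <- jump + abs(U) * w / dat$n
    }
    expect_true(all(abs(ef) <= jump + 1e-7))
  }
})

test_that("smoothed fits verify their root independently of the solver", {
  dat <- simulate_setup2(200, 0.5, seed = 44)
  fit <- induced_smoothing_estimate(dat, 0.5)
  expect_true(fit$converged)
  ef <- smoothed_estimating_function(fit$gamma, dat, 0.5, fit$basis,
                                     fit$G, fit$H)
  expect_lt(max(abs(ef)), fit$control$tol)
})

test_that("smoothing preserves monotonicity in each coordinate", {
  set.seed(88)
  U <- abs(rnorm(6)) + 0.1
  r <- 0.4; sig <- 0.3
  gammas <- seq(-2, 2, length.out = 41)
  for (k in 1:6) {
    vals <- vapply(gammas, function(g) {
      gam <- rep(0.2, 6); gam[k] <- g
      pnorm((sum(gam * U) - r) / sig)
    }, 0)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("smoothed and nonsmooth estimates agree within sampling error", {
  set.seed(60)
  seeds <- sample.int(2^31 - 2, 5)
  times <- c(0.1, 0.2, 0.5, 0.8)
  for (sd in seeds) {
    dat <- simulate_setup2(400, 0.5, seed = sd)
    ns <- nonsmooth_estimate(dat, 0.5)
    is <- qrl_variance(induced_smoothing_estimate(dat, 0.5), K = 100,
                       seed = sd)
    a <- evaluate_coefficient_functions(ns$gamma, ns$basis, times, 1, 1)
    b <- evaluate_coefficient_functions(is$gamma, is$basis, times, 1, 1,
                                        Sigma = is$covariance)
    # the two estimators differ by far less than one standard error, cellwise
    expect_true(all(abs(a$estimate - b$estimate) < b$se),
                info = paste("max ratio =",
                             signif(max(abs(a$estimate - b$estimate) / b$se),
                                    3)))
  }
})

test_that("both estimators recover the design-II truth at large n", {
  set.seed(71)
  reps <- 20; n <- 2000
  seeds <- sample.int(2^31 - 2, reps)
  times <- c(0.1, 0.2, 0.5, 0.8)
  truth <- true_coefficients(2, 0.5, times)
  for (est in c("nonsmooth", "smoothed")) {
    vals <- matrix(NA_real_, reps, 12)
    for (r in seq_len(reps)) {
      dat <- simulate_setup2(n, 0.5, seed = seeds[r])
      f <- if (est == "nonsmooth") nonsmooth_estimate(dat, 0.5)
           else induced_smoothing_estimate(dat, 0.5)
      vals[r, ] <- evaluate_coefficient_functions(f$gamma, f$basis, times,
                                                  1, 1)$estimate
    }
    bias <- colMeans(vals) - truth$true
    mcse <- apply(vals, 2, sd) / sqrt(reps)
    # simultaneous band across the 12 cells (~3 sigma per cell keeps the
    # familywise false-alarm rate near 1%)
    expect_true(all(abs(bias) <= 3 * mcse + 0.005),
                info = paste(est, "max |bias| =", signif(max(abs(bias)), 3)))
  }
})

test_that("fit objects carry diagnostics and layout metadata", {
  dat <- simulate_setup1(120, seed = 2)
  fit <- induced_smoothing_estimate(dat, 0.5)
  expect_s3_class(fit, "qrl_fit")
  expect_length(coef(fit), 12L)
  expect_equal(fit$layout$labels, c("alpha0", "alpha1", "beta1"))
  expect_output(print(fit), "smoothed")
  expect_error(induced_smoothing_estimate(dat, 1.5), "tau")
})
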