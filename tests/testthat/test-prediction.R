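test_that("predicted residual life is the exponentiated linear predictor", {
  dat <- simulate_setup2(100, 0.5, seed = 12)
  fit <- induced_smoothing_estimate(dat, 0.5)
  # zero coefficients predict one time unit for any profile
  fit0 <- fit; fit0$gamma <- rep(0, 12)
  expect_equal(predict_residual_life(fit0, W = c(0, 1), Z = c(2, -1), t = 0.3),
               c(1, 1))
  # doubling Z doubles the Z-block contribution on the log scale
  p1 <- predict_residual_life(fit, W = 0, Z = 1, t = 0.3)
  p2 <- predict_residual_life(fit, W = 0, Z = 2, t = 0.3)
  p0 <- predict_residual_life(fit, W = 0, Z = 0, t = 0.3)
  expect_equal(log(p2) - log(p0), 2 * (log(p1) - log(p0)), tolerance = 1e-10)
})

test_that("design-II truth reproduces the closed-form residual quantile", {
  tau <- 0.5
  dat <- simulate_setup2(200, tau, seed = 9)
  lat <- attr(dat, "latent")
  fit <- induced_smoothing_estimate(dat, tau)
  # oracle coefficients: alpha0 = log(t), alpha1 = 0, beta = sqrt(t)
  fit$gamma <- c(0, 1, 0, 0, rep(0, 4), 0, 0, 1, 0)
  for (tt in c(0.1, 0.5, 0.8)) {
    Zt <- log(sqrt(-log(1 - tau) / (lat$lambda * tt^2) + 1) - 1) / sqrt(tt)
    pred <- predict_residual_life(fit, W = dat$W, Z = Zt, t = tt)
    expect_equal(pred, sqrt(-log(1 - tau) / lat$lambda + tt^2) - tt,
                 tolerance = 1e-10)
  }
})

test_that("mean absolute prediction error truncates only the truth", {
  # perfect predictions below the truncation point
  expect_equal(mae_p(true_time = c(1, 2), predictions = c(0.5, 1.5),
                     t = 0.5, L_trunc = 10), 0)
  # |min(2, 1.5) - 1| = 0.5 for a single subject
  expect_equal(mae_p(2.5, 1, t = 0.5, L_trunc = 2), 0.5)
  # three-subject hand average; the never-eligible subject is dropped
  truth <- c(1.2, 3.0, 0.1); pred <- c(0.9, 0.4, 99)
  # eligible: subjects 1 and 2; truncated truths: 0.7, min(2.5, 1.3) = 1.3
  expect_equal(mae_p(truth, pred, t = 0.5, L_trunc = 1.8),
               mean(c(abs(0.7 - 0.9), abs(1.3 - 0.4))))
  expect_error(mae_p(c(0.1, 0.2), c(1, 1), t = 0.5, L_trunc = 2),
               "at risk")
})

test_that("concordance matches a brute-force double loop with censoring", {
  set.seed(11)
  n <- 50
  Y <- rexp(n); del <- rbinom(n, 1, 0.7); pr <- runif(n)
  G <- fit_censoring_km(Y, del)
  t0 <- 0.1; L <- 2
  num <- den <- 0
  Gt <- evaluate_G(G, t0)
  for (i in 1:n) for (j in 1:n) {
    if (del[i] == 1 && Y[i] > t0 && Y[i] < Y[j] && Y[i] < L) {
      w <- (evaluate_G(G, Y[i]) / Gt)^(-2)
      den <- den + w
      if (pr[i] < pr[j]) num <- num + w
    }
  }
  expect_equal(c_index(Y, del, pr, t0, L, G), num / den, tolerance = 1e-12)
})

test_that("concordance has the right extremes, invariances and pair symmetry", {
  set.seed(19)
  n <- 40
  Y <- 0.2 + rexp(n); del <- rep(1, n)
  L <- max(Y) + 1
  # rank-concordant and anti-concordant predictors
  expect_equal(c_index(Y, del, Y, 0.1, L), 1)
  expect_equal(c_index(Y, del, -Y, 0.1, L), 0)
  # invariant to strictly increasing transforms
  pr <- runif(n)
  expect_equal(c_index(Y, del, pr, 0.1, L),
               c_index(Y, del, exp(3 * pr), 0.1, L), tolerance = 1e-12)
  # flipping the predictor flips concordant and discordant pairs
  expect_equal(c_index(Y, del, pr, 0.1, L) + c_index(Y, del, -pr, 0.1, L),
               1, tolerance = 1e-12)
  # random predictions hover near one half
  set.seed(7)
  cc <- replicate(200, c_index(Y, del, runif(n), 0.1, L))
  expect_lt(abs(mean(cc) - 0.5), 0.03)
  expect_error(c_index(Y, del, pr, max(Y) + 0.5, L), "comparable")
})

test_that("default truncation is the upper 5% point of censoring times", {
  dat <- simulate_setup2(500, 0.5, seed = 40)
  lat <- attr(dat, "latent")
  expect_equal(default_truncation(dat),
               quantile(lat$C, 0.95, names = FALSE))
  # falls back to observed censored times without latent values
  dat2 <- dat; attr(dat2, "latent") <- NULL
  expect_equal(default_truncation(dat2),
               quantile(dat$time[dat$status == 0], 0.95, names = FALSE))
})

test_that("prediction grids repeat deterministic rows per profile", {
  dat <- simulate_setup2(100, 0.5, seed = 3)
  fit <- induced_smoothing_estimate(dat, 0.5)
  prof <- data.frame(W = c(1, 1), Z = c(0.2, 0.2))
  g <- prediction_grid(fit, prof, times = c(0.2, 0.5))
  expect_equal(nrow(g), 4L)
  expect_equal(g$predicted_residual_life[g$t == 0.2][1],
               g$predicted_residual_life[g$t == 0.2][2])
  fit$gamma <- rep(0, 12)
  g0 <- prediction_grid(fit, prof, times = 0.5)
  expect_equal(g0$predicted_residual_life, c(1, 1))
})
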