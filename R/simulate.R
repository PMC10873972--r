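# Synthetic-data generators for the three validation designs, their
# closed-form true coefficient functions, and the replication drivers.
#
# Shared structure across designs: a binary time-fixed covariate W, a mixture
# censoring time C = Unif(0, 4) with probability 0.9 and the constant 4
# otherwise, a 12-visit planned schedule on (0, 1], and attendance
# eta_ij = I(Y_i >= t_j) * zeta_ij with Bernoulli zeta whose success
# probability depends on W.

default_schedule <- function()
  c(0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)

sim_censoring <- function(n, mix = 0.9, upper = 4) {
  kappa <- stats::rbinom(n, 1, mix)
  ifelse(kappa == 1, stats::runif(n, 0, upper), upper)
}

sim_attendance <- function(Y, W, schedule, p_visit) {
  n <- length(Y); D <- length(schedule)
  pv <- ifelse(W == 1, p_visit[2], p_visit[1])
  zeta <- matrix(stats::rbinom(n * D, 1, rep(pv, D)), n, D)
  alive <- outer(Y, schedule, `>=`)
  zeta * alive
}

finish_sim <- function(id, Tt, C, W, schedule, attended, Zfull, lambda = NULL) {
  Y <- pmin(Tt, C)
  delta <- as.integer(Tt <= C)
  Z <- Zfull
  Z[attended == 0] <- NA_real_
  d <- study_data(id, Y, delta, matrix(W, ncol = 1), schedule, attended,
                  Z)
  attr(d, "latent") <- list(T = Tt, C = C, Z_full = Zfull, lambda = lambda)
  d
}

#' Simulated design I: constant coefficients, noise time-varying covariate
#'
#' `W ~ Bernoulli(0.5)`; failure times are exponential with rate 1.5 when
#' `W = 0` and rate 1 when `W = 1`, so the log quantile residual life is
#' `log(-log(1 - tau)/1.5) + log(1.5) W` at every base time (memorylessness).
#' The time-varying covariate is independent `Unif(-1, 1)` noise with true
#' coefficient zero. Censoring is `Unif(0, 4)` with probability 0.9 and the
#' constant 4 otherwise (about 19% censoring); attendance probabilities are
#' (0.75, 0.9) for `W = (0, 1)`.
#'
#' @param n sample size.
#' @param seed optional integer seed.
#' @param p_visit attendance probabilities `(p_V0, p_V1)`.
#' @param cens_mix,cens_upper censoring mixture weight and support upper end.
#' @return a [study_data()] with the latent failure/censoring times attached.
#' @export
simulate_setup1 <- function(n, seed = NULL, p_visit = c(0.75, 0.9),
                            cens_mix = 0.9, cens_upper = 4) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  schedule <- default_schedule()
  W <- stats::rbinom(n, 1, 0.5)
  rate <- ifelse(W == 1, 1, 1.5)
  Tt <- stats::rexp(n, rate)
  C <- sim_censoring(n, cens_mix, cens_upper)
  Y <- pmin(Tt, C)
  attended <- sim_attendance(Y, W, schedule, p_visit)
  Zfull <- matrix(stats::runif(n * length(schedule), -1, 1), n)
  finish_sim(seq_len(n), Tt, C, W, schedule, attended, Zfull)
}

# deterministic time-varying covariate of designs II/III at one visit time
z_setup2 <- function(lambda, t, tau)
  log(sqrt(-log(1 - tau) / (lambda * t^2) + 1) - 1) / sqrt(t)

z_setup3 <- function(lambda, t, tau)
  log(sqrt(-log(1 - tau) / (lambda * t^2) + 1) - 1) /
    (0.1 * (t + 1)^2 + 0.1 / t)

sim_setup23 <- function(n, tau, seed, p_visit, setup, cens_mix, cens_upper) {
  stopifnot(n >= 2)
  check_tau(tau)
  if (!is.null(seed)) set.seed(seed)
  schedule <- default_schedule()
  W <- stats::rbinom(n, 1, 0.5)
  lambda <- stats::runif(n, 0.5, 1.5)
  Tt <- sqrt(-log(stats::runif(n)) / lambda)   # S(t) = exp(-lambda t^2)
  C <- sim_censoring(n, cens_mix, cens_upper)
  Y <- pmin(Tt, C)
  attended <- sim_attendance(Y, W, schedule, p_visit)
  zfun <- if (setup == 2L) z_setup2 else z_setup3
  Zfull <- outer(lambda, schedule, zfun, tau = tau)
  finish_sim(seq_len(n), Tt, C, W, schedule, attended, Zfull, lambda = lambda)
}

#' Simulated design II: time-varying coefficients, informative biomarker
#'
#' Failure times have survival `exp(-lambda t^2)` with subject-specific
#' `lambda ~ Unif(0.5, 1.5)`; the quantile residual life at `t` is then
#' `sqrt(-log(1 - tau)/lambda + t^2) - t` in closed form. The biomarker is the
#' deterministic transform of `lambda` that makes the model hold exactly with
#' `alpha_0(t) = log(t)`, `alpha_1(t) = 0` and `beta(t) = sqrt(t)`. Censoring
#' as in design I (about 21% censoring); attendance probabilities (0.5, 0.7).
#'
#' @inheritParams simulate_setup1
#' @param tau the quantile level the biomarker is constructed for.
#' @return a [study_data()] with latent values attached.
#' @export
simulate_setup2 <- function(n, tau, seed = NULL, p_visit = c(0.5, 0.7),
                            cens_mix = 0.9, cens_upper = 4)
  sim_setup23(n, tau, seed, p_visit, 2L, cens_mix, cens_upper)

#' Simulated design III: misspecified coefficient structure
#'
#' Identical to design II (same `W`, failure, censoring and attendance streams
#' for the same seed) except the biomarker transform, which makes the true
#' time-varying coefficient `beta(t) = 0.1 (t + 1)^2 + 0.1 / t` - a function
#' outside the span of the default fractional-polynomial basis, so fits with
#' that basis are structurally misspecified by design.
#'
#' @inheritParams simulate_setup2
#' @return a [study_data()] with latent values attached.
#' @export
simulate_setup3 <- function(n, tau, seed = NULL, p_visit = c(0.5, 0.7),
                            cens_mix = 0.9, cens_upper = 4)
  sim_setup23(n, tau, seed, p_visit, 3L, cens_mix, cens_upper)

#' True coefficient functions of the simulated designs
#'
#' @param setup 1, 2 or 3.
#' @param tau quantile level.
#' @param t base time(s), positive.
#' @return data.frame with columns `coefficient`, `t`, `true`.
#' @export
true_coefficients <- function(setup, tau, t) {
  check_tau(tau)
  if (any(t <= 0)) stop("base times must be positive")
  vals <- switch(as.character(setup),
    "1" = list(alpha0 = rep(log(-log(1 - tau) / 1.5), length(t)),
               alpha1 = rep(log(1.5), length(t)),
               beta1 = rep(0, length(t))),
    "2" = list(alpha0 = log(t), alpha1 = rep(0, length(t)), beta1 = sqrt(t)),
    "3" = list(alpha0 = log(t), alpha1 = rep(0, length(t)),
               beta1 = 0.1 * (t + 1)^2 + 0.1 / t),
    stop("setup must be 1, 2 or 3"))
  data.frame(coefficient = rep(names(vals), each = length(t)),
             t = rep(t, 3), true = unlist(vals, use.names = FALSE))
}

sim_generate <- function(setup, n, tau, seed, ...) {
  switch(as.character(setup),
         "1" = simulate_setup1(n, seed = seed, ...),
         "2" = simulate_setup2(n, tau, seed = seed, ...),
         "3" = simulate_setup3(n, tau, seed = seed, ...),
         stop("setup must be 1, 2 or 3"))
}

#' Replication study of bias and standard errors
#'
#' Repeatedly simulates a design, fits the chosen estimator at each `tau`, and
#' summarizes, per (tau, base time, coefficient): the truth, the empirical
#' bias (EB) of the pointwise coefficient estimates, their empirical standard
#' error (ESE), and the average of the delta-method standard errors (ASE) from
#' the resampling sandwich covariance.
#'
#' @param setup design 1, 2 or 3.
#' @param n per-replication sample size.
#' @param taus quantile levels.
#' @param reps number of replications (>= 2).
#' @param eval_times base times at which coefficient functions are read off.
#' @param K resampling replicates for each variance estimate; `K = 0` skips
#'   variance estimation (no ASE column).
#' @param seed integer seed controlling the whole study.
#' @param estimator `"smoothed"` or `"nonsmooth"`.
#' @param basis basis for fitting.
#' @param max_fail abort if the proportion of non-converged fits exceeds this.
#' @param csv_path optional path for the summary CSV.
#' @param ... passed to the generator (attendance/censoring overrides).
#' @return data.frame with columns `tau, t, coefficient, true, EB, ESE, ASE`
#'   plus attribute `"estimates"` holding the per-replication values.
#' @export
run_simulation_study <- function(setup, n = 400, taus = c(0.25, 0.5),
                                 reps = 200,
                                 eval_times = c(0.1, 0.2, 0.5, 0.8),
                                 K = 200, seed = 1,
                                 estimator = c("smoothed", "nonsmooth"),
                                 basis = fp_basis(), max_fail = 0.05,
                                 csv_path = NULL, ...) {
  estimator <- match.arg(estimator)
  stopifnot(reps >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  out <- list()
  est_store <- list()
  for (tau in taus) {
    est <- array(NA_real_, c(reps, length(eval_times), 3L))
    ase <- array(NA_real_, c(reps, length(eval_times), 3L))
    failed <- 0L
    for (r in seq_len(reps)) {
      dat <- sim_generate(setup, n, tau, seed = rep_seeds[r], ...)
      fit <- tryCatch({
        f <- if (estimator == "smoothed")
          induced_smoothing_estimate(dat, tau, basis)
        else nonsmooth_estimate(dat, tau, basis)
        if (K > 0 && estimator == "smoothed")
          f <- qrl_variance(f, K = K, seed = rep_seeds[r] %% 100000L + r)
        f
      }, error = function(e) NULL)
      ok <- !is.null(fit) &&
        (fit$estimator == "nonsmooth" || fit$converged)
      if (!ok) {
        failed <- failed + 1L
        if (failed / reps > max_fail)
          stop("non-convergence rate exceeded ", max_fail,
               " (", failed, " failures in ", r, " replications)")
        next
      }
      tbl <- evaluate_coefficient_functions(fit$gamma, basis, eval_times,
                                            dat$p, dat$q,
                                            Sigma = fit$covariance)
      est[r, , ] <- matrix(tbl$estimate, length(eval_times))
      if (!is.null(fit$covariance))
        ase[r, , ] <- matrix(tbl$se, length(eval_times))
    }
    truth <- true_coefficients(setup, tau, eval_times)
    labels <- unique(truth$coefficient)
    for (b in seq_along(labels)) {
      for (ti in seq_along(eval_times)) {
        e <- est[, ti, b]
        tv <- truth$true[truth$coefficient == labels[b] &
                           truth$t == eval_times[ti]]
        out[[length(out) + 1L]] <- data.frame(
          tau = tau, t = eval_times[ti], coefficient = labels[b], true = tv,
          EB = mean(e, na.rm = TRUE) - tv,
          ESE = stats::sd(e, na.rm = TRUE),
          ASE = if (K > 0 && estimator == "smoothed")
            mean(ase[, ti, b], na.rm = TRUE) else NA_real_,
          n_reps = sum(!is.na(e)))
      }
    }
    est_store[[paste0("tau_", tau)]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "estimates") <- est_store
  if (!is.null(csv_path))
    utils::write.csv(res, csv_path, row.names = FALSE, quote = FALSE)
  res
}

#' Dynamic-prediction accuracy study
#'
#' Per replication: fit the model on an independent training set from design
#' II, predict quantile residual lifetimes for a large test set at each base
#' time, and record the calibration error ([mae_p()]) and the truncated IPCW
#' concordance ([c_index()]) computed with the test set's own censoring
#' estimate. The truncation time is the upper 5% point of the test set's
#' censoring times.
#'
#' @param n_train,n_test training and test sample sizes.
#' @param taus quantile levels.
#' @param reps replications.
#' @param pred_times base times for prediction.
#' @param seed integer seed.
#' @param estimator `"smoothed"` or `"nonsmooth"`.
#' @param basis fitting basis.
#' @param csv_path optional per-replication CSV output.
#' @return data.frame with one row per (tau, t, rep): `MAE_p`, `C_index`.
#' @export
run_prediction_study <- function(n_train = 400, n_test = 2000,
                                 taus = c(0.25, 0.5), reps = 100,
                                 pred_times = c(0.1, 0.2, 0.5, 0.8),
                                 seed = 1,
                                 estimator = c("smoothed", "nonsmooth"),
                                 basis = fp_basis(), csv_path = NULL) {
  estimator <- match.arg(estimator)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * reps), reps)
  rows <- list()
  for (tau in taus) {
    for (r in seq_len(reps)) {
      train <- simulate_setup2(n_train, tau, seed = rep_seeds[r, 1])
      test <- simulate_setup2(n_test, tau, seed = rep_seeds[r, 2])
      fit <- if (estimator == "smoothed")
        induced_smoothing_estimate(train, tau, basis)
      else nonsmooth_estimate(train, tau, basis)
      lat <- attr(test, "latent")
      L <- default_truncation(test)
      Gtest <- fit_censoring_km(test)
      for (tt in pred_times) {
        Zt <- z_setup2(lat$lambda, tt, tau)
        pred <- predict_residual_life(fit, W = test$W, Z = Zt, t = tt)
        rows[[length(rows) + 1L]] <- data.frame(
          tau = tau, t = tt, rep = r,
          MAE_p = mae_p(lat$T, pred, tt, L),
          C_index = c_index(test$time, test$status, pred, tt, L, G = Gtest))
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(csv_path))
    utils::write.csv(res, csv_path, row.names = FALSE, quote = FALSE)
  res
}
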