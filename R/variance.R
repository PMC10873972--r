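# Sandwich covariance for the induced-smoothing estimator: analytic slope
# matrix, multiplier-perturbed estimating functions (with the censoring
# Kaplan-Meier refit under the same multipliers), and their assembly.

#' Slope matrix of the smoothed estimating function
#'
#' Analytic Jacobian of [smoothed_estimating_function()] with respect to
#' `gamma`: each term contributes its IPCW weight times the standard-normal
#' density of the scaled residual, divided by the smoothing scale
#' `sqrt(U' H U)`, times the rank-one matrix `U U'`. The density kernel makes
#' this a nonnegative mixture of rank-one terms, hence symmetric positive
#' semidefinite.
#'
#' @inheritParams smoothed_estimating_function
#' @return `d x d` matrix.
#' @export
slope_matrix <- function(gamma, data, tau, basis, G = NULL, H = NULL) {
  check_tau(tau)
  if (is.null(G)) G <- fit_censoring_km(data)
  tm <- qrl_terms(data, basis, G)
  if (is.null(H)) H <- default_H(tm)
  slope_terms(gamma, tm, tau, term_sigma(tm, H))
}

# Precomputed structures for fast theta-weighted censoring KM refits.
km_precompute <- function(time, status) {
  jumps <- sort(unique(time[status == 0]))
  ord <- order(time)
  n_lt <- if (length(jumps)) findInterval(jumps, time[ord], left.open = TRUE)
          else integer(0)
  cens_grp <- rep(NA_integer_, length(time))
  cens_grp[status == 0] <- match(time[status == 0], jumps)
  fail_grp <- rep(NA_integer_, length(time))
  hit <- status == 1 & time %in% jumps
  fail_grp[hit] <- match(time[hit], jumps)
  list(jumps = jumps, ord = ord, n_lt = n_lt,
       cens_idx = which(status == 0), cens_grp = cens_grp[status == 0],
       fail_idx = which(hit), fail_grp = fail_grp[hit])
}

km_eval_weighted <- function(pre, theta) {
  nj <- length(pre$jumps)
  if (nj == 0L) return(numeric(0))
  cums <- c(0, cumsum(theta[pre$ord]))
  atrisk <- cums[length(cums)] - cums[pre$n_lt + 1L]
  if (length(pre$fail_idx)) {
    agg <- rowsum(theta[pre$fail_idx], pre$fail_grp)
    gi <- as.integer(rownames(agg))
    atrisk[gi] <- atrisk[gi] - agg[, 1]
  }
  dcens <- numeric(nj)
  agg <- rowsum(theta[pre$cens_idx], pre$cens_grp)
  gi <- as.integer(rownames(agg))
  dcens[gi] <- agg[, 1]
  frac <- ifelse(atrisk > 0, dcens / atrisk, 0)
  pmax(cumprod(1 - frac), 0)
}

#' Multiplier-perturbed smoothed estimating function
#'
#' Re-evaluates the smoothed estimating function at a fitted `gamma` with
#' i.i.d. positive subject multipliers: each subject's entire contribution is
#' scaled by its multiplier, and the censoring survival estimate is refit with
#' the same multipliers before forming the IPCW ratios.
#'
#' @param fit a `qrl_fit` from [induced_smoothing_estimate()].
#' @param multipliers strictly positive vector, one entry per subject
#'   (exponential with unit mean in the resampling procedure).
#' @return numeric vector of length `d`.
#' @export
perturbed_estimating_function <- function(fit, multipliers) {
  stopifnot(inherits(fit, "qrl_fit"))
  if (is.null(fit$H)) stop("perturbation applies to the smoothed fit")
  if (length(multipliers) != fit$n || any(multipliers <= 0))
    stop("multipliers must be strictly positive, one per subject")
  tm <- qrl_terms(fit$data, fit$basis, fit$G)
  pre <- km_precompute(fit$data$time, fit$data$status)
  sigma <- term_sigma(tm, fit$H)
  ph <- stats::pnorm((as.numeric(tm$U %*% fit$gamma) - tm$logres) / sigma)
  perturbed_ef_fast(tm, pre, ph, fit$tau, multipliers)
}

perturbed_ef_fast <- function(tm, pre, ph, tau, theta) {
  surv <- km_eval_weighted(pre, theta)
  Gt <- c(1, surv)[tm$idx_t + 1L]
  GY <- c(1, surv)[tm$idx_Y + 1L]
  ratio <- ifelse(tm$delta == 1 & GY > 0, Gt / GY, 0)
  as.numeric(crossprod(tm$U, theta[tm$i] * (ph * ratio - tau))) / tm$n
}

#' Resampling covariance of the estimating function
#'
#' Sample covariance of `K` multiplier-perturbed estimating functions
#' evaluated at the fitted `gamma`, with unit-mean exponential multipliers
#' redrawn each replicate and the censoring estimate refit per replicate.
#'
#' @param fit a smoothed `qrl_fit`.
#' @param K number of resampling replicates (>= 2).
#' @param seed optional integer seed; identical seeds reproduce the result
#'   exactly.
#' @return `d x d` covariance matrix with the `K x d` replicate matrix
#'   attached as attribute `"replicates"`.
#' @export
resampling_covariance <- function(fit, K = 200, seed = NULL) {
  stopifnot(inherits(fit, "qrl_fit"))
  if (K < 2) stop("K must be at least 2")
  if (is.null(fit$H)) stop("resampling variance applies to the smoothed fit")
  if (!is.null(seed)) set.seed(seed)
  tm <- qrl_terms(fit$data, fit$basis, fit$G)
  pre <- km_precompute(fit$data$time, fit$data$status)
  sigma <- term_sigma(tm, fit$H)
  ph <- stats::pnorm((as.numeric(tm$U %*% fit$gamma) - tm$logres) / sigma)
  reps <- matrix(NA_real_, K, tm$d)
  for (k in seq_len(K)) {
    theta <- stats::rexp(fit$n)
    reps[k, ] <- perturbed_ef_fast(tm, pre, ph, fit$tau, theta)
  }
  V <- stats::cov(reps)
  attr(V, "replicates") <- reps
  V
}

#' Assemble the sandwich covariance
#'
#' `Sigma = (A^{-1})' V (A^{-1})` with `A` the slope matrix at the fitted
#' `gamma` and `V` the resampling covariance of the estimating function.
#'
#' @param A slope matrix (invertible).
#' @param V resampling covariance matrix.
#' @return symmetric `d x d` covariance matrix.
#' @export
sandwich_covariance <- function(A, V) {
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular slope matrix: reduce the basis or increase n"))
  S <- t(Ainv) %*% V %*% Ainv
  (S + t(S)) / 2
}

#' Attach a resampling sandwich covariance to a fit
#'
#' Convenience wrapper running [slope_matrix()], [resampling_covariance()] and
#' [sandwich_covariance()] and storing the result on the fit.
#'
#' @param fit a smoothed `qrl_fit`.
#' @param K resampling replicates.
#' @param seed optional seed for the multiplier draws.
#' @return the fit with elements `covariance` (the `d x d` matrix) and
#'   `sandwich` (components `A`, `V`, `K`, `seed`).
#' @export
qrl_variance <- function(fit, K = 200, seed = NULL) {
  stopifnot(inherits(fit, "qrl_fit"))
  A <- slope_matrix(fit$gamma, fit$data, fit$tau, fit$basis, fit$G, fit$H)
  V <- resampling_covariance(fit, K = K, seed = seed)
  attr(V, "replicates") <- NULL
  Sigma <- sandwich_covariance(A, V)
  fit$covariance <- Sigma
  fit$sandwich <- list(A = A, V = V, K = K, seed = seed)
  fit
}

#' Full multiplier-bootstrap variance of the nonsmooth estimator
#'
#' Reference implementation of the resampling scheme that refits the perturbed
#' L1 objective per replicate (each subject's weights and the censoring
#' estimate perturbed by the same exponential multipliers) and reports the
#' sample covariance of the refitted coefficients. Much slower than the
#' sandwich route; kept for runtime and agreement comparisons.
#'
#' @param fit a nonsmooth `qrl_fit` from [nonsmooth_estimate()].
#' @param K bootstrap replicates.
#' @param seed optional seed.
#' @return `d x d` covariance matrix with replicate coefficients attached as
#'   attribute `"replicates"`.
#' @export
nonsmooth_bootstrap_covariance <- function(fit, K = 200, seed = NULL) {
  stopifnot(inherits(fit, "qrl_fit"))
  if (K < 2) stop("K must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  tm <- qrl_terms(fit$data, fit$basis, fit$G)
  pre <- km_precompute(fit$data$time, fit$data$status)
  reps <- matrix(NA_real_, K, tm$d)
  for (k in seq_len(K)) {
    theta <- stats::rexp(fit$n)
    surv <- km_eval_weighted(pre, theta)
    Gt <- c(1, surv)[tm$idx_t + 1L]
    GY <- c(1, surv)[tm$idx_Y + 1L]
    tm_k <- tm
    tm_k$ratio <- ifelse(tm$delta == 1 & GY > 0, Gt / GY, 0)
    reps[k, ] <- ns_solve_terms(tm_k, fit$tau, fit$control,
                                theta = theta)$coefficients
  }
  V <- stats::cov(reps)
  attr(V, "replicates") <- reps
  V
}

#' Coefficient-function table from a fitted model
#'
#' Pointwise estimates of every time-varying coefficient with delta-method
#' standard errors and Wald confidence limits when a sandwich covariance has
#' been attached (see [qrl_variance()]).
#'
#' @param object a `qrl_fit`.
#' @param times evaluation times (default: the visit-schedule subset
#'   `0.1, 0.2, 0.5, 0.8` clipped to the schedule range).
#' @param level confidence level.
#' @param ... unused.
#' @return data.frame with columns `tau`, `coefficient`, `t`, `estimate` and,
#'   when a covariance is available, `se`, `lower`, `upper`.
#' @export
summary.qrl_fit <- function(object, times = NULL, level = 0.95, ...) {
  if (is.null(times)) {
    cand <- c(0.1, 0.2, 0.5, 0.8)
    rng <- range(object$data$visit_schedule)
    times <- cand[cand >= rng[1] & cand <= rng[2]]
    if (length(times) == 0) times <- object$data$visit_schedule
  }
  tbl <- evaluate_coefficient_functions(object$gamma, object$basis, times,
                                        object$p, object$q,
                                        Sigma = object$covariance,
                                        level = level)
  cbind(tau = object$tau, tbl)
}

#' Write a coefficient table to CSV and/or JSON
#'
#' @param table a data.frame as returned by [summary.qrl_fit()].
#' @param csv_path,json_path optional output paths.
#' @return the table, invisibly.
#' @export
write_coefficient_table <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(table, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(table, json_path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(table)
}
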