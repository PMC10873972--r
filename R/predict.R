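#' Predict quantile residual lifetimes
#'
#' The predicted residual life at base time `t` is the exponentiated linear
#' predictor `exp(gamma' U(t))`, with `U(t)` the design row built from the
#' supplied covariate profile at `t`.
#'
#' @param fit a `qrl_fit`.
#' @param W matrix (or vector) of time-fixed covariates, one row per profile;
#'   `NULL` when the model has none.
#' @param Z matrix (or vector) of time-varying covariate values at time `t`,
#'   one row per profile.
#' @param t base time (scalar) within the basis domain.
#' @return positive predicted residual lifetimes, one per profile.
#' @export
predict_residual_life <- function(fit, W = NULL, Z = NULL, t) {
  stopifnot(inherits(fit, "qrl_fit"))
  if (length(t) != 1L) stop("t must be a single base time")
  if (fit$p > 0) {
    W <- if (is.null(dim(W))) matrix(W, ncol = fit$p) else as.matrix(W)
    if (ncol(W) != fit$p) stop("W must have ", fit$p, " column(s)")
  }
  if (fit$q > 0) {
    Z <- if (is.null(dim(Z))) matrix(Z, ncol = fit$q) else as.matrix(Z)
    if (ncol(Z) != fit$q) stop("Z must have ", fit$q, " column(s)")
  }
  nr <- max(if (fit$p > 0) nrow(W) else 1L, if (fit$q > 0) nrow(Z) else 1L)
  V <- cbind(rep(1, nr),
             if (fit$p > 0) W,
             if (fit$q > 0) Z)
  if (any(!is.finite(V))) stop("non-finite covariates")
  xi <- evaluate_basis(fit$basis, t)[1, ]
  U <- V[, rep(seq_len(ncol(V)), each = fit$basis$n_basis), drop = FALSE] *
    matrix(xi, nr, fit$d, byrow = TRUE)
  as.numeric(exp(U %*% fit$gamma))
}

#' Mean absolute prediction error for residual lifetimes
#'
#' Calibration measure: the average, over subjects still at risk at `t`
#' (`T_i > t`), of the absolute difference between the truncated true residual
#' life `min(T_i - t, L - t)` and the predicted quantile residual life. Only
#' the true residual is truncated.
#'
#' @param true_time true failure times `T_i` (available in simulations).
#' @param predictions predicted residual lifetimes, one per subject (entries
#'   for ineligible subjects are ignored).
#' @param t base time.
#' @param L_trunc truncation time `L > t`.
#' @return nonnegative scalar.
#' @export
mae_p <- function(true_time, predictions, t, L_trunc) {
  stopifnot(length(true_time) == length(predictions), L_trunc > t)
  eligible <- true_time > t
  if (!any(eligible)) stop("no subjects at risk at t")
  truth <- pmin(true_time[eligible] - t, L_trunc - t)
  mean(abs(truth - predictions[eligible]))
}

#' Truncated IPCW concordance index for predicted residual lifetimes
#'
#' Discrimination measure: the weighted proportion of comparable pairs whose
#' predicted residual lifetimes are ordered like their observed ones. A pair
#' `(i, j)` is comparable when `i` is uncensored, `0 < Y_i - t < Y_j - t` and
#' `Y_i < L`; the pair carries the inverse-censoring weight
#' `delta_i (G(Y_i)/G(t))^{-2}`. Ties in predictions count as discordant
#' (strict inequality).
#'
#' @param time observed times of the evaluation set.
#' @param status event indicators of the evaluation set.
#' @param predictions predicted residual lifetimes at `t`, one per subject.
#' @param t base (prediction) time.
#' @param L_trunc truncation time; defaults via [default_truncation()] should
#'   be computed by the caller from the evaluation set.
#' @param G censoring survival estimate for the evaluation set; defaults to
#'   the Kaplan-Meier estimate from (`time`, `status`).
#' @return concordance in `[0, 1]`.
#' @export
c_index <- function(time, status, predictions, t, L_trunc, G = NULL) {
  stopifnot(length(time) == length(status),
            length(predictions) == length(time))
  if (is.null(G)) G <- fit_censoring_km(time, status)
  Gt <- evaluate_G(G, t)
  wi <- numeric(length(time))
  anchor <- status == 1 & time > t & time < L_trunc
  if (any(anchor)) {
    GY <- evaluate_G(G, time[anchor])
    if (any(GY <= 0))
      stop("degenerate IPCW weight in concordance computation")
    wi[anchor] <- (GY / Gt)^(-2)
  }
  # single sweep in decreasing Y with a Fenwick tree over prediction ranks:
  # when subject i is visited, exactly the j with Y_j > Y_i have been inserted,
  # so concordant counts are dominance queries rather than an O(n^2) scan
  n <- length(time)
  u <- sort(unique(predictions))
  pr <- findInterval(predictions, u)
  nb <- length(u)
  tree <- numeric(nb)
  bit_add <- function(ix) {
    while (ix <= nb) { tree[ix] <<- tree[ix] + 1; ix <- ix + bitwAnd(ix, -ix) }
  }
  bit_le <- function(ix) {
    s <- 0
    while (ix > 0) { s <- s + tree[ix]; ix <- ix - bitwAnd(ix, -ix) }
    s
  }
  o <- order(time, decreasing = TRUE)
  num <- 0; den <- 0
  inserted <- 0
  k <- 1
  while (k <= n) {
    k2 <- k
    while (k2 < n && time[o[k2 + 1]] == time[o[k]]) k2 <- k2 + 1
    for (idx in o[k:k2]) {
      if (anchor[idx]) {
        den <- den + wi[idx] * inserted
        num <- num + wi[idx] * (inserted - bit_le(pr[idx]))
      }
    }
    for (idx in o[k:k2]) bit_add(pr[idx])
    inserted <- inserted + (k2 - k + 1)
    k <- k2 + 1
  }
  if (den == 0)
    stop("no comparable pairs: concordance undefined at this t and L")
  num / den
}

#' Default truncation time for prediction accuracy measures
#'
#' The upper 5% point (95th percentile) of the evaluation set's censoring
#' times: the latest time at which censoring still leaves support, slightly
#' below the maximum censoring time. Uses the true censoring times when the
#' dataset carries them (simulated data), otherwise the observed censored
#' follow-up times.
#'
#' @param data a [study_data()] object.
#' @param prob upper quantile probability (default 0.95).
#' @return a single time.
#' @export
default_truncation <- function(data, prob = 0.95) {
  stopifnot(inherits(data, "study_data"))
  ct <- attr(data, "latent")$C
  if (is.null(ct)) ct <- data$time[data$status == 0]
  if (length(ct) == 0) stop("no censoring times available for truncation")
  as.numeric(stats::quantile(ct, prob, names = FALSE))
}

#' Prediction grid over covariate profiles
#'
#' Evaluates predicted quantile residual lifetimes over a grid of base times
#' and covariate profiles, in long format suitable for tabulation or heat-map
#' style displays.
#'
#' @param fit a `qrl_fit`.
#' @param profiles data.frame whose columns are the model covariates (time-
#'   fixed first, then time-varying values assumed current at each `t`).
#' @param times base times.
#' @return data.frame with one row per (time, profile).
#' @export
prediction_grid <- function(fit, profiles, times) {
  stopifnot(is.data.frame(profiles), ncol(profiles) == fit$p + fit$q)
  out <- do.call(rbind, lapply(times, function(tt) {
    W <- if (fit$p > 0) as.matrix(profiles[, seq_len(fit$p), drop = FALSE])
    Z <- if (fit$q > 0)
      as.matrix(profiles[, fit$p + seq_len(fit$q), drop = FALSE])
    data.frame(t = tt, profile = seq_len(nrow(profiles)), tau = fit$tau,
               predicted_residual_life =
                 predict_residual_life(fit, W, Z, tt))
  }))
  rownames(out) <- NULL
  out
}
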