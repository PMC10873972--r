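#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimator of `G(t) = P(C > t)` obtained by treating censoring
#' as the event of interest and observed failures as censored. Optional
#' positive subject multipliers weight both the event counts and the risk-set
#' sizes, giving the perturbed estimate used by the multiplier-resampling
#' variance procedure.
#'
#' Tie convention: when a failure and a censoring share a time, the failure is
#' taken to occur first, so subjects failing at `t` are excluded from the risk
#' set of the censoring jump at `t`.
#'
#' @param data a [study_data()] object, or a numeric vector of observed times.
#' @param status event indicators (1 = failure, 0 = censored); ignored when
#'   `data` is a `study_data`.
#' @param multipliers optional strictly positive per-subject weights.
#' @return object of class `censoring_km` with `time` (jump times: distinct
#'   censoring times) and `surv` (value of `G` at and after each jump).
#' @export
fit_censoring_km <- function(data, status = NULL, multipliers = NULL) {
  if (inherits(data, "study_data")) {
    time <- data$time; status <- data$status
  } else {
    time <- as.numeric(data)
    if (is.null(status) || length(status) != length(time))
      stop("status must accompany a raw time vector")
  }
  n <- length(time)
  if (n < 1L) stop("empty data")
  if (is.null(multipliers)) multipliers <- rep(1, n)
  if (length(multipliers) != n || any(!is.finite(multipliers)) ||
      any(multipliers <= 0))
    stop("multipliers must be strictly positive, one per subject")
  ct <- sort(unique(time[status == 0]))
  if (length(ct) == 0L) {
    return(structure(list(time = numeric(0), surv = numeric(0), n = n),
                     class = "censoring_km"))
  }
  # theta-weighted censoring counts and risk sets at each censoring time;
  # failures at exactly u leave the risk set before the censoring jump at u
  dcens <- vapply(ct, function(u) sum(multipliers[time == u & status == 0]),
                  0)
  atrisk <- vapply(ct, function(u)
    sum(multipliers[time >= u]) - sum(multipliers[time == u & status == 1]),
    0)
  frac <- ifelse(atrisk > 0, dcens / atrisk, 0)
  surv <- pmax(cumprod(1 - frac), 0)   # guard against -0 at an exhausted risk set
  structure(list(time = ct, surv = surv, n = n), class = "censoring_km")
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("<censoring_km> %d jump(s), final level %.4f\n",
              length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Evaluate a censoring survival estimate
#'
#' Right-continuous step evaluation with `G(0) = 1`.
#'
#' @param G a `censoring_km` object.
#' @param t nonnegative evaluation times.
#' @return numeric vector of survival probabilities.
#' @export
evaluate_G <- function(G, t) {
  stopifnot(inherits(G, "censoring_km"))
  if (any(t < 0)) stop("negative evaluation time")
  if (length(G$time) == 0L) return(rep(1, length(t)))
  c(1, G$surv)[findInterval(t, G$time) + 1L]
}

#' Inverse-probability-of-censoring weights
#'
#' The weight attached to subject `i`'s term at planned visit time `t_j`:
#' `eta_ij * delta_i * I(Y_i > t_j) * G(t_j) / G(Y_i)`. Zero whenever the
#' subject is censored, missed the visit, or had already left follow-up.
#'
#' @param G a fitted `censoring_km`.
#' @param time observed times `Y_i`.
#' @param status event indicators `delta_i`.
#' @param attended attendance indicators `eta_ij` (same length).
#' @param visit_time visit times `t_j` (scalar or same length).
#' @return nonnegative weights.
#' @export
ipcw_weight <- function(G, time, status, attended, visit_time) {
  k <- max(length(time), length(visit_time))
  time <- rep_len(time, k); status <- rep_len(status, k)
  attended <- rep_len(attended, k); visit_time <- rep_len(visit_time, k)
  active <- attended == 1 & status == 1 & time > visit_time
  w <- numeric(k)
  if (any(active)) {
    GY <- evaluate_G(G, time[active])
    if (any(GY <= 0))
      stop("degenerate IPCW weight: censoring survival estimate is 0 at an ",
           "observed failure time")
    w[active] <- evaluate_G(G, visit_time[active]) / GY
  }
  w
}
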