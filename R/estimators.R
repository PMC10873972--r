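#' Control parameters for the residual-life estimators
#'
#' @param M large positive constant for the two pseudo-observations of the L1
#'   objective (default `1e6`).
#' @param max_iter Newton iteration cap for the induced-smoothing root finder.
#' @param tol convergence tolerance on the sup-norm of the smoothed estimating
#'   function.
#' @param step_tol minimum Newton step size before declaring a stall.
#' @param max_halving maximum number of step-halvings per Newton iteration.
#' @param h_scale scalar multiplier on the default smoothing matrix
#'   `H = h_scale / n * I`.
#' @param init initializer for the smoothed fit: the nonsmooth LP estimate
#'   (default) or zero.
#' @return a list of class `qrl_control`.
#' @export
qrl_control <- function(M = 1e6, max_iter = 50, tol = 1e-9, step_tol = 1e-12,
                        max_halving = 20, h_scale = 1,
                        init = c("nonsmooth", "zero")) {
  stopifnot(M > 0, max_iter >= 1, tol > 0, h_scale > 0)
  structure(list(M = M, max_iter = max_iter, tol = tol, step_tol = step_tol,
                 max_halving = max_halving, h_scale = h_scale,
                 init = match.arg(init)),
            class = "qrl_control")
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  tau
}

# internal: sigma_ij = sqrt(U' H U) per term
term_sigma <- function(terms, H) {
  sig <- sqrt(rowSums((terms$U %*% H) * terms$U))
  if (any(sig <= 0))
    stop("U' H U not positive: H violates positive definiteness")
  sig
}

# Default smoothing matrix: Gram-standardized, ||H|| = O(1/n).
# H = (U'U/m)^{-1} / n equalizes the induced smoothing bandwidth
# sqrt(U' H U) across covariate patterns and basis scalings (average
# bandwidth^2 = d/n), mimicking the sampling covariance of the estimator the
# smoothing is meant to emulate. A raw identity H = I/n lets the bandwidth
# grow with ||U||, which smooths covariate groups unevenly and leaves a
# visible finite-sample bias in their coefficients.
default_H <- function(tm, h_scale = 1) {
  S <- crossprod(tm$U) / tm$m
  H <- tryCatch(solve(S), error = function(e)
    stop("singular design Gram matrix: reduce the basis or increase n"))
  H <- (H + t(H)) / 2
  H * (h_scale / tm$n)
}

#' Nonsmooth IPCW estimating function
#'
#' The stacked estimating function summing, over subjects and attended visits
#' with `Y_i > t_j`, the design row times the difference between the
#' IPCW-reweighted residual indicator `I(log(Y_i - t_j) <= gamma'U_ij)` and
#' `tau`, divided by `n`.
#'
#' @param gamma stacked coefficient vector.
#' @param data a [study_data()] object.
#' @param tau quantile level.
#' @param basis a `qrl_basis`.
#' @param G a fitted `censoring_km`; defaults to the estimate from `data`.
#' @return numeric vector of length `d`.
#' @export
nonsmooth_estimating_function <- function(gamma, data, tau, basis, G = NULL) {
  check_tau(tau)
  if (is.null(G)) G <- fit_censoring_km(data)
  tm <- qrl_terms(data, basis, G)
  ns_ef_terms(gamma, tm, tau)
}

ns_ef_terms <- function(gamma, tm, tau) {
  ind <- as.numeric(tm$logres <= as.numeric(tm$U %*% gamma))
  as.numeric(crossprod(tm$U, ind * tm$ratio - tau)) / tm$n
}

#' Induced-smoothed IPCW estimating function
#'
#' Smooth surrogate of [nonsmooth_estimating_function()] obtained by averaging
#' the nonsmooth function over a normal perturbation of `gamma` with
#' covariance `H`; the residual indicator becomes a standard-normal CDF with
#' scale `sqrt(U' H U)`.
#'
#' @inheritParams nonsmooth_estimating_function
#' @param H symmetric positive-definite smoothing matrix with norm of order
#'   `1/n`; default is the Gram-standardized matrix `(U'U/m)^{-1}/n`, which
#'   keeps the smoothing bandwidth comparable across covariate patterns.
#' @return numeric vector of length `d`.
#' @export
smoothed_estimating_function <- function(gamma, data, tau, basis, G = NULL,
                                         H = NULL) {
  check_tau(tau)
  if (is.null(G)) G <- fit_censoring_km(data)
  tm <- qrl_terms(data, basis, G)
  if (is.null(H)) H <- default_H(tm)
  sm_ef_terms(gamma, tm, tau, term_sigma(tm, H))
}

sm_ef_terms <- function(gamma, tm, tau, sigma) {
  ph <- stats::pnorm((as.numeric(tm$U %*% gamma) - tm$logres) / sigma)
  as.numeric(crossprod(tm$U, ph * tm$ratio - tau)) / tm$n
}

# slope of the smoothed estimating function (normal density kernel)
slope_terms <- function(gamma, tm, tau, sigma) {
  r <- (as.numeric(tm$U %*% gamma) - tm$logres) / sigma
  cc <- tm$ratio * stats::dnorm(r) / sigma
  crossprod(tm$U * sqrt(cc)) / tm$n
}

qrl_fit_result <- function(gamma, tau, basis, data, G, H, estimator, converged,
                           ef_norm, iterations, control) {
  lay <- gamma_layout(data$p, data$q, basis$n_basis)
  names(gamma) <- paste0(rep(lay$labels, each = basis$n_basis), ".",
                         rep(basis$terms, length(lay$labels)))
  structure(
    list(gamma = gamma, tau = tau, basis = basis, H = H,
         estimator = estimator, converged = converged, ef_norm = ef_norm,
         iterations = iterations, p = data$p, q = data$q, d = lay$d,
         n = data$n, layout = lay, data = data, G = G, control = control,
         covariance = NULL, sandwich = NULL),
    class = "qrl_fit")
}

#' @export
print.qrl_fit <- function(x, ...) {
  cat(sprintf("<qrl_fit> %s estimator, tau = %g, n = %d, d = %d\n",
              x$estimator, x$tau, x$n, x$d))
  cat(sprintf("  converged: %s (|EF|_inf = %.2e, %d iterations)\n",
              x$converged, x$ef_norm, x$iterations))
  if (!is.null(x$covariance))
    cat(sprintf("  sandwich covariance from K = %d resampling replicates\n",
                x$sandwich$K))
  invisible(x)
}

#' @export
coef.qrl_fit <- function(object, ...) object$gamma

#' Nonsmooth estimator via exact weighted L1 linear programming
#'
#' Minimizes the IPCW-weighted least-absolute-deviation objective
#' `sum_ij w_ij |log(Y_i - t_j) - gamma' U_ij| / n` augmented with two
#' pseudo-observations at response `M` whose design rows are
#' `-sum_ij U_ij w_ij / n` and `2 tau sum_ij U_ij / n` (sums over attended
#' visits with `Y_i > t_j`). The subgradient of this objective equals twice
#' the nonsmooth estimating function, so its minimizer is the estimating-
#' equation root in the generalized sense.
#'
#' @inheritParams nonsmooth_estimating_function
#' @param control a [qrl_control()] list.
#' @return a `qrl_fit` object.
#' @export
nonsmooth_estimate <- function(data, tau, basis = fp_basis(), G = NULL,
                               control = qrl_control()) {
  check_tau(tau)
  if (is.null(G)) G <- fit_censoring_km(data)
  tm <- qrl_terms(data, basis, G)
  fit <- ns_solve_terms(tm, tau, control)
  ef <- ns_ef_terms(fit$coefficients, tm, tau)
  # subgradient certificate: at an L1 minimizer every component of the
  # estimating function is bounded by the summed jumps of the terms whose
  # residuals sit at the kink (the active vertex terms)
  res <- tm$logres - as.numeric(tm$U %*% fit$coefficients)
  active <- abs(res) <= 1e-7 * (1 + abs(tm$logres))
  jump <- colSums(abs(tm$U[active, , drop = FALSE]) * tm$ratio[active]) / tm$n
  at_root <- all(abs(ef) <= jump + 1e-8)
  qrl_fit_result(fit$coefficients, tau, basis, data, G, H = NULL,
                 estimator = "nonsmooth",
                 converged = fit$converged || at_root,
                 ef_norm = max(abs(ef)), iterations = fit$iterations,
                 control = control)
}

ns_solve_terms <- function(tm, tau, control, theta = NULL) {
  w <- tm$ratio
  two_tau_row <- 2 * tau * colSums(tm$U * if (is.null(theta)) 1
                                   else theta[tm$i]) / tm$n
  if (!is.null(theta)) w <- w * theta[tm$i]
  pos <- w > 0
  if (!any(pos))
    stop("no (subject, visit) term has positive IPCW weight")
  X <- rbind(tm$U[pos, , drop = FALSE],
             -colSums(tm$U * w) / tm$n,
             two_tau_row)
  y <- c(tm$logres[pos], control$M, control$M)
  wt <- c(w[pos] / tm$n, 1, 1)
  qr_fit_ip(X, y, tau = 0.5, weights = wt)
}

#' Induced-smoothing estimator
#'
#' Solves the smoothed estimating equation by damped Newton iteration with the
#' analytic slope matrix, initialized at the nonsmooth LP estimate. The
#' returned root is re-verified against the estimating function itself; a fit
#' that fails to reach the tolerance is returned with `converged = FALSE`.
#'
#' @inheritParams nonsmooth_estimating_function
#' @param control a [qrl_control()] list; `control$h_scale` scales the default
#'   smoothing matrix `H = h_scale / n * I`.
#' @param H optional explicit smoothing matrix.
#' @return a `qrl_fit` object.
#' @export
induced_smoothing_estimate <- function(data, tau, basis = fp_basis(),
                                       G = NULL, control = qrl_control(),
                                       H = NULL) {
  check_tau(tau)
  if (is.null(G)) G <- fit_censoring_km(data)
  tm <- qrl_terms(data, basis, G)
  if (is.null(H)) H <- default_H(tm, control$h_scale)
  sigma <- term_sigma(tm, H)
  gamma <- if (control$init == "nonsmooth")
    ns_solve_terms(tm, tau, control)$coefficients
  else rep(0, tm$d)
  ef <- sm_ef_terms(gamma, tm, tau, sigma)
  nrm <- max(abs(ef))
  it <- 0
  converged <- nrm <= control$tol
  while (!converged && it < control$max_iter) {
    it <- it + 1
    A <- slope_terms(gamma, tm, tau, sigma)
    kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
    if (!is.finite(kap) || kap > 1e12) {
      # derivative-free polish when the slope is ill-conditioned
      op <- stats::optim(gamma, function(g)
        sum(sm_ef_terms(g, tm, tau, sigma)^2), method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14))
      gamma <- op$par
      ef <- sm_ef_terms(gamma, tm, tau, sigma)
      nrm <- max(abs(ef))
      break
    }
    step <- solve(A, ef)
    lam <- 1
    improved <- FALSE
    for (h in seq_len(control$max_halving)) {
      cand <- gamma - lam * step
      efc <- sm_ef_terms(cand, tm, tau, sigma)
      if (max(abs(efc)) < nrm) {
        gamma <- cand; ef <- efc; nrm <- max(abs(efc))
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved || lam * sqrt(sum(step^2)) < control$step_tol) break
    converged <- nrm <= control$tol
  }
  converged <- max(abs(sm_ef_terms(gamma, tm, tau, sigma))) <= control$tol
  qrl_fit_result(gamma, tau, basis, data, G, H = H,
                 estimator = "smoothed", converged = converged,
                 ef_norm = nrm, iterations = it, control = control)
}
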