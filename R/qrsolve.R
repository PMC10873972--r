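# Primal-dual interior-point solver for weighted quantile regression
# (equivalently, weighted L1 regression when tau = 0.5).
#
# The problem  min_g  sum_k  omega_k * rho_tau(y_k - x_k' g)  is solved through
# the bounded-variable LP dual
#     max  y'a   s.t.  X'a = (1 - tau) X'1,   0 <= a <= 1
# (rows pre-scaled by their weights, valid because rho_tau is positively
# homogeneous). A Mehrotra predictor-corrector iteration on the primal-dual
# pair recovers the regression coefficients as the equality multipliers.

#' Weighted quantile regression by interior-point linear programming
#'
#' Exact (to interior-point tolerance) minimizer of the weighted check-function
#' objective; with `tau = 0.5` this is weighted least-absolute-deviations
#' regression. Used internally to minimize the censored, IPCW-weighted L1
#' objective with large-M pseudo-observations, and exported because it is
#' useful for oracle checks.
#'
#' @param X design matrix (`m x d`), full column rank after weighting.
#' @param y responses.
#' @param tau quantile level in (0, 1).
#' @param weights optional nonnegative case weights; zero-weight rows are
#'   dropped.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the (relative) duality gap; the default
#'   is tight because pseudo-observations with very large responses inflate
#'   the gap's scale.
#' @return list with `coefficients`, `iterations`, `gap`, `converged`.
#' @export
qr_fit_ip <- function(X, y, tau = 0.5, weights = NULL,
                      max_iter = 200, tol = 1e-13) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  X <- as.matrix(X)
  if (!is.null(weights)) {
    if (length(weights) != nrow(X) || any(weights < 0) ||
        any(!is.finite(weights)))
      stop("weights must be nonnegative and finite")
    keep <- weights > 0
    X <- X[keep, , drop = FALSE] * weights[keep]
    y <- y[keep] * weights[keep]
  }
  m <- nrow(X); d <- ncol(X)
  if (m < d) stop("fewer (weighted) observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < d)
    stop("rank-deficient design: collinear column(s) ",
         paste(qrX$pivot[(qrX$rank + 1L):d], collapse = ", "))
  ceq <- crossprod(X, rep(1 - tau, m))
  a <- rep(1 - tau, m); s <- 1 - a
  b <- qr.coef(qrX, y)
  r <- as.numeric(y - X %*% b)
  e0 <- max(1e-5, stats::sd(r) * 1e-4)
  z <- pmax(-r, 0) + e0
  w <- r + z
  yscale <- 1 + sum(abs(y)) / m
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    gap <- sum(z * a) + sum(w * s)
    rp <- ceq - crossprod(X, a)
    rd <- as.numeric(y - X %*% b) - w + z
    if (!is.finite(gap)) break
    if (gap / (m * yscale) < tol && max(abs(rp)) / (1 + sum(abs(ceq))) < tol &&
        max(abs(rd)) / yscale < sqrt(tol)) {
      converged <- TRUE
      break
    }
    if (any(!is.finite(b)) || max(abs(b)) > 1e12 * yscale)
      stop("unbounded L1 objective: try a larger pseudo-observation constant ",
           "or fewer basis terms")
    qv <- 1 / (z / a + w / s)
    XtQ <- X * qv
    Mm <- crossprod(XtQ, X)
    ch <- tryCatch(chol(Mm), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(Mm + diag(1e-10 * max(diag(Mm)), d))
    solveM <- function(v) backsolve(ch, forwardsolve(t(ch), v))
    # predictor (affine) direction
    rhs_a <- rd + w - z
    db_a <- solveM(crossprod(X, qv * rhs_a) - rp)
    da_a <- qv * (rhs_a - as.numeric(X %*% db_a))
    dz_a <- -z - (z / a) * da_a
    dw_a <- -w + (w / s) * da_a
    step <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
    }
    ap <- min(step(a, da_a), step(s, -da_a))
    ad <- min(step(z, dz_a), step(w, dw_a))
    gap_aff <- sum((z + ad * dz_a) * (a + ap * da_a)) +
      sum((w + ad * dw_a) * (s - ap * da_a))
    mu <- (gap_aff / gap)^3 * gap / (2 * m)
    # numerically stalled (typically already at vertex precision): stop here
    if (!is.finite(mu) || !all(is.finite(da_a)) || !all(is.finite(db_a)))
      break
    # corrector
    cz <- (mu - a * z - da_a * dz_a) / a
    cw <- (mu - s * w + da_a * dw_a) / s
    rhs <- rd - cw + cz
    db <- solveM(crossprod(X, qv * rhs) - rp)
    da <- qv * (rhs - as.numeric(X %*% db))
    dz <- cz - (z / a) * da
    dw <- cw + (w / s) * da
    if (!all(is.finite(da)) || !all(is.finite(db)) ||
        !all(is.finite(dz)) || !all(is.finite(dw)))
      break
    eta <- 0.9995
    ap <- eta * min(step(a, da), step(s, -da))
    ad <- eta * min(step(z, dz), step(w, dw))
    floor_dual <- 1e-14 * yscale
    a <- a + ap * da
    s <- 1 - a
    b <- b + ad * db
    z <- pmax(z + ad * dz, floor_dual)
    w <- pmax(w + ad * dw, floor_dual)
    a <- pmin(pmax(a, 1e-14), 1 - 1e-14)
    s <- pmin(pmax(s, 1e-14), 1 - 1e-14)
  }
  list(coefficients = as.numeric(b), iterations = it,
       gap = sum(z * a) + sum(w * s), converged = converged)
}
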