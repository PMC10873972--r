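#' Fractional-polynomial basis for time-varying coefficients
#'
#' Constructs a set of basis functions `f_0(t), ..., f_L(t)` from a vector of
#' fractional-polynomial term labels. Time-varying regression coefficients are
#' represented as linear combinations of these functions, so the choice of
#' terms controls the flexibility of the coefficient curves.
#'
#' The default set `{1, log(t), sqrt(t), 1/sqrt(t)}` is the working basis used
#' throughout the built-in simulation studies. Terms involving `log(t)`,
#' `1/sqrt(t)` or `1/t` diverge at the origin, so such bases can only be
#' evaluated at strictly positive times.
#'
#' @param terms character vector of term labels; supported labels are
#'   `"1"`, `"log(t)"`, `"sqrt(t)"`, `"1/sqrt(t)"`, `"1/t"`, `"t"`, `"t^2"`.
#' @return An object of class `qrl_basis` with elements `kind`, `terms`,
#'   `n_basis` (the number of functions, `L + 1`) and `domain_min`.
#' @examples
#' b <- fp_basis()
#' evaluate_basis(b, c(0.25, 1))
#' @seealso [bspline_basis()], [evaluate_basis()]
#' @export
fp_basis <- function(terms = c("1", "log(t)", "sqrt(t)", "1/sqrt(t)")) {
  known <- c("1", "log(t)", "sqrt(t)", "1/sqrt(t)", "1/t", "t", "t^2")
  bad <- setdiff(terms, known)
  if (length(bad) > 0L)
    stop("unknown fractional-polynomial term(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(terms))
    stop("duplicated basis terms")
  singular0 <- c("log(t)", "1/sqrt(t)", "1/t")
  domain_min <- if (any(terms %in% singular0)) .Machine$double.xmin else 0
  structure(
    list(kind = "fractional_polynomial",
         terms = terms,
         n_basis = length(terms),
         domain_min = domain_min),
    class = "qrl_basis")
}

#' B-spline basis for time-varying coefficients
#'
#' A constant function plus a B-spline expansion on a bounded time window.
#' The leading constant keeps the basis comparable with the
#' fractional-polynomial sets (whose first term is identically 1) and makes an
#' intercept-only model a special case.
#'
#' @param n_knots number of interior knots, placed equally spaced inside
#'   `boundary`.
#' @param degree spline degree (default cubic).
#' @param boundary length-2 numeric, the boundary knots. Evaluation outside
#'   this window extrapolates and is not recommended.
#' @return An object of class `qrl_basis`.
#' @export
bspline_basis <- function(n_knots = 0, degree = 3, boundary = c(0.1, 1)) {
  stopifnot(n_knots >= 0, degree >= 1, length(boundary) == 2,
            boundary[1] < boundary[2])
  knots <- if (n_knots > 0)
    seq(boundary[1], boundary[2], length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  else numeric(0)
  structure(
    list(kind = "bspline",
         terms = c("1", paste0("bs", seq_len(degree + n_knots))),
         n_basis = 1L + degree + n_knots,
         degree = degree,
         knots = knots,
         boundary = boundary,
         domain_min = 0),
    class = "qrl_basis")
}

#' @export
print.qrl_basis <- function(x, ...) {
  cat(sprintf("<qrl_basis> %s with %d functions: %s\n",
              x$kind, x$n_basis, paste(x$terms, collapse = ", ")))
  invisible(x)
}

#' Evaluate basis functions
#'
#' @param basis a `qrl_basis`.
#' @param t numeric vector of evaluation times, each `>= basis$domain_min`.
#' @return numeric matrix, `length(t)` rows by `basis$n_basis` columns; row `i`
#'   is `(f_0(t_i), ..., f_L(t_i))`.
#' @export
evaluate_basis <- function(basis, t) {
  stopifnot(inherits(basis, "qrl_basis"), is.numeric(t))
  if (any(!is.finite(t)))
    stop("non-finite evaluation time")
  if (any(t < basis$domain_min)) {
    offender <- if (basis$kind == "fractional_polynomial")
      intersect(basis$terms, c("log(t)", "1/sqrt(t)", "1/t"))[1]
    else "spline"
    stop(sprintf("evaluation time below basis domain (t = %g): term %s undefined",
                 min(t), offender))
  }
  out <- switch(basis$kind,
    fractional_polynomial = {
      cols <- lapply(basis$terms, function(tm)
        switch(tm,
               "1"         = rep(1, length(t)),
               "log(t)"    = log(t),
               "sqrt(t)"   = sqrt(t),
               "1/sqrt(t)" = 1 / sqrt(t),
               "1/t"       = 1 / t,
               "t"         = t,
               "t^2"       = t^2))
      do.call(cbind, cols)
    },
    bspline = {
      sp <- splines::bs(t, knots = basis$knots, degree = basis$degree,
                        Boundary.knots = basis$boundary, intercept = FALSE)
      cbind(1, unclass(sp)[, , drop = FALSE])
    },
    stop("unknown basis kind"))
  out <- matrix(as.numeric(out), nrow = length(t))
  colnames(out) <- basis$terms
  if (any(!is.finite(out)))
    stop("basis evaluation produced non-finite values")
  out
}
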