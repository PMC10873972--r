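# Stacked-coefficient layout and design-row construction.
#
# The full parameter vector gamma stacks one block of basis coefficients per
# regression coefficient function, in the order
#   alpha_0, alpha_1, ..., alpha_p, beta_1, ..., beta_q,
# each block of length L + 1 (the number of basis functions), so
# d = (p + 1 + q)(L + 1).

#' Coefficient block layout of the stacked parameter vector
#'
#' @param p number of time-fixed covariates (excluding the intercept).
#' @param q number of time-varying covariates.
#' @param n_basis number of basis functions `L + 1`.
#' @return a list with `labels` (one per coefficient function), `d` (total
#'   parameter length) and `block` (a function mapping a coefficient label or
#'   index to the positions of its block in the stacked vector).
#' @export
gamma_layout <- function(p, q, n_basis) {
  labels <- c(paste0("alpha", 0:p), if (q > 0) paste0("beta", seq_len(q)))
  nb <- n_basis
  block <- function(which) {
    b <- if (is.character(which)) match(which, labels) else as.integer(which)
    if (is.na(b) || b < 1L || b > length(labels))
      stop("unknown coefficient block: ", which)
    ((b - 1L) * nb + 1L):(b * nb)
  }
  list(labels = labels, d = length(labels) * nb, block = block,
       n_basis = nb, p = p, q = q)
}

#' Design row for one subject at one attended visit
#'
#' Builds the stacked covariate-by-basis row
#' `(xi(t_j), W_1 xi(t_j), ..., W_p xi(t_j), Z_1(t_j) xi(t_j), ..., Z_q(t_j) xi(t_j))`
#' used by the estimating functions. The intercept block is implicit: the
#' leading `xi(t_j)` plays the role of the constant covariate.
#'
#' @param data a [study_data()] object.
#' @param subject subject index (row) in `data`.
#' @param visit planned-visit index `j`; must be attended and satisfy
#'   `Y > t_j`.
#' @param basis a [fp_basis()] or [bspline_basis()] object.
#' @return numeric vector of length `(p + 1 + q) * n_basis`.
#' @export
build_design_row <- function(data, subject, visit, basis) {
  stopifnot(inherits(data, "study_data"))
  i <- as.integer(subject); j <- as.integer(visit)
  if (i < 1L || i > data$n) stop("subject index out of range")
  if (j < 1L || j > data$D) stop("visit index out of range")
  if (data$attended[i, j] != 1)
    stop(sprintf("visit %d not attended by subject %d", j, i))
  tj <- data$visit_schedule[j]
  if (data$time[i] <= tj)
    stop(sprintf("observed time (%g) not beyond visit time (%g)",
                 data$time[i], tj))
  xi <- evaluate_basis(basis, tj)[1, ]
  v <- c(1, if (data$p > 0) data$W[i, ], if (data$q > 0) data$Z[i, j, ])
  if (any(!is.finite(v))) stop("non-finite covariates in design row")
  as.numeric(kronecker(v, xi))
}

# Internal: flatten a dataset into the (i, j) term representation used by all
# estimating functions. One row per attended visit with Y_i > t_j. The IPCW
# ratio Ghat(t_j)/Ghat(Y_i) is attached per term, together with the grid
# indices needed to re-evaluate it under a perturbed censoring estimate.
qrl_terms <- function(data, basis, G) {
  n <- data$n
  xi <- evaluate_basis(basis, data$visit_schedule)   # D x (L+1)
  nb <- basis$n_basis
  ncov <- 1L + data$p + data$q
  d <- ncov * nb
  rows <- vector("list", data$D)
  for (j in seq_len(data$D)) {
    tj <- data$visit_schedule[j]
    sel <- which(data$attended[, j] == 1 & data$time > tj)
    if (length(sel) == 0L) next
    V <- cbind(rep(1, length(sel)),
               if (data$p > 0) data$W[sel, , drop = FALSE],
               if (data$q > 0) matrix(data$Z[sel, j, ], ncol = data$q))
    U <- V[, rep(seq_len(ncov), each = nb), drop = FALSE] *
      matrix(xi[j, ], nrow = length(sel), ncol = d, byrow = TRUE)
    rows[[j]] <- list(U = U, i = sel, j = rep(j, length(sel)),
                      tj = rep(tj, length(sel)))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no usable (subject, visit) terms")
  U <- do.call(rbind, lapply(rows, `[[`, "U"))
  i <- unlist(lapply(rows, `[[`, "i"))
  j <- unlist(lapply(rows, `[[`, "j"))
  tj <- unlist(lapply(rows, `[[`, "tj"))
  Yi <- data$time[i]
  delta <- data$status[i]
  logres <- log(Yi - tj)
  Gt <- evaluate_G(G, tj)
  GY <- evaluate_G(G, Yi)
  ratio <- ifelse(delta == 1, Gt / GY, 0)
  bad <- delta == 1 & GY <= 0
  if (any(bad)) {
    warning(sum(bad), " term(s) dropped: censoring survival estimate is 0 at ",
            "an observed failure time (degenerate IPCW weight)")
    keep <- !bad
    U <- U[keep, , drop = FALSE]; i <- i[keep]; j <- j[keep]; tj <- tj[keep]
    Yi <- Yi[keep]; delta <- delta[keep]; logres <- logres[keep]
    Gt <- Gt[keep]; GY <- GY[keep]; ratio <- ratio[keep]
  }
  # grid indices into G's jump times, for fast perturbed re-evaluation
  idx_t <- findInterval(tj, G$time)
  idx_Y <- findInterval(Yi, G$time)
  list(U = U, i = i, j = j, tj = tj, Y = Yi, delta = delta,
       logres = logres, ratio = ratio, idx_t = idx_t, idx_Y = idx_Y,
       n = n, d = d, m = nrow(U))
}

#' Evaluate time-varying coefficient functions from a stacked estimate
#'
#' Each coefficient function is the inner product of its block of `gamma` with
#' the basis vector `xi(t)`. When a covariance matrix for `gamma` is supplied,
#' delta-method standard errors and Wald 95% confidence limits are added:
#' `SE(t) = sqrt(xi(t)' Sigma_block xi(t))`.
#'
#' @param gamma stacked coefficient vector of length `(p + 1 + q) * n_basis`.
#' @param basis the basis the fit used.
#' @param times evaluation times.
#' @param p,q covariate counts (see [gamma_layout()]).
#' @param Sigma optional `d x d` covariance matrix of `gamma`.
#' @param level confidence level for the Wald interval.
#' @return data.frame with columns `coefficient`, `t`, `estimate` and, when
#'   `Sigma` is given, `se`, `lower`, `upper`.
#' @export
evaluate_coefficient_functions <- function(gamma, basis, times, p, q,
                                           Sigma = NULL, level = 0.95) {
  lay <- gamma_layout(p, q, basis$n_basis)
  if (length(gamma) != lay$d)
    stop("gamma has length ", length(gamma), ", expected ", lay$d)
  xi <- evaluate_basis(basis, times)
  out <- do.call(rbind, lapply(seq_along(lay$labels), function(b) {
    idx <- lay$block(b)
    est <- as.numeric(xi %*% gamma[idx])
    df <- data.frame(coefficient = lay$labels[b], t = times, estimate = est)
    if (!is.null(Sigma)) {
      Sb <- Sigma[idx, idx, drop = FALSE]
      se <- sqrt(pmax(rowSums((xi %*% Sb) * xi), 0))
      zq <- stats::qnorm(1 - (1 - level) / 2)
      df$se <- se
      df$lower <- est - zq * se
      df$upper <- est + zq * se
    }
    df
  }))
  rownames(out) <- NULL
  out
}
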