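#' Assemble a censored longitudinal study dataset
#'
#' Container for right-censored outcomes with time-fixed covariates and
#' longitudinal covariates measured on a shared schedule of planned visits.
#' Visits may be missed; the attendance matrix records which planned visits
#' each subject actually made, and time-varying covariate values exist exactly
#' at attended visits.
#'
#' @param id vector of subject labels (unique).
#' @param time observed follow-up times `Y = min(T, C)`, strictly positive.
#' @param status event indicators, 1 = failure observed, 0 = censored.
#' @param W `n x p` matrix (or data.frame) of time-fixed covariates, or `NULL`
#'   for none. Do not include an intercept column; it is added when design
#'   rows are built.
#' @param visit_schedule strictly increasing vector of planned visit times,
#'   all positive, shared by every subject.
#' @param attended `n x D` 0/1 matrix of attendance indicators.
#' @param Z `n x D x q` array (or `n x D` matrix when `q = 1`) of time-varying
#'   covariate values; entries must be finite where `attended == 1` and are
#'   ignored (conventionally `NA`) elsewhere. `NULL` for a model without
#'   time-varying covariates.
#' @return An object of class `study_data`.
#' @export
study_data <- function(id, time, status, W = NULL, visit_schedule, attended, Z) {
  n <- length(time)
  if (n < 1L) stop("empty data")
  if (length(id) != n || length(status) != n)
    stop("id, time, status must have equal length")
  if (anyDuplicated(id)) stop("duplicated subject ids")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("observed times must be finite and > 0")
  if (!all(status %in% c(0, 1)))
    stop("event indicators must be 0 or 1")
  if (is.null(W)) W <- matrix(numeric(0), nrow = n, ncol = 0)
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (nrow(W) != n) stop("W must have one row per subject")
  if (ncol(W) > 0 && any(!is.finite(W))) stop("non-finite time-fixed covariates")
  p <- ncol(W)
  D <- length(visit_schedule)
  if (D < 1L) stop("visit schedule must be non-empty")
  if (any(visit_schedule <= 0) || is.unsorted(visit_schedule, strictly = TRUE))
    stop("visit schedule must be strictly increasing and positive")
  attended <- as.matrix(attended)
  if (!identical(dim(attended), c(n, D)) &&
      !(nrow(attended) == n && ncol(attended) == D))
    stop("attended must be an n x D matrix")
  if (!all(attended %in% c(0, 1))) stop("attendance indicators must be 0 or 1")
  if (is.null(Z)) Z <- array(numeric(0), dim = c(n, D, 0L))
  if (is.matrix(Z)) Z <- array(Z, dim = c(nrow(Z), ncol(Z), 1L))
  if (!is.array(Z) || length(dim(Z)) != 3L)
    stop("Z must be an n x D x q array (or n x D matrix)")
  if (dim(Z)[1] != n || dim(Z)[2] != D)
    stop("Z dimensions do not match (n, D)")
  q <- dim(Z)[3]
  att <- attended == 1
  for (k in seq_len(q)) {
    zk <- Z[, , k]
    if (any(!is.finite(zk[att])))
      stop("time-varying covariate ", k,
           " missing or non-finite at an attended visit")
  }
  if (is.null(colnames(W)) && p > 0) colnames(W) <- paste0("W", seq_len(p))
  structure(
    list(id = id, time = as.numeric(time), status = as.integer(status),
         W = W, visit_schedule = as.numeric(visit_schedule),
         attended = attended, Z = Z,
         n = n, p = p, q = q, D = D),
    class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf(
    "<study_data> n = %d subjects, %d fixed + %d time-varying covariates, %d planned visits\n",
    x$n, x$p, x$q, x$D))
  cat(sprintf("  censoring: %.1f%%; attended visits: %d of %d possible\n",
              100 * mean(x$status == 0), sum(x$attended), x$n * x$D))
  invisible(x)
}

#' Read a long-format study CSV
#'
#' The dialect has one row per (subject, planned visit) with columns
#' `id, Y, delta, W1..Wp, visit_time, attended, Z1..Zq`. Subject-level columns
#' must be constant within subject; `Z` values must be present exactly at
#' attended visits. [write_study_csv()] emits the identical dialect.
#'
#' @param path file path.
#' @return a [study_data()] object.
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "Y", "delta", "visit_time", "attended")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  wcols <- grep("^W[0-9]+$", names(df), value = TRUE)
  zcols <- grep("^Z[0-9]+$", names(df), value = TRUE)
  if (length(zcols) == 0) stop("no time-varying covariate columns Z1..Zq")
  schedule <- sort(unique(df$visit_time))
  ids <- unique(df$id)
  n <- length(ids); D <- length(schedule); q <- length(zcols); p <- length(wcols)
  time <- numeric(n); status <- integer(n)
  W <- matrix(NA_real_, n, p, dimnames = list(NULL, wcols))
  attended <- matrix(0, n, D)
  Z <- array(NA_real_, dim = c(n, D, q))
  for (i in seq_len(n)) {
    rows <- df[df$id == ids[i], , drop = FALSE]
    for (cn in c("Y", "delta", wcols))
      if (length(unique(rows[[cn]])) != 1L)
        stop(sprintf("column %s not constant within subject %s", cn, ids[i]))
    time[i] <- rows$Y[1]; status[i] <- rows$delta[1]
    if (p > 0) W[i, ] <- as.numeric(rows[1, wcols])
    jj <- match(rows$visit_time, schedule)
    if (anyDuplicated(jj))
      stop("duplicated visit rows for subject ", ids[i])
    attended[i, jj] <- rows$attended
    for (k in seq_len(q)) {
      zv <- rows[[zcols[k]]]
      att1 <- rows$attended == 1
      if (any(att1 & !is.finite(zv)))
        stop(sprintf("missing %s at attended visit (id = %s, visit_time = %g)",
                     zcols[k], ids[i][1],
                     rows$visit_time[which(att1 & !is.finite(zv))[1]]))
      Z[i, jj, k] <- zv
    }
  }
  study_data(ids, time, status, if (p > 0) W else NULL, schedule, attended, Z)
}

#' Write a study dataset as a long-format CSV
#'
#' @param data a [study_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(data, path) {
  stopifnot(inherits(data, "study_data"))
  n <- data$n; D <- data$D
  df <- data.frame(
    id = rep(data$id, each = D),
    Y = rep(data$time, each = D),
    delta = rep(data$status, each = D))
  for (k in seq_len(data$p))
    df[[colnames(data$W)[k]]] <- rep(data$W[, k], each = D)
  df$visit_time <- rep(data$visit_schedule, times = n)
  df$attended <- as.integer(t(data$attended))
  for (k in seq_len(data$q)) {
    zk <- t(data$Z[, , k])
    zk[t(data$attended) == 0] <- NA_real_
    df[[paste0("Z", k)]] <- as.numeric(zk)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
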