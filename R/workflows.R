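# High-level fitting front end and the file-based workflows used by the
# command-line script (inst/cli/qreslife.R).

#' Fit a quantile residual-life regression model
#'
#' One-call front end: estimates the censoring distribution, fits the chosen
#' estimator, and (for the smoothed estimator) attaches the resampling
#' sandwich covariance.
#'
#' @param data a [study_data()] object.
#' @param tau quantile level in (0, 1).
#' @param basis basis for the time-varying coefficients.
#' @param estimator `"smoothed"` (induced smoothing, default) or
#'   `"nonsmooth"` (exact L1 linear programming).
#' @param se compute the sandwich covariance (smoothed estimator only).
#' @param K resampling replicates for the covariance.
#' @param seed optional seed for the resampling multipliers.
#' @param control a [qrl_control()] list.
#' @return a `qrl_fit`.
#' @export
qrl_fit <- function(data, tau, basis = fp_basis(),
                    estimator = c("smoothed", "nonsmooth"),
                    se = TRUE, K = 200, seed = NULL,
                    control = qrl_control()) {
  estimator <- match.arg(estimator)
  G <- fit_censoring_km(data)
  fit <- if (estimator == "smoothed")
    induced_smoothing_estimate(data, tau, basis, G = G, control = control)
  else nonsmooth_estimate(data, tau, basis, G = G, control = control)
  if (se && estimator == "smoothed")
    fit <- qrl_variance(fit, K = K, seed = seed)
  fit
}

#' Serialize a fit to JSON
#'
#' Writes the coefficient layout, estimates, smoothing scale, convergence
#' diagnostics and (if present) the sandwich covariance.
#'
#' @param fit a `qrl_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    schema = "qreslife/fit/v1",
    estimator = fit$estimator,
    tau = fit$tau,
    n = fit$n,
    basis = list(kind = fit$basis$kind, terms = fit$basis$terms),
    layout = list(p = fit$p, q = fit$q, labels = fit$layout$labels),
    gamma = as.list(fit$gamma),
    h_scale = if (!is.null(fit$H)) fit$H[1, 1] * fit$n else NULL,
    convergence = list(converged = fit$converged, ef_norm = fit$ef_norm,
                       iterations = fit$iterations),
    covariance = if (!is.null(fit$covariance))
      unname(apply(fit$covariance, 1, as.list)) else NULL,
    K = if (!is.null(fit$sandwich)) fit$sandwich$K else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' File-based model fit
#'
#' Reads a long-format study CSV, fits the model at each requested quantile,
#' and writes per-(tau, time) coefficient tables and fit JSON artifacts into
#' an output directory.
#'
#' @param input path to a study CSV (dialect of [write_study_csv()]).
#' @param output_dir directory for results (created if missing).
#' @param taus quantile levels.
#' @param eval_times base times for the coefficient table.
#' @param basis fitting basis.
#' @param estimator,K,seed,control passed to [qrl_fit()].
#' @return the combined coefficient table, invisibly.
#' @export
fit_from_csv <- function(input, output_dir, taus = 0.5,
                         eval_times = c(0.1, 0.2, 0.5, 0.8),
                         basis = fp_basis(),
                         estimator = "smoothed", K = 200, seed = NULL,
                         control = qrl_control()) {
  data <- read_study_csv(input)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list()
  for (tau in taus) {
    fit <- qrl_fit(data, tau, basis, estimator, se = estimator == "smoothed",
                   K = K, seed = seed, control = control)
    if (fit$estimator == "smoothed" && !fit$converged)
      stop("estimator did not converge at tau = ", tau,
           " (|EF|_inf = ", signif(fit$ef_norm, 3), ")")
    tab <- summary(fit, times = eval_times)
    tag <- gsub("\\.", "p", sprintf("tau%.2f", tau))
    write_coefficient_table(
      tab,
      csv_path = file.path(output_dir, paste0("coefficients_", tag, ".csv")),
      json_path = file.path(output_dir, paste0("coefficients_", tag, ".json")))
    write_fit_json(fit, file.path(output_dir, paste0("fit_", tag, ".json")))
    tabs[[length(tabs) + 1L]] <- tab
  }
  invisible(do.call(rbind, tabs))
}

#' Simulate a design to CSV
#'
#' Writes a generated dataset in the long-format dialect together with a JSON
#' file of the true coefficient values at the requested times.
#'
#' @param setup design 1, 2 or 3.
#' @param n sample size.
#' @param tau quantile level (used by designs II/III).
#' @param seed integer seed.
#' @param data_path output CSV path.
#' @param truth_path optional JSON path for the true coefficients.
#' @param truth_times times at which truths are tabulated.
#' @return the dataset, invisibly.
#' @export
simulate_to_csv <- function(setup, n, tau = 0.5, seed = 1, data_path,
                            truth_path = NULL,
                            truth_times = c(0.1, 0.2, 0.5, 0.8)) {
  dat <- sim_generate(setup, n, tau, seed = seed)
  write_study_csv(dat, data_path)
  if (!is.null(truth_path)) {
    tr <- true_coefficients(setup, tau, truth_times)
    jsonlite::write_json(list(schema = "qreslife/truth/v1", setup = setup,
                              tau = tau, table = tr),
                         truth_path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dat)
}
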