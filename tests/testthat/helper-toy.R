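# Small in-code fixtures shared across test files.

# three-subject toy with one censored subject, one fixed and one varying
# covariate on a two-visit schedule; small enough for hand/loop oracles
toy3 <- function() {
  study_data(
    id = c("s1", "s2", "s3"),
    time = c(1.4, 0.9, 2.5),
    status = c(1, 0, 1),
    W = matrix(c(0, 1, 1), ncol = 1),
    visit_schedule = c(0.3, 0.7),
    attended = rbind(c(1, 1), c(1, 0), c(0, 1)),
    Z = matrix(c(0.5, -1.0, NA,
                 1.2,   NA, 0.4), nrow = 3))
}

# literal double-loop transcription of the nonsmooth estimating function:
# (1/n) sum_i sum_j eta_ij I(Y_i > t_j) U_ij { I(log(Y_i - t_j) <= g'U) *
#   delta_i G(t_j)/G(Y_i) - tau }
loop_nonsmooth_ef <- function(gamma, data, tau, basis, G) {
  d <- (1 + data$p + data$q) * basis$n_basis
  out <- numeric(d)
  for (i in seq_len(data$n)) {
    for (j in seq_len(data$D)) {
      tj <- data$visit_schedule[j]
      if (data$attended[i, j] != 1 || data$time[i] <= tj) next
      U <- build_design_row(data, i, j, basis)
      ind <- as.numeric(log(data$time[i] - tj) <= sum(gamma * U))
      ratio <- if (data$status[i] == 1)
        evaluate_G(G, tj) / evaluate_G(G, data$time[i]) else 0
      out <- out + U * (ind * ratio - tau)
    }
  }
  out / data$n
}

# literal transcription of the induced-smoothed estimating function, with an
# optional per-subject multiplier (theta) and censoring estimate override
loop_smoothed_ef <- function(gamma, data, tau, basis, G, H,
                             theta = rep(1, data$n), Gstar = G) {
  d <- (1 + data$p + data$q) * basis$n_basis
  out <- numeric(d)
  for (i in seq_len(data$n)) {
    for (j in seq_len(data$D)) {
      tj <- data$visit_schedule[j]
      if (data$attended[i, j] != 1 || data$time[i] <= tj) next
      U <- build_design_row(data, i, j, basis)
      sig <- sqrt(sum(U * (H %*% U)))
      ph <- pnorm((sum(gamma * U) - log(data$time[i] - tj)) / sig)
      ratio <- if (data$status[i] == 1)
        evaluate_G(Gstar, tj) / evaluate_G(Gstar, data$time[i]) else 0
      out <- out + theta[i] * U * (ph * ratio - tau)
    }
  }
  out / data$n
}

# naive product-limit estimator for censoring times with positive weights,
# written independently of the package's implementation
naive_weighted_G <- function(time, status, theta, at) {
  cens <- sort(unique(time[status == 0]))
  vapply(at, function(tt) {
    g <- 1
    for (u in cens[cens <= tt]) {
      d <- sum(theta[time == u & status == 0])
      r <- sum(theta[time >= u]) - sum(theta[time == u & status == 1])
      if (r > 0) g <- g * (1 - d / r)
    }
    g
  }, 0)
}
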