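# Independent fixed-step explicit-Euler integrator of the five-species
# cycle, used as a brute-force oracle against the adaptive solver.
euler_cycle <- function(config, k, out_times, step = 1e-4) {
  y <- c(F = config$F0, P = config$P0, I = 0, A = 0, W = 0)
  res <- matrix(NA_real_, length(out_times), 5,
                dimnames = list(NULL, names(y)))
  t_prev <- 0
  for (j in seq_along(out_times)) {
    n_steps <- round((out_times[j] - t_prev) / step)
    h <- (out_times[j] - t_prev) / n_steps
    for (i in seq_len(n_steps)) {
      act <- k$k1 * y[1] * y[2]
      y <- y + h * c(-k$k0 * y[1] - act,
                     -act + k$k3 * y[3] + k$k4 * y[4],
                     act - (k$k2 + k$k3) * y[3],
                     k$k2 * y[3] - k$k4 * y[4],
                     k$k0 * y[1] + (k$k2 + k$k3) * y[3])
    }
    res[j, ] <- y
    t_prev <- out_times[j]
  }
  cbind(time = out_times, as.data.frame(res))
}

# random but physically plausible rate-constant draws
random_constants <- function() {
  rate_constants(k0 = runif(1, 0.01, 0.3),
                 k1 = runif(1, 0.002, 0.06),
                 k2 = runif(1, 0.5, 5),
                 k3 = runif(1, 0.5, 8),
                 k4 = runif(1, 0.05, 0.4))
}

# hand-built time course from an anhydride trace (other species zero/flat)
trace_tc <- function(time, A, F = 0, P = 0) {
  as_time_course(data.frame(
    time_min = time, F_mM = F, P_mM = P, I_mM = 0, A_mM = A, W_mM = 0))
}
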