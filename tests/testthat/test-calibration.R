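truth_k <- default_rate_constants()

test_that("noiseless self-generated data return the generator's constants", {
  cfg <- experiment_config(F0 = 25)
  # the intermediate equilibrates within the first minute, so the schedule
  # must sample it early for k2 and k3 to be separable
  times <- sort(unique(c(seq(0.1, 0.9, by = 0.2), seq(1, 30, length.out = 12))))
  d <- synth_hplc(cfg, truth_k, sample_times = times,
                  noise = noise_spec(0, 0, seed = 1),
                  species = c("fuel", "anhydride", "precursor"))
  guess <- rate_constants(truth_k$k0 * 1.6, truth_k$k1 * 0.6,
                          truth_k$k2 * 1.4, truth_k$k3 * 0.7,
                          truth_k$k4 * 1.5)
  fit <- fit_rate_constants(d, cfg, guess)
  expect_true(fit$converged)
  rel <- abs(unlist(fit$rate_constants) / unlist(truth_k) - 1)
  expect_lt(max(rel), 1e-3)
  expect_false(fit$under_determined)
})

test_that("fuel-only experiments pin down only the fuel hydrolysis rate", {
  cfg <- experiment_config(F0 = 25, P0 = 0)
  d <- synth_hplc(cfg, truth_k, sample_times = seq(2, 40, by = 4),
                  noise = noise_spec(0, 0, seed = 2), species = "fuel")
  w <- capture_warnings(fit <- fit_rate_constants(d, cfg, truth_k))
  expect_match(w, "only k0", all = FALSE)
  expect_true(fit$under_determined)
  expect_identical(fit$free, "k0")
  expect_equal(fit$rate_constants$k0, truth_k$k0, tolerance = 1e-4)
})

test_that("constants are recovered without bias from noisy replicates", {
  # joint calibration over a low- and a high-fuel course, as one constant
  # set must describe every condition; the high-fuel precursor draw-down is
  # what separates direct hydrolysis (k0) from activation (k1)
  times <- sort(unique(c(seq(0.1, 0.9, by = 0.2), seq(1, 30, length.out = 12))))
  guess <- rate_constants(truth_k$k0 * 1.3, truth_k$k1 * 0.8,
                          truth_k$k2 * 1.2, truth_k$k3 * 0.9,
                          truth_k$k4 * 1.2)
  rec <- sapply(1:20, function(i) {
    d <- do.call(rbind, lapply(c(25, 60), function(f0) {
      di <- synth_hplc(experiment_config(F0 = f0), truth_k, times,
                       noise_spec(0.05, 0, seed = 100 + i + 1000 * f0),
                       species = c("fuel", "anhydride", "precursor"))
      di$F0_mM <- f0
      di
    }))
    unlist(fit_rate_constants(d, experiment_config(F0 = 25), guess)$rate_constants)
  })
  med <- apply(rec, 1, median)
  expect_lt(max(abs(med / unlist(truth_k) - 1)), 0.10)
})

test_that("dropping filtrate rows is announced", {
  cfg <- experiment_config(F0 = 25)
  d <- synth_hplc(cfg, truth_k, seq(1, 20, 2), noise_spec(0, 0, 1),
                  species = c("fuel", "anhydride", "precursor"))
  filt <- synth_hplc(cfg, truth_k, seq(1, 20, 4), noise_spec(0, 0, 1),
                     species = "anhydride", filtrate = TRUE)
  expect_warning(fit_rate_constants(rbind(d, filt), cfg, truth_k),
                 "filtrate")
})

test_that("quench correction undoes the post-filtration production", {
  tc <- simulate_cycle(experiment_config(F0 = 25), truth_k, t_end = 30,
                       output_step = 1 / 60)
  for (t_f in c(1, 3, 8, 15)) {
    for (delay in c(20, 60)) {
      i_f <- which.min(abs(tc$time_min - t_f))
      i_m <- which.min(abs(tc$time_min - (t_f + delay / 60)))
      state <- c(F = tc$F_mM[i_f], P = tc$P_mM[i_f], I = tc$I_mM[i_f])
      corrected <- quench_correction(tc$A_mM[i_m], state, delay, truth_k)
      expect_lt(abs(corrected / tc$A_mM[i_f] - 1), 0.01)
    }
  }
})

test_that("quench correction is the identity at zero delay and monotone in delay", {
  state <- c(F = 15, P = 20, I = 0.5)
  expect_identical(quench_correction(2, state, 0, truth_k), 2)
  sweep <- vapply(seq(15, 25, by = 2.5), function(d)
    quench_correction(2, state, d, truth_k), numeric(1))
  expect_true(all(diff(sweep) < 0))  # longer delay, larger subtraction
  expect_error(quench_correction(2, state, -1, truth_k), ">= 0")
  # correction larger than the measurement floors at zero with a warning
  expect_warning(z <- quench_correction(0.01, c(F = 50, P = 23, I = 2), 60,
                                        truth_k), "floor")
  expect_identical(z, 0)
})

test_that("the one-site isotherm fit recovers a noiseless truth exactly", {
  truth <- binding_model(Kd = 2.9, dH = -4, n = 1)
  iso <- synth_itc(truth, noise = noise_spec(0, 0, seed = 1))
  fit <- fit_binding_isotherm(iso)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$Kd / truth$Kd - 1), 1e-3)
  expect_lt(abs(fit$model$dH / truth$dH - 1), 1e-3)
  expect_lt(abs(fit$model$n / truth$n - 1), 1e-3)
  expect_true(fit$low_c)  # c ~ 0.4 by design of this titration
})

test_that("a zero-enthalpy isotherm is flagged unidentifiable, not fitted", {
  iso <- synth_itc(binding_model(Kd = 2.9, dH = 0, n = 1),
                   noise = noise_spec(0, 0, seed = 1))
  expect_true(all(iso$heats_uJ == 0))
  fit <- fit_binding_isotherm(iso)
  expect_true(fit$unidentifiable)
})

test_that("the isotherm fit is equivariant under uniform rescaling of heats", {
  iso <- synth_itc(binding_model(Kd = 2.9, dH = -4, n = 1),
                   noise = noise_spec(0.02, 0, seed = 9))
  f1 <- fit_binding_isotherm(iso)
  iso$heats_uJ <- iso$heats_uJ * 3
  f3 <- fit_binding_isotherm(iso)
  expect_equal(f3$model$dH, 3 * f1$model$dH, tolerance = 1e-4)
  expect_equal(f3$model$Kd, f1$model$Kd, tolerance = 1e-4)
  expect_equal(f3$model$n, f1$model$n, tolerance = 1e-4)
})
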