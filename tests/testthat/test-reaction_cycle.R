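test_that("rate laws match hand-evaluated examples and balance both totals", {
  k <- rate_constants(0.01, 0.002, 0.5, 0.2, 0.1)

  # empty system: nothing moves
  expect_equal(unname(cycle_derivatives(
    c(F = 0, P = 0, I = 0, A = 0, W = 0), k)), rep(0, 5))

  # pure deactivation limb: only anhydride hydrolysis runs
  d <- cycle_derivatives(c(F = 0, P = 0, I = 0, A = 2, W = 0),
                         rate_constants(0.3, 0.1, 1, 1, 0.1))
  expect_equal(unname(d), c(0, 0.2, 0, -0.2, 0))

  # frozen hand evaluation of the five rate laws:
  # act = 0.002*10*20 = 0.4; dF = -0.1-0.4; dP = -0.4+0.2+0.05;
  # dI = 0.4-0.7; dA = 0.5-0.05; dW = 0.1+0.7
  d <- cycle_derivatives(c(F = 10, P = 20, I = 1, A = 0.5, W = 0), k)
  expect_equal(unname(d), c(-0.5, -0.15, -0.3, 0.45, 0.8))

  expect_error(cycle_derivatives(c(F = -1, P = 0, I = 0, A = 0, W = 0), k),
               "negative")

  # both balances close for random states
  set.seed(42)
  for (i in 1:10) {
    st <- c(F = runif(1, 0, 60), P = runif(1, 0, 30), I = runif(1, 0, 5),
            A = runif(1, 0, 8), W = runif(1, 0, 60))
    d <- cycle_derivatives(st, random_constants())
    expect_equal(unname(d["dP"] + d["dI"] + d["dA"]), 0, tolerance = 1e-12)
    expect_equal(unname(d["dF"] + d["dI"] + d["dW"]), 0, tolerance = 1e-12)
  }
})

test_that("without fuel nothing is activated", {
  tc <- simulate_cycle(experiment_config(F0 = 0), default_rate_constants(),
                       t_end = 20)
  expect_true(all(tc$A_mM == 0))
  expect_true(all(abs(tc$P_mM - 23) < 1e-8))
})

test_that("integration conserves both totals and matches a fine-step Euler oracle", {
  set.seed(7)
  grid <- seq(1, 10, length.out = 10)
  for (i in 1:3) {
    k <- random_constants()
    cfg <- experiment_config(F0 = runif(1, 5, 50))
    tc <- simulate_cycle(cfg, k, times = c(0, grid))

    pep <- tc$P_mM + tc$I_mM + tc$A_mM
    carb <- tc$F_mM + tc$I_mM + tc$W_mM
    expect_lt(max(abs(pep - cfg$P0)) / cfg$P0, 1e-6)
    expect_lt(max(abs(carb - cfg$F0)) / cfg$F0, 1e-6)

    eu <- euler_cycle(cfg, k, grid)
    for (col in c("F", "P", "A")) {
      got <- tc[[paste0(col, "_mM")]][-1]
      ref <- eu[[col]]
      expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-3)), 1e-3)
    }
  }
})

test_that("fuel never rises, waste never falls, and more fuel never lowers the peak", {
  set.seed(11)
  for (i in 1:4) {
    k <- random_constants()
    f0 <- runif(1, 5, 30)
    tc <- simulate_cycle(experiment_config(F0 = f0), k, t_end = 40)
    expect_true(all(diff(tc$F_mM) <= 1e-9))
    expect_true(all(diff(tc$W_mM) >= -1e-9))
    pk1 <- peak_anhydride(tc)$A_peak
    pk2 <- peak_anhydride(simulate_cycle(experiment_config(F0 = 2 * f0), k,
                                         t_end = 40))$A_peak
    expect_gte(pk2, pk1 - 1e-9)
  }
})

test_that("with no activation the fuel decays exponentially and no product forms", {
  k <- rate_constants(0.12, 0, 1, 2, 0.1)
  cfg <- experiment_config(F0 = 20)
  tc <- simulate_cycle(cfg, k, t_end = 30)
  expect_true(all(tc$A_mM == 0))
  expect_lt(max(abs(tc$F_mM - 20 * exp(-0.12 * tc$time_min))), 1e-6)
})

test_that("peak location reports the earliest maximum", {
  flat <- trace_tc(seq(0, 10, 0.5), 0)
  expect_equal(peak_anhydride(flat), list(t_peak = 0, A_peak = 0))

  # dense scan of a known unimodal pulse recovers its analytic maximum
  tt <- seq(0, 20, 0.01)
  a <- 0.085; b <- 0.8                    # A ~ exp(-a t) - exp(-b t)
  t_star <- log(b / a) / (b - a)
  pk <- peak_anhydride(trace_tc(tt, exp(-a * tt) - exp(-b * tt)))
  expect_equal(pk$t_peak, t_star, tolerance = 1e-2)
})

test_that("threshold crossings interpolate a piecewise-linear trace exactly", {
  # triangle: rises 0->2 over [0,4], falls 2->0 over [4,8]
  tt <- seq(0, 8, 0.5)
  tri <- trace_tc(tt, ifelse(tt <= 4, tt / 2, (8 - tt) / 2))
  th <- threshold_times(tri, A_crit = 0.5)
  expect_equal(th$t_on, 1)    # 0.5 = t/2
  expect_equal(th$t_off, 7)   # 0.5 = (8-t)/2

  low <- threshold_times(tri, A_crit = 3)
  expect_true(is.na(low$t_on) && is.na(low$t_off))

  never_off <- threshold_times(trace_tc(tt, tt / 4), A_crit = 0.5)
  expect_equal(never_off$t_on, 2)
  expect_true(is.na(never_off$t_off))
})

test_that("depletion time matches the analytic crossing of an exponential decay", {
  tt <- seq(0, 60, 0.01)
  r <- 0.23; C0 <- 25
  tc <- trace_tc(tt, C0 * exp(-r * tt), F = C0 * exp(-r * tt))
  expect_equal(depletion_time(tc, 0.1), log(C0 / 0.1) / r, tolerance = 1e-3)

  expect_equal(depletion_time(
    simulate_cycle(experiment_config(F0 = 0), t_end = 5), 0.1), 0)

  short <- trace_tc(seq(0, 2, 0.1), 5, F = 5)
  expect_warning(res <- depletion_time(short, 0.1), "not depleted")
  expect_true(is.na(res))
})
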