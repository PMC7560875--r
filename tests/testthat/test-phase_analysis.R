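k_std <- default_rate_constants()

test_that("the critical concentration is the peak product at the onset fuel", {
  expect_identical(critical_concentration(0), 0)

  # with no deactivation and no direct hydrolysis, all fuel funnels through
  # the intermediate, so the asymptotic product is F0 * k2/(k2+k3):
  # the carbodiimide balance in closed form
  k <- rate_constants(0, 0.04, 1.5, 4.5, 0)
  a_inf <- critical_concentration(2, k = k, t_end = 120)
  expect_equal(a_inf, 2 * 1.5 / 6, tolerance = 1e-4)
})

test_that("the fuel scan finds the onset and is monotone in the threshold", {
  expect_identical(fuel_threshold_scan(A_crit = 0, resolution = 0.5), 0.5)

  ths <- vapply(c(0.3, 0.6, 0.9, 1.2), function(ac)
    fuel_threshold_scan(k = k_std, A_crit = ac, resolution = 0.5),
    numeric(1))
  expect_true(all(diff(ths) >= 0))

  # scan/threshold consistency: the returned fuel reaches at least A_crit
  for (ac in c(0.5, 0.9)) {
    f <- fuel_threshold_scan(k = k_std, A_crit = ac, resolution = 0.5)
    expect_gte(critical_concentration(f, k = k_std), ac)
  }

  expect_warning(
    res <- fuel_threshold_scan(k = k_std, A_crit = 50, resolution = 1,
                               fuel_max = 30),
    "never reaches")
  expect_true(is.na(res))
})

test_that("conditions map onto the observed phase regimes", {
  expect_identical(classify_regime(5, 4.1), "no_droplets")
  expect_identical(classify_regime(25, 4.1), "dynamic")
  expect_identical(classify_regime(60, 4.1), "metastable")
  expect_identical(classify_regime(25, 1.4), "metastable")
})

test_that("regime labels are exhaustive and ordered along the fuel axis", {
  order_of <- c(no_droplets = 1L, dynamic = 2L, metastable = 3L)
  for (u in c(0.5, 1.4, 2.7, 4.1, 6)) {
    labs <- vapply(seq(0, 70, by = 2.5), classify_regime, character(1), U0 = u)
    expect_true(all(labs %in% names(order_of)))
    expect_true(all(diff(order_of[labs]) >= 0))
  }
})

test_that("the two-phase mass balance reconstructs the total exactly", {
  set.seed(3)
  for (i in 1:20) {
    total <- runif(1, 0.5, 8)
    phi <- runif(1, 1e-4, 0.05)
    filt <- runif(1, 0, total)
    mb <- mass_balance(total, filt, phi)
    recon <- mb$outer_mM * (1 - phi) + mb$in_droplet_M * phi * 1000
    expect_equal(recon, total, tolerance = 1e-9)
  }
})

test_that("mass-balance edge cases behave", {
  mb <- mass_balance(3, 3, 0.001)
  expect_lt(mb$droplet_mM, 0.01)  # nothing partitioned beyond the pellet volume

  expect_warning(mb2 <- mass_balance(1, 2, 0.001), "clamp")
  expect_identical(mb2$droplet_mM, 0)
  expect_true(mb2$clamped)

  expect_error(mass_balance(1, 0.5, 0), "between 0 and 1")
  expect_error(mass_balance(1, 0.5, 1), "between 0 and 1")
})

test_that("the charge ratio is linear in product and excludes the precursor by default", {
  expect_identical(charge_ratio(0, 4.1), 0)
  r1 <- charge_ratio(1.2, 3.69)
  expect_equal(charge_ratio(2.4, 3.69), 2 * r1)
  expect_equal(r1, 3 * 1.2 / 3.69)
  expect_error(charge_ratio(1, 0), "> 0")
  with_prec <- charge_ratio(1.2, 3.69,
                            charge_model(include_precursor = TRUE),
                            precursor_mM = 2)
  expect_equal(with_prec, (3 * 1.2 + 2) / 3.69)
})

test_that("turbidity lifetime is the last drop below the cutoff", {
  expect_true(is.na(turbidity_lifetime(turbidity_trace(0:30, rep(0, 31)))))

  # square pulse on over minutes 1..8, off at 9
  pulse <- turbidity_trace(0:12, c(0, rep(0.5, 8), rep(0, 4)))
  expect_equal(turbidity_lifetime(pulse), 9, tolerance = 0.05)

  tc60 <- simulate_cycle(experiment_config(F0 = 60), k_std, t_end = 90)
  meta <- synth_turbidity(tc60, turbidity_model(regime = "metastable",
                                                persistence_min = 76),
                          noise_spec(0, 0, 1))
  expect_equal(turbidity_lifetime(meta), 76, tolerance = 1.5)
})
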