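triangle_trace <- function(n_cycles = 10, peak = 80, de = 0.5,
                           stress_fun = function(e) e / 40) {
  up <- seq(0, peak, by = de)
  cyc <- c(up, rev(up)[-1])
  strain <- c(cyc, rep(cyc[-1], n_cycles - 1))
  time <- seq_along(strain) * 0.05
  force <- stress_fun(strain) * 10 / 1000  # area 10 mm^2
  mech_trace(time, strain, force)
}

test_that("nominal stress is force over initial area, in kPa", {
  tr <- mech_trace(1:3, c(0, 10, 20), c(0, 0.005, 0.01))
  g <- section_geometry(10)
  expect_equal(to_nominal_stress(tr, g), c(0, 0.5, 1.0))

  # zero force maps to zero stress
  tr0 <- mech_trace(1:3, c(0, 10, 20), c(0, 0, 0))
  expect_equal(to_nominal_stress(tr0, g), c(0, 0, 0))

  # round trip recovers force
  set.seed(2)
  f <- runif(50)
  trr <- mech_trace(1:50, seq(0, 49), f)
  s <- to_nominal_stress(trr, section_geometry(13.7))
  expect_equal(s * 13.7 / 1000, f, tolerance = 1e-12)

  expect_error(section_geometry(0), "positive")
})

test_that("cycle segmentation splits a clean cyclic trace", {
  tr <- triangle_trace()
  stress <- to_nominal_stress(tr, section_geometry(10))
  cycles <- segment_cycles(tr, stress, expected_cycles = 10)
  expect_length(cycles, 10)
  for (cy in cycles) {
    expect_true(all(diff(cy$loading$strain_pct) >= 0))
    expect_true(all(diff(cy$unloading$strain_pct) <= 0))
    # branches share the peak sample
    expect_equal(cy$loading$strain_pct[nrow(cy$loading)],
                 cy$unloading$strain_pct[1])
    expect_equal(max(cy$loading$strain_pct), 80)
  }
})

test_that("segmentation errors on missing excursions", {
  flat <- mech_trace(1:100, rep(1, 100), rep(0, 100))
  expect_error(segment_cycles(flat, rep(0, 100), 10), "0 cycle")
  tr3 <- triangle_trace(n_cycles = 3)
  s3 <- to_nominal_stress(tr3, section_geometry(10))
  expect_error(segment_cycles(tr3, s3, 10), "3 cycle")
})

test_that("peak detection matches the per-period argmax oracle under noise", {
  set.seed(31)
  gen <- generate_mech_trace(
    list(low_strain_stiffness = 2, high_strain_stiffness = 100,
         hysteresis_loss = 50, plastic_strain = 30),
    strain_noise_pct = 0.2, seed = 99)
  tr <- gen$trace
  samples_per_period <- (length(tr$strain_pct) - 1) / 10
  oracle_peaks <- argmax_per_period_oracle(tr$strain_pct,
                                           samples_per_period, 10)
  detected <- clotsim:::find_strain_peaks(tr$strain_pct, prominence = 5)
  expect_length(detected, 10)
  # same excursions: within a tiny fraction of a period of the oracle
  expect_true(all(abs(detected - oracle_peaks) <= samples_per_period * 0.01))
})

test_that("secant modulus reproduces analytic window slopes", {
  tr <- triangle_trace(stress_fun = function(e) 2.0 * (e / 100))
  stress <- to_nominal_stress(tr, section_geometry(10))
  c1 <- segment_cycles(tr, stress, 10)[[1]]
  expect_equal(secant_modulus(c1, c(0, 10)), 2.0, tolerance = 1e-9)
  expect_equal(secant_modulus(c1, c(75, 80)), 2.0, tolerance = 1e-9)

  # zero stress
  c0 <- segment_cycles(tr, stress * 0, 10)[[1]]
  expect_equal(secant_modulus(c0, c(0, 10)), 0)

  # quintic loading: closed-form OLS slope from analytic moments
  a_coef <- 1; b_coef <- 100
  trq <- triangle_trace(de = 0.1,
                        stress_fun = function(e) a_coef * (e / 100) +
                          b_coef * (e / 100)^5)
  sq <- to_nominal_stress(trq, section_geometry(10))
  cq <- segment_cycles(trq, sq, 10)[[1]]
  for (w in list(c(0, 10), c(75, 80))) {
    expect_equal(secant_modulus(cq, w),
                 poly_window_slope_oracle(a_coef, b_coef,
                                          w[1] / 100, w[2] / 100),
                 tolerance = 0.005)
  }
  expect_error(secant_modulus(cq, c(40, 40.001)), "window")
})

make_cycle <- function(load_fun, unload_fun, n = 1001) {
  eps_up <- seq(0, 100, length.out = n)
  eps_dn <- rev(eps_up)
  structure(list(cycle_index = 1L,
                 loading = data.frame(strain_pct = eps_up,
                                      stress_kpa = load_fun(eps_up / 100)),
                 unloading = data.frame(strain_pct = eps_dn,
                                        stress_kpa = unload_fun(eps_dn / 100))),
            class = "cycle_branch")
}

test_that("hysteresis loss handles the limiting cases", {
  rev_cycle <- make_cycle(function(e) e, function(e) e)
  expect_equal(hysteresis_loss(rev_cycle), 0, tolerance = 1e-12)

  dissip <- make_cycle(function(e) e, function(e) 0 * e)
  expect_equal(hysteresis_loss(dissip), 100, tolerance = 1e-12)

  zero <- make_cycle(function(e) 0 * e, function(e) 0 * e)
  expect_error(hysteresis_loss(zero), "loading energy")
})

test_that("hysteresis is invariant to stress rescaling; stiffness scales", {
  set.seed(5)
  ft <- list(low_strain_stiffness = 3, high_strain_stiffness = 60,
             hysteresis_loss = 40, plastic_strain = 20)
  g1 <- generate_mech_trace(ft, section_geometry(20))
  g2 <- g1
  g2$trace$force_N <- g2$trace$force_N * 2
  f1 <- extract_mech_features(g1$trace, g1$geometry)
  f2 <- extract_mech_features(g2$trace, g2$geometry)
  expect_equal(f2$low_strain_stiffness, 2 * f1$low_strain_stiffness)
  expect_equal(f2$high_strain_stiffness, 2 * f1$high_strain_stiffness)
  expect_equal(f2$hysteresis_loss, f1$hysteresis_loss, tolerance = 1e-9)
})

test_that("plastic strain finds the baseline return by interpolation", {
  # reversible elastic cycle returns to zero strain at zero stress
  elastic <- make_cycle(function(e) 2 * e, function(e) 2 * e)
  expect_equal(as.numeric(plastic_strain(elastic, baseline_tol = 0)), 0)

  # linear unloading from peak stress to zero at 30% strain
  lin <- make_cycle(function(e) e,
                    function(e) pmax(e - 0.30, 0) / (1 - 0.30))
  expect_equal(as.numeric(plastic_strain(lin, baseline_tol = 0)), 30,
               tolerance = 1e-6)

  # stress never returns to baseline -> min strain with flag
  stuck <- make_cycle(function(e) e + 1, function(e) e + 1)
  ps <- plastic_strain(stuck, baseline_tol = 0.01)
  expect_equal(as.numeric(ps), 0)
  expect_true(attr(ps, "no_return"))
})

test_that("refining the sampling reduces extraction error", {
  ft <- list(low_strain_stiffness = 2, high_strain_stiffness = 150,
             hysteresis_loss = 55, plastic_strain = 35)
  errs <- vapply(c(1, 0.4, 0.1), function(de) {
    g <- generate_mech_trace(ft, delta_eps_pct = de)
    fe <- extract_mech_features(g$trace, g$geometry, baseline_tol = 0)
    max(abs(fe$low_strain_stiffness - ft$low_strain_stiffness) / ft$low_strain_stiffness,
        abs(fe$high_strain_stiffness - ft$high_strain_stiffness) / ft$high_strain_stiffness,
        abs(fe$hysteresis_loss - ft$hysteresis_loss) / ft$hysteresis_loss,
        abs(fe$plastic_strain - ft$plastic_strain) / ft$plastic_strain)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
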