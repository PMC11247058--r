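test_that("cohort generation is deterministic and sized by feasibility", {
  c1 <- generate_cohort(seed = 42)
  c2 <- generate_cohort(seed = 42)
  expect_identical(c1, c2)
  c3 <- generate_cohort(seed = 43)
  expect_false(identical(c1$ncct_density, c3$ncct_density))

  # 6 donors x 15 recipes minus the recipes the dilute-PRP donors cannot
  # reach leaves 87 clots with the default panel and design
  expect_equal(nrow(c1), 87)
  expect_equal(length(unique(c1$donor_id)), 6)
  expect_s3_class(c1, "clot_cohort")
  expect_s3_class(attr(c1, "truth"), "generative_truth")
  expect_false(any(duplicated(c1$clot_id)))
})

test_that("realized contents span the design's composition range", {
  cohort <- generate_cohort(seed = 1)
  expect_lt(min(cohort$rbc_content), 1)
  expect_gt(max(cohort$rbc_content), 90)
  expect_lt(min(cohort$platelet_content), 1)
  expect_gt(max(cohort$platelet_content), 60)
  expect_true(all(cohort$rbc_content + cohort$platelet_content <= 100))
  expect_true(all(cohort$retained_fraction > 0 &
                    cohort$retained_fraction <= 1))
  expect_true(all(cohort$diameter_mm > 0 & cohort$diameter_mm < 9))
})

test_that("contraction is monotone in platelet concentration", {
  cc <- simulate_contraction(c(30, 90, 270), 0.05)
  expect_true(all(diff(cc$retained_fraction) < 0))
  expect_true(all(diff(cc$rbc_content) > 0))   # RBCs concentrate
  # no platelets, no contraction: the full volume is retained
  cc0 <- simulate_contraction(0, 0.05)
  expect_equal(cc0$retained_fraction, 1, tolerance = 1e-12)
  expect_equal(cc0$platelet_content, 0)
  expect_equal(cc0$rbc_content, 5, tolerance = 1e-12)
})

test_that("zero-noise observables follow the truth lines exactly", {
  tr <- generative_truth()
  tr$ncct$sd <- 0; tr$cect$sd <- 0
  for (f in names(tr$mech)) tr$mech[[f]]$sd <- 0
  tr$contraction$jitter_sd <- 0
  cohort <- generate_cohort(tr, seed = 5)
  expect_equal(cohort$ncct_density,
               tr$ncct$beta0 + tr$ncct$beta_rbc * cohort$rbc_content +
                 tr$ncct$beta_plt * cohort$platelet_content,
               tolerance = 1e-12)
  expect_equal(cohort$cect_increase,
               tr$cect$gamma0 + tr$cect$gamma_plt * cohort$platelet_content +
                 tr$cect$gamma_diameter * cohort$diameter_mm,
               tolerance = 1e-12)
  m <- tr$mech$hysteresis_loss
  expect_equal(cohort$hysteresis_loss,
               m$beta0 + m$beta_rbc * cohort$rbc_content +
                 m$beta_plt * cohort$platelet_content,
               tolerance = 1e-12)
})

test_that("loading-curve solver inverts the window-slope relations", {
  ab <- solve_loading_curve(2, 120)
  expect_gt(ab$A, 0)
  expect_gt(ab$B, 0)
  expect_equal(poly_window_slope_oracle(ab$A, ab$B, 0, 0.10), 2,
               tolerance = 1e-9)
  expect_equal(poly_window_slope_oracle(ab$A, ab$B, 0.75, 0.80), 120,
               tolerance = 1e-9)
  # high < low would need B < 0
  expect_error(solve_loading_curve(10, 1), "infeasible")
})

test_that("generated traces have the closed-form geometry they claim", {
  ft <- list(low_strain_stiffness = 2, high_strain_stiffness = 120,
             hysteresis_loss = 55, plastic_strain = 30)
  gen <- generate_mech_trace(ft, section_geometry(20), delta_eps_pct = 0.05)
  an <- gen$analytic
  # peak stress and strain
  stress <- to_nominal_stress(gen$trace, gen$geometry)
  expect_equal(max(gen$trace$strain_pct), 80)
  expect_equal(max(stress), an$sigma_max, tolerance = 1e-9)
  # strain rate 10%/s: full cycle of 160% strain takes 16 s
  expect_equal(diff(an$peak_times)[1], 16, tolerance = 1e-9)
  # later cycles are softened copies: peak stress scales by 0.95 per cycle
  cyc <- segment_cycles(gen$trace, stress, 10)
  peaks <- vapply(cyc, function(cy) max(cy$loading$stress_kpa), numeric(1))
  expect_equal(peaks / peaks[1], 0.95^(0:9), tolerance = 1e-9)
  # hysteresis ratio is softening-invariant cycle to cycle
  h <- vapply(cyc, hysteresis_loss, numeric(1))
  expect_equal(h, rep(h[1], 10), tolerance = 1e-6)

  # infeasible requests are refused with explanation
  expect_error(generate_mech_trace(
    list(low_strain_stiffness = 2, high_strain_stiffness = 120,
         hysteresis_loss = 105, plastic_strain = 30)), "infeasible")
  expect_error(generate_mech_trace(
    list(low_strain_stiffness = 2, high_strain_stiffness = 120,
         hysteresis_loss = 55, plastic_strain = 85)), "infeasible")
  expect_error(generate_mech_trace(
    list(low_strain_stiffness = 2, high_strain_stiffness = 120,
         hysteresis_loss = 5, plastic_strain = 70)), "q = ")
})

test_that("analytic return strain reduces to eps_p at zero tolerance", {
  ft <- list(low_strain_stiffness = 2, high_strain_stiffness = 120,
             hysteresis_loss = 55, plastic_strain = 30)
  gen <- generate_mech_trace(ft)
  expect_equal(analytic_return_strain(gen$analytic, 0), 30)
  # finite tolerance crosses above eps_p, below peak strain
  r <- analytic_return_strain(gen$analytic, 0.01)
  expect_gt(r, 30)
  expect_lt(r, 80)
  # tolerance above the peak stress saturates at the peak strain
  expect_equal(analytic_return_strain(gen$analytic,
                                      gen$analytic$sigma_max * 2), 80)
})

test_that("trace noise is reproducible and confined to the channels", {
  ft <- list(low_strain_stiffness = 2, high_strain_stiffness = 120,
             hysteresis_loss = 55, plastic_strain = 30)
  g1 <- generate_mech_trace(ft, strain_noise_pct = 0.2,
                            stress_noise_kpa = 0.05, seed = 8)
  g2 <- generate_mech_trace(ft, strain_noise_pct = 0.2,
                            stress_noise_kpa = 0.05, seed = 8)
  expect_identical(g1$trace, g2$trace)
  g0 <- generate_mech_trace(ft)
  expect_false(identical(g1$trace$strain_pct, g0$trace$strain_pct))
  expect_identical(g1$analytic[names(g0$analytic)], g0$analytic)
})

test_that("phantom generation is deterministic and media is contrasted", {
  p1 <- generate_ct_phantom(40, 12, 5, noise_sd = 3, seed = 2)
  p2 <- generate_ct_phantom(40, 12, 5, noise_sd = 3, seed = 2)
  expect_identical(p1, p2)
  p0 <- generate_ct_phantom(40, 12, 5, noise_sd = 0)
  expect_equal(unique(p0$ncct$hu[!p0$ncct$clot_mask]), 10)
  expect_equal(unique(p0$cect$hu[!p0$cect$clot_mask]), 260)
  expect_equal(unique(p0$cect$hu[p0$cect$clot_mask]), 52)
})

test_that("label-mask generation is deterministic per seed", {
  m1 <- generate_label_mask(40, 15, style = "blob", seed = 4)
  m2 <- generate_label_mask(40, 15, style = "blob", seed = 4)
  expect_identical(m1, m2)
  m3 <- generate_label_mask(40, 15, style = "blob", seed = 5)
  expect_false(identical(m1$msb$labels, m3$msb$labels))
})

test_that("parameter recovery table is complete and seeded", {
  tr <- generative_truth()
  rec <- recover_truth(tr, n_replicates = 5, seed = 3)
  expect_equal(nrow(rec), 12)  # 6 outcomes x 2 slope coefficients
  expect_setequal(unique(rec$outcome),
                  c("ncct_density", "cect_increase", "low_strain_stiffness",
                    "high_strain_stiffness", "hysteresis_loss",
                    "plastic_strain"))
  expect_true(all(rec$coverage_pct >= 0 & rec$coverage_pct <= 100))
  expect_equal(rec$bias, rec$mean_estimate - rec$true_beta)
  rec2 <- recover_truth(tr, n_replicates = 5, seed = 3)
  expect_identical(rec, rec2)
})
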