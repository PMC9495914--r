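test_that("liver phantom is reproducible with a plausible area fraction", {
  ph <- make_liver_phantom(96, seed = 3)
  expect_true(any(ph$liver))
  expect_false(any(ph$liver & ph$background))
  frac <- mean(ph$liver)
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
  ph2 <- make_liver_phantom(96, seed = 3)
  expect_identical(ph$liver, ph2$liver)
  expect_identical(ph$baseline, ph2$baseline)
  expect_false(identical(ph$liver, make_liver_phantom(96, seed = 4)$liver))
  expect_error(make_liver_phantom(8), ">= 16")
})

test_that("uptake kinetics are zero pre-injection and peak on schedule", {
  m <- uptake_model(spike_amplitude_mtr = 0.01, spike_peak_delay_min = 7,
                    accumulation_slope_mtr_per_min = 0)
  expect_equal(uptake_mtr_at(c(0, 10, 22.9), m), c(0, 0, 0))
  tt <- seq(0, 120, by = 0.05)
  v <- uptake_mtr_at(tt, m)
  expect_equal(tt[which.max(v)], 23 + 7)
  expect_equal(max(v), 0.01, tolerance = 1e-6)
  expect_equal(uptake_mtr_at(seq(0, 120, 5), control_uptake_model()),
               rep(0, 25))
  # continuity at the injection time
  expect_lt(uptake_mtr_at(23 + 1e-6, m), 1e-8)
})

test_that("fraction calibration inverts the MTR response", {
  f <- fx_field()
  cal <- calibrate_uptake(fx_three_pool(), f, b1_uT = 0.7, max_mtr = 0.02)
  z0 <- steady_state_cw(fx_three_pool(), -2.7, 0.7, f)
  for (target in c(0.002, 0.0064, 0.015)) {
    df <- cal(target)
    pools <- fx_three_pool()
    pools[[2]]$fraction <- pools[[2]]$fraction + df
    expect_equal(z0 - steady_state_cw(pools, -2.7, 0.7, f), target,
                 tolerance = 1e-4)
  }
  expect_equal(cal(0), 0)
})

test_that("identical seed and config give a bit-identical dataset", {
  s1 <- fx_series(n_cycles = 3, grid = 24, sigma = 0.005, seed = 11)
  s2 <- fx_series(n_cycles = 3, grid = 24, sigma = 0.005, seed = 11)
  expect_identical(s1$images, s2$images)
  s3 <- fx_series(n_cycles = 3, grid = 24, sigma = 0.005, seed = 12)
  expect_false(identical(s1$images, s3$images))
})

test_that("background magnitude noise has the Rician floor", {
  s <- fx_series(n_cycles = 6, grid = 32, sigma = 0.01, seed = 2)
  bg <- s$images[rep(s$masks$background, dim(s$images)[3])]
  ph <- make_liver_phantom(32, 7)
  sigma_abs <- 0.01 * mean(ph$baseline[ph$liver])
  expect_equal(mean(bg), sigma_abs * sqrt(pi / 2), tolerance = 0.02)
})

test_that("noiseless artifact-free series is static before and after the pipeline", {
  s <- fx_series(n_cycles = 20, grid = 20,
                 uptake = control_uptake_model())
  gt <- s$ground_truth
  expect_equal(gt$mtr_true, rep(0, nrow(gt)), tolerance = 1e-12)
  cv <- dynamic_mtr_curves(s)[["-2.7"]]
  expect_equal(cv$mtr, rep(0, length(cv$mtr)), tolerance = 1e-12)
})

test_that("generator demands a matching uptake pool", {
  sched <- build_fl1(n_cycles = 2)
  expect_error(generate_series(sched, pools = list(water_pool()), grid = 20),
               "pool named")
})

test_that("injected B0 drift is recovered by the DWS fit", {
  # full +/-5 ppm sweep rendered with a constant-equivalent drift
  offs <- build_full_zspec_list()
  f_drift <- field_params()
  sched <- build_partial_list(-5, 5, n_offsets = 51, n_cycles = 1)
  art <- artifact_model(drift_hz_per_min = 2)   # ~0.07 ppm over the sweep mid
  s <- generate_series(sched, uptake = control_uptake_model(),
                       artifacts = art, noise = noise_model(sigma_frac = 0),
                       pools = list(water_pool()), uptake_pool = "water",
                       uptake_offset_ppm = 0, render = "pixel", grid = 16,
                       phantom_seed = 5)
  zc <- zspectra_from_series(s)
  bm <- b0_map(zc, mask = s$masks$liver)
  # expected shift: mean drift (in ppm) over the retained measure entries
  e <- s$entries
  keep <- e$retain & e$role == "measure"
  drift_ppm <- 2 * (e$t_mid_s[keep] / 60) / hz_per_ppm(f_drift)
  expect_equal(mean(bm$shift_ppm[s$masks$liver]), mean(drift_ppm),
               tolerance = 0.01 / mean(drift_ppm))
})
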