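lorentzian_z <- function(offs, center, fwhm, depth, baseline)
  baseline - depth * (fwhm / 2)^2 / ((fwhm / 2)^2 + (offs - center)^2)

test_that("DWS fit recovers its own model exactly without noise", {
  offs <- build_full_zspec_list()
  zs <- structure(list(offsets_ppm = offs,
                       z = lorentzian_z(offs, 0, 1.4, 0.85, 0.98),
                       reference_offset_ppm = 333), class = "zspectrum")
  ft <- fit_dws(zs)
  expect_true(ft$ok)
  expect_equal(ft$center_ppm, 0, tolerance = 1e-6)
  expect_equal(ft$fwhm_ppm, 1.4, tolerance = 1e-6)
  expect_equal(ft$depth, 0.85, tolerance = 1e-6)
  expect_equal(ft$baseline, 0.98, tolerance = 1e-6)
  expect_lt(ft$residual_rms, 1e-8)
})

test_that("shifted dips are recovered within 0.01 ppm under 1% noise", {
  offs <- build_full_zspec_list()
  set.seed(9)
  for (d in c(-0.1, 0.1)) {
    z0 <- lorentzian_z(offs, d, 1.4, 0.85, 0.99)
    centers <- replicate(40, {
      zs <- structure(list(offsets_ppm = offs,
                           z = z0 + rnorm(length(offs), 0, 0.01),
                           reference_offset_ppm = 333), class = "zspectrum")
      fit_dws(zs)$center_ppm
    })
    expect_equal(mean(centers), d, tolerance = 0.01 / abs(d))
  }
})

test_that("flat spectra and degenerate inputs are flagged, not raised", {
  offs <- build_full_zspec_list()
  flat <- structure(list(offsets_ppm = offs, z = rep(0.99, length(offs)),
                         reference_offset_ppm = 333), class = "zspectrum")
  ft <- fit_dws(flat)
  expect_false(ft$ok)
  expect_true(is.na(ft$center_ppm))
  tiny <- structure(list(offsets_ppm = offs[1:3], z = rep(1, 3),
                         reference_offset_ppm = 333), class = "zspectrum")
  expect_error(fit_dws(tiny), "at least 5")
})

test_that("B0 maps are shift-equivariant and flag hopeless pixels", {
  offs <- build_full_zspec_list()
  g <- 4
  mk_cube <- function(shift) {
    z <- lorentzian_z(offs, shift, 1.4, 0.85, 0.99)
    array(rep(z, each = g * g), dim = c(g, g, length(offs)))
  }
  m0 <- b0_map(mk_cube(0), offs)
  m1 <- b0_map(mk_cube(0.25), offs)
  expect_equal(mean(m1$shift_ppm) - mean(m0$shift_ppm), 0.25,
               tolerance = 1e-5)
  flat <- array(0.99, dim = c(g, g, length(offs)))
  expect_warning(mf <- b0_map(flat, offs), "flagged")
  expect_equal(mf$frac_flagged, 1)
})

test_that("partial maps have sweep structure and a null control map", {
  sched <- build_partial_list(-4.3, -1.1, n_cycles = 8)
  ctrl <- generate_group(2, schedule = sched,
                         uptake = control_uptake_model(),
                         noise = noise_model(sigma_frac = 0), render = "roi")
  pm <- partial_map(ctrl)
  expect_equal(pm$offsets_ppm, c(-4.3, -3.5, -2.7, -1.9, -1.1))
  expect_equal(dim(pm$mtr_avg), c(5, 8))
  expect_equal(max(abs(pm$mtr_avg)), 0, tolerance = 1e-12)
  prof <- partial_profile(pm, 30)
  expect_equal(nrow(prof), 5)

  # a longer schedule that actually covers the post-injection spike
  sched_long <- build_partial_list(-4.3, -1.1, n_cycles = 20)
  test_grp <- generate_group(2, schedule = sched_long,
                             noise = noise_model(sigma_frac = 0),
                             render = "roi")
  pm_t <- partial_map(test_grp)
  j <- which.min(abs(pm_t$times_min - 30))
  expect_equal(pm_t$offsets_ppm[which.max(pm_t$mtr_avg[, j])], -2.7)

  bad <- ctrl
  bad[[2]]$entries$offset_ppm[20] <- 0.5
  expect_error(partial_map(bad), "share the schedule")
})
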