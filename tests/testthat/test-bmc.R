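test_that("exchange matrix has the expected Bloch-McConnell structure", {
  f <- fx_field()
  sys <- build_exchange_matrix(fx_two_pool(), -2.7, 1.2, f)
  expect_equal(dim(sys$A), c(6, 6))
  w <- fx_water(); th <- fx_thiol()
  kb <- th$fraction * th$k_exch_per_s
  # diagonals carry -(1/T2 + k); off-diagonal exchange blocks carry +k
  expect_equal(sys$A[1, 1], -(1 / w$T2_s + kb))
  expect_equal(sys$A[4, 4], -(1 / th$T2_s + th$k_exch_per_s))
  expect_equal(sys$A[1, 4], th$k_exch_per_s)
  expect_equal(sys$A[4, 1], kb)             # detailed balance: f * k
  expect_equal(sys$b, c(0, 0, 1 / w$T1_s, 0, 0, th$fraction / th$T1_s))
})

test_that("zero-fraction solute decouples water from exchange", {
  f <- fx_field()
  sys2 <- build_exchange_matrix(list(fx_water(), fx_thiol(fraction = 0)),
                                -2.7, 1.2, f)
  sys1 <- build_exchange_matrix(list(fx_water()), -2.7, 1.2, f)
  expect_equal(sys2$A[1:3, 1:3], sys1$A)
  expect_equal(steady_state_cw(list(fx_water(), fx_thiol(fraction = 0)),
                               -2.7, 1.2, f),
               steady_state_cw(list(fx_water()), -2.7, 1.2, f))
})

test_that("exchange terms conserve longitudinal magnetization flow", {
  f <- fx_field()
  with_k <- build_exchange_matrix(fx_two_pool(), 1, 0, f)$A
  no_k <- build_exchange_matrix(list(fx_water(), fx_thiol(k = 0)), 1, 0, f)$A
  K <- with_k - no_k                      # pure exchange contribution
  zi <- c(3, 6)
  expect_equal(colSums(K[zi, zi]), c(0, 0))  # what leaves one pool enters the other
})

test_that("matrix construction rejects invalid pool sets", {
  f <- fx_field()
  expect_error(build_exchange_matrix(list(fx_thiol()), 0, 1, f), "water")
  expect_error(build_exchange_matrix(list(fx_water(), fx_water()), 0, 1, f),
               "more than one water")
  bad_w <- cest_pool("water", 0, 1.4, 0.03, fraction = 0.5, k_exch_per_s = 0)
  expect_error(build_exchange_matrix(list(bad_w), 0, 1, f), "fraction = 1")
})

test_that("CW steady state matches the closed-form single-pool solution", {
  f <- fx_field(); w <- fx_water()
  for (off in c(-2.7, -0.5, 0, 1.3, 333)) {
    expect_equal(steady_state_cw(list(w), off, 1.2, f),
                 single_pool_ss(w, off, 1.2, f), tolerance = 1e-12)
  }
  expect_equal(steady_state_cw(list(w), 0.5, 0, f), 1)   # b1 = 0
  expect_equal(steady_state_cw(list(w), 333, 1.2, f), 1, tolerance = 1e-3)
})

test_that("adding an exchanging solute only removes water signal", {
  f <- fx_field()
  offs <- seq(-5, 5, by = 0.5)
  z1 <- steady_state_cw(list(fx_water()), offs, 1.2, f)
  z2 <- steady_state_cw(fx_two_pool(), offs, 1.2, f)
  # holds wherever water is not already almost fully saturated; at the DWS
  # centre back-exchange from the less-saturated solute can return a few
  # ppm of water signal
  unsat <- z1 > 0.01
  expect_true(all(z2[unsat] <= z1[unsat] + 1e-12))
  i <- which.min(abs(offs + 2.7))
  expect_lt(z2[i], z1[i])
  expect_true(all(z1 >= 0 & z1 <= 1))
  expect_true(all(z2 >= 0 & z2 <= 1))
})

test_that("pulse train in the CW limit converges to the analytic fixed point", {
  f <- fx_field()
  tr <- sat_train(sat_pulse("cw", 1.2, 0.03), n_pulses = 1500,
                  interpulse_delay_s = 0)
  z_train <- simulate_pulse_train(fx_two_pool(), tr, -2.7, f)
  z_ss <- steady_state_cw(fx_two_pool(), -2.7, 1.2, f)
  expect_lt(abs(z_train - z_ss), 1e-6)
})

test_that("pulse train handles trivial and degenerate inputs", {
  f <- fx_field()
  tr <- default_train()
  expect_error(simulate_pulse_train(fx_two_pool(), tr, 0, f, substep_s = 1),
               "substep")
  # fraction-0 solutes, far off resonance: nothing saturates
  pools0 <- list(fx_water(), fx_thiol(fraction = 0), fx_amide(fraction = 0))
  z <- simulate_pulse_train(pools0, tr, 333, f)
  expect_equal(z, 1, tolerance = 1e-3)
})

test_that("sub-step refinement has converged at the default setting", {
  f <- fx_field()
  tr <- sat_train(sat_pulse("gaussian", 1.2, 0.03), n_pulses = 20,
                  interpulse_delay_s = 0.01041)
  z1 <- simulate_pulse_train(fx_two_pool(), tr, -2.7, f, substep_s = 1e-4)
  z2 <- simulate_pulse_train(fx_two_pool(), tr, -2.7, f, substep_s = 5e-5)
  expect_lt(abs(z1 - z2), 1e-6)
})

test_that("Z-spectrum of an exchange-free single pool is even in offset", {
  f <- fx_field()
  offs <- build_full_zspec_list(3, 0.5)
  tr <- default_train()
  zs <- zspectrum(list(fx_water()), offs, tr, f, method = "cw_steady")
  expect_equal(zs$z, rev(zs$z), tolerance = 1e-12)
  expect_error(zspectrum(list(fx_water()), numeric(0), tr, f), "non-empty")
})

test_that("thiol asymmetry and MTR profile behave as expected", {
  f <- fx_field()
  offs <- build_full_zspec_list(5, 0.2)
  expect_length(offs, 51)
  tr <- default_train()
  z_with <- zspectrum(fx_two_pool(), offs, tr, f, method = "cw_steady")
  z_without <- zspectrum(list(fx_water()), offs, tr, f, method = "cw_steady")
  # upfield window around -2.7 dips deeper than its downfield mirror
  up <- offs >= -3.3 & offs <= -2.1
  down <- offs >= 2.1 & offs <= 3.3
  expect_lt(min(z_with$z[up]), min(z_with$z[down]))
  prof <- mtr_profile(z_with, z_without)
  # broad peak centred on the thiol resonance (grid resolution 0.2 ppm)
  expect_lt(abs(prof$offsets_ppm[which.max(prof$mtr)] - (-2.7)), 0.2)
  expect_equal(mtr_profile(z_with, z_with)$mtr, rep(0, 51))
  z_bad <- zspectrum(fx_two_pool(), offs + 1, tr, f, method = "cw_steady")
  expect_error(mtr_profile(z_with, z_bad), "grids differ")
})

test_that("MTR at the solute resonance grows monotonically with fraction", {
  f <- fx_field()
  fr <- c(2e-4, 5e-4, 1e-3, 2e-3)
  z0 <- steady_state_cw(list(fx_water()), -2.7, 1.2, f)
  mtr <- vapply(fr, function(x)
    z0 - steady_state_cw(list(fx_water(), fx_thiol(fraction = x)),
                         -2.7, 1.2, f), 0)
  expect_true(all(diff(mtr) > 0))
})
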