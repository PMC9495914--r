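test_that("Savitzky-Golay window 3 / order 2 is the identity transform", {
  set.seed(1)
  x <- rnorm(40)
  expect_equal(sg_filter(x, 3, 2), x, tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces polynomials up to its order", {
  t <- 1:30
  q <- 2 + 0.3 * t - 0.01 * t^2
  expect_equal(sg_filter(q, 7, 2), q, tolerance = 1e-9)
  expect_equal(sg_filter(rep(5, 20), 5, 2), rep(5, 20), tolerance = 1e-12)
  expect_error(sg_filter(q, 4, 2), "odd")
  expect_error(sg_filter(q, 3, 3), "order")
  expect_error(sg_filter(1:2, 3, 2), "at least")
})

test_that("S0 baseline follows constant and linearly drifting signals", {
  s <- fx_series(n_cycles = 15, grid = 20, uptake = control_uptake_model())
  b <- build_s0_baseline(s)
  expect_equal(length(b$s0_sg), nrow(s$entries))
  expect_equal(diff(range(b$s0_sg)), 0, tolerance = 1e-10)  # constant signal

  s2 <- fx_series(n_cycles = 15, grid = 20, uptake = control_uptake_model(),
                  artifacts = artifact_model(signal_drift_frac_per_min = 1e-3))
  b2 <- build_s0_baseline(s2)
  i_s0 <- which(s2$entries$role == "s0")
  sm <- cestdyn:::roi_means(s2)
  # baseline reproduces the drifting S0 at S0 times, linear in between
  # (outside the S0 time hull the boundary value is held)
  expect_equal(b2$s0_sg[i_s0], sm[i_s0], tolerance = 1e-9)
  # inside the S0 hull the baseline is exactly linear in time
  hull <- b2$times_s >= min(b2$s0_times_s) & b2$times_s <= max(b2$s0_times_s)
  th <- b2$times_s[hull]; bh <- b2$s0_sg[hull]
  slope <- (bh[length(bh)] - bh[1]) / (th[length(th)] - th[1])
  expect_equal(bh, bh[1] + slope * (th - th[1]), tolerance = 1e-9)
})

test_that("dummy S0 images are excluded from the baseline", {
  s <- fx_series(n_cycles = 5, grid = 20, uptake = control_uptake_model())
  # corrupt the dummies; the baseline must not move
  b0 <- build_s0_baseline(s)
  s$images[, , s$entries$role == "dummy"] <- 99
  b1 <- build_s0_baseline(s)
  expect_equal(b1$s0_sg, b0$s0_sg)
  s$entries <- s$entries[s$entries$role != "s0", ]
  s$images <- s$images[, , which(s$entries$role != "s0"), drop = FALSE]
  expect_error(build_s0_baseline(s), "S0 entries")
})

test_that("normalisation returns S/S0 and cancels multiplicative drift", {
  s <- fx_series(n_cycles = 10, grid = 20, uptake = control_uptake_model())
  z <- normalize_series(s)
  expect_true(all(z$offset_ppm %in% c(-2.7, 3.6)))
  # scaling every image by a common gain leaves Z unchanged
  s_scaled <- s
  s_scaled$images <- s$images * 3.7
  expect_equal(normalize_series(s_scaled)$Z, z$Z, tolerance = 1e-12)
  # a slow multiplicative drift common to S and S0 cancels wherever the
  # baseline interpolates between S0 samples (the trailing entries past the
  # last S0 image use a held boundary value and keep a residual)
  s_drift <- fx_series(n_cycles = 10, grid = 20,
                       uptake = control_uptake_model(),
                       artifacts = artifact_model(signal_drift_frac_per_min = 2e-3))
  zd <- normalize_series(s_drift)
  t_last_s0 <- max(s_drift$entries$t_mid_s[s_drift$entries$role == "s0"]) / 60
  hull <- zd$t_min <= t_last_s0
  expect_equal(zd$Z[hull], z$Z[hull], tolerance = 1e-9)
})

test_that("MTR referencing forces a zero pre-injection mean", {
  set.seed(4)
  t <- seq(8, 118, by = 2)
  z <- 1 - 0.01 * (t > 23) + rnorm(length(t), 0, 1e-3)
  cv <- mtr_curve(z, t, injection_start_min = 23)
  pre <- cv$times_min < 23
  expect_equal(mean(cv$mtr[pre]), 0, tolerance = 1e-15)
  expect_equal(cv$mtr, cv$z_pre_avg - z)
  # signal loss of 1.3% appears as MTR = +1.3%
  z2 <- c(rep(1, 10), rep(1 - 0.013, 10))
  cv2 <- mtr_curve(z2, seq(10, 48, by = 2), 23)
  expect_equal(max(cv2$mtr), 0.013)
  expect_equal(mtr_curve(rep(0.97, 20), seq(10, 48, 2), 23)$mtr, rep(0, 20))
  expect_error(mtr_curve(z2, seq(30, 68, 2), 23), "pre-injection")
})

test_that("AUC integration is exact for rectangles, additive and linear", {
  t <- seq(10, 50, by = 1)
  cv <- mtr_curve(rep(1, length(t)), t, injection_start_min = 23)
  cv$mtr <- rep(0.01, length(t))             # constant MTR of 1%
  expect_equal(mtr_auc(cv, c(20, 35)), 0.01 * 15)
  expect_equal(mtr_auc(cv, c(20, 27)) + mtr_auc(cv, c(27, 35)),
               mtr_auc(cv, c(20, 35)))
  cv2 <- cv; cv2$mtr <- cv$mtr * 3
  expect_equal(mtr_auc(cv2, c(20, 35)), 3 * mtr_auc(cv, c(20, 35)))
  expect_error(mtr_auc(cv, c(35, 35)), "empty")
  expect_error(mtr_auc(cv, c(0, 20)), "outside")
})

test_that("pixel-wise AUC maps recover injected uptake contrast", {
  s <- fx_series(n_cycles = 80, grid = 20, sigma = 0.002, seed = 3)
  pre <- pixelwise_auc(s, c(8, 23))
  post <- pixelwise_auc(s, c(24, 39))
  liver <- s$masks$liver
  expect_true(all(is.na(pre$values[!liver])))
  expect_gt(mean(post$values[liver]), mean(pre$values[liver]))
  # null map: control series, noiseless -> zero AUC everywhere
  s0 <- fx_series(n_cycles = 80, grid = 20, uptake = control_uptake_model())
  m0 <- pixelwise_auc(s0, c(24, 39))
  expect_equal(max(abs(m0$values[liver])), 0, tolerance = 1e-10)
})

test_that("group averages report pointwise mean, SD and smoothing", {
  t <- seq(8, 118, by = 2)
  mk <- function(eps) {
    cv <- mtr_curve(1 - eps * (t > 23), t, 23)
    cv
  }
  g <- group_average(list(mk(0.01), mk(0.02), mk(0.03)))
  expect_equal(g$n, 3)
  post <- g$times_min > 23
  expect_equal(unique(round(g$mean[post], 12)), 0.02)
  expect_equal(unique(round(g$sd[post], 12)), 0.01)
  g_same <- group_average(list(mk(0.01), mk(0.01)))
  expect_equal(g_same$sd, rep(0, length(t)))
  expect_warning(g1 <- group_average(list(mk(0.01))), "SD undefined")
  expect_true(all(is.na(g1$sd)))
  short <- mtr_curve(rep(1, 10), t[1:10], 23)
  expect_error(group_average(list(mk(0.01), short)), "common time grid")
})
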