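#' Uptake kinetics model
#'
#' Parametric model of the injected-solute MTR contribution: a
#' gamma-variate spike (the standard single-peaked bolus-response form)
#' starting at the injection and peaking `spike_peak_delay_min` later, plus
#' a linear accumulation term, with an optional late exponential decay.
#' Amplitudes are in MTR units (fraction of S0; 0.0064 = 0.64%).
#'
#' @param injection_start_min Injection start, minutes into the scan.
#' @param spike_amplitude_mtr Peak MTR of the spike (>= 0). The default is
#'   the group-mean peak scale of the in vivo data (0.64%).
#' @param spike_peak_delay_min Delay from injection start to spike peak.
#' @param spike_width_min Gamma-variate width scale; the shape parameter is
#'   `(spike_peak_delay_min / spike_width_min)^2` (default width gives
#'   shape 2).
#' @param accumulation_slope_mtr_per_min Late linear MTR rise per minute.
#' @param decay_after_min If finite, the uptake decays exponentially after
#'   this time with time constant `decay_tau_min`.
#' @param decay_tau_min Decay time constant, minutes.
#' @return An object of class `uptake_model`.
#' @export
uptake_model <- function(injection_start_min = 23,
                         spike_amplitude_mtr = 0.0064,
                         spike_peak_delay_min = 7,
                         spike_width_min = 7 / sqrt(2),
                         accumulation_slope_mtr_per_min = 5e-5,
                         decay_after_min = Inf,
                         decay_tau_min = 60) {
  stopifnot(spike_amplitude_mtr >= 0, spike_peak_delay_min > 0,
            spike_width_min > 0, injection_start_min >= 0,
            accumulation_slope_mtr_per_min >= 0, decay_tau_min > 0)
  structure(list(injection_start_min = injection_start_min,
                 spike_amplitude_mtr = spike_amplitude_mtr,
                 spike_peak_delay_min = spike_peak_delay_min,
                 spike_width_min = spike_width_min,
                 accumulation_slope_mtr_per_min = accumulation_slope_mtr_per_min,
                 decay_after_min = decay_after_min,
                 decay_tau_min = decay_tau_min),
            class = "uptake_model")
}

#' Control (no-uptake) kinetics
#' @inheritParams uptake_model
#' @return An `uptake_model` with all amplitudes zero.
#' @export
control_uptake_model <- function(injection_start_min = 23) {
  uptake_model(injection_start_min = injection_start_min,
               spike_amplitude_mtr = 0,
               accumulation_slope_mtr_per_min = 0)
}

#' Injected MTR contribution at a time point
#'
#' The target MTR (in fraction-of-S0 units) contributed by the injected
#' solute at `t_min` minutes into the scan: 0 before injection, then the
#' gamma-variate spike plus linear accumulation. Continuous in `t_min`.
#'
#' @param t_min Time, minutes (vectorised).
#' @param model An `uptake_model`.
#' @return MTR contribution (same length as `t_min`).
#' @export
uptake_mtr_at <- function(t_min, model) {
  stopifnot(inherits(model, "uptake_model"), all(t_min >= 0))
  dt <- pmax(0, t_min - model$injection_start_min)
  tp <- model$spike_peak_delay_min
  alpha <- (tp / model$spike_width_min)^2
  spike <- model$spike_amplitude_mtr * (dt / tp)^alpha * exp(alpha * (1 - dt / tp))
  spike[dt == 0] <- 0
  accum <- model$accumulation_slope_mtr_per_min * dt
  out <- spike + accum
  late <- t_min > model$decay_after_min
  if (any(late))
    out[late] <- out[late] * exp(-(t_min[late] - model$decay_after_min) /
                                   model$decay_tau_min)
  out
}

#' Solute pool-fraction increment at a time point
#'
#' Converts the injected MTR target at `t_min` into an absolute increment
#' of the exchanging pool's proton fraction (the concentration proxy through
#' which uptake enters the physics), using a calibration from
#' [calibrate_uptake()]. Without a calibration the MTR target itself is
#' returned.
#'
#' @inheritParams uptake_mtr_at
#' @param calibration Function mapping MTR target to fraction increment.
#' @return Pool-fraction increment (>= 0).
#' @export
uptake_fraction_at <- function(t_min, model, calibration = NULL) {
  m <- uptake_mtr_at(t_min, model)
  if (is.null(calibration)) m else calibration(m)
}

#' Calibrate pool fraction against MTR
#'
#' Tabulates the steady-state MTR at the solute resonance as a function of
#' the extra solute proton fraction and returns the monotone inverse, so
#' that a target MTR time course can be injected exactly through the pool
#' fraction. MTR here is Z(base) - Z(base + extra fraction) at
#' `offset_ppm`.
#'
#' @param pools Pool list (water + solutes) at baseline.
#' @param field A `field_params`.
#' @param b1_uT CW saturation amplitude used by the generator.
#' @param pool_name Which pool carries the uptake.
#' @param offset_ppm Offset at which MTR is calibrated (the pool resonance).
#' @param max_mtr Largest MTR the calibration must cover.
#' @param n_grid Grid size of the tabulation.
#' @return Function: MTR target -> fraction increment.
#' @export
calibrate_uptake <- function(pools, field, b1_uT, pool_name = "thiol",
                             offset_ppm = -2.7, max_mtr = 0.05,
                             n_grid = 200L) {
  pools <- validate_pools(pools)
  ip <- which(vapply(pools, function(p) p$name == pool_name, TRUE))
  if (length(ip) != 1) stop("calibrate_uptake: no pool named '", pool_name, "'")
  z_of <- function(df) {
    p2 <- pools
    p2[[ip]]$fraction <- p2[[ip]]$fraction + df
    steady_state_cw(p2, offset_ppm, b1_uT, field)
  }
  z0 <- z_of(0)
  # grow the fraction range until the tabulated MTR covers max_mtr
  f_hi <- 1e-3
  while (z0 - z_of(f_hi) < max_mtr) {
    f_hi <- f_hi * 2
    if (f_hi > 1) stop("calibrate_uptake: cannot reach max_mtr = ", max_mtr)
  }
  f_grid <- seq(0, f_hi, length.out = n_grid)
  mtr_grid <- z0 - vapply(f_grid, z_of, 0)
  stats::approxfun(mtr_grid, f_grid, rule = 2)
}

#' Slow-artifact model
#'
#' B0 drift (Hz/min, shifts the apparent offset axis), multiplicative
#' signal drift (fraction per minute, applied to every image so that the
#' S0 normalisation can cancel it), and a late motion pseudo-CEST term: an
#' additive signal-loss ramp applied to measure images only, growing
#' linearly from `motion_onset_min` to `motion_amplitude_mtr` at
#' `motion_full_min`.
#'
#' @param drift_hz_per_min Linear B0 drift rate.
#' @param signal_drift_frac_per_min Multiplicative S0 drift per minute.
#' @param motion_onset_min Motion artifact onset, minutes.
#' @param motion_amplitude_mtr Pseudo-CEST amplitude reached at
#'   `motion_full_min`, MTR units.
#' @param motion_full_min Time at which the ramp reaches full amplitude.
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(drift_hz_per_min = 0,
                           signal_drift_frac_per_min = 0,
                           motion_onset_min = Inf,
                           motion_amplitude_mtr = 0,
                           motion_full_min = 120) {
  stopifnot(is.finite(drift_hz_per_min), is.finite(signal_drift_frac_per_min),
            motion_amplitude_mtr >= 0)
  structure(list(drift_hz_per_min = drift_hz_per_min,
                 signal_drift_frac_per_min = signal_drift_frac_per_min,
                 motion_onset_min = motion_onset_min,
                 motion_amplitude_mtr = motion_amplitude_mtr,
                 motion_full_min = motion_full_min),
            class = "artifact_model")
}

#' Default in-vivo-like artifact settings
#'
#' Mild drift and late motion shared by test and control cohorts: 0.5
#' Hz/min B0 drift, 0.02 %/min signal drift, motion pseudo-CEST ramping
#' from 60 min to 0.3% at 120 min.
#' @return An `artifact_model`.
#' @export
default_artifacts <- function() {
  artifact_model(drift_hz_per_min = 0.5,
                 signal_drift_frac_per_min = 2e-4,
                 motion_onset_min = 60,
                 motion_amplitude_mtr = 0.003,
                 motion_full_min = 120)
}

motion_mtr_at <- function(t_min, art) {
  ramp <- (t_min - art$motion_onset_min) /
    max(art$motion_full_min - art$motion_onset_min, 1e-9)
  art$motion_amplitude_mtr * pmin(1, pmax(0, ramp))
}

#' Magnitude-noise model
#'
#' @param sigma_frac Noise SD as a fraction of the mean liver baseline
#'   signal. The default 0.5% is a calibration choice giving per-pixel MTR
#'   scatter of order 1% (a plausible magnitude-image SNR for this
#'   protocol), not a measured value; between-subject biological
#'   variability is not part of the noise model.
#' @param distribution `"rician"` (magnitude of complex Gaussian noise) or
#'   `"gaussian"`.
#' @param seed Integer seed; identical seed gives an identical dataset.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_frac = 0.005,
                        distribution = c("rician", "gaussian"), seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(sigma_frac >= 0, is.finite(seed))
  structure(list(sigma_frac = sigma_frac, distribution = distribution,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic liver phantom
#'
#' A smooth, simply connected liver-like region on a square grid: an
#' ellipse with a seeded low-order harmonic boundary perturbation, area
#' 20-40% of the grid. Baseline intensity is 1 inside the liver with a
#' gentle seeded spatial modulation, 0 outside.
#'
#' @param grid Grid size (>= 16); images are `grid x grid`.
#' @param seed Integer seed for the boundary/intensity perturbations.
#' @return List with `liver` and `background` logical masks and `baseline`
#'   intensity matrix.
#' @export
make_liver_phantom <- function(grid = 96L, seed = 1L) {
  if (grid < 16) stop("make_liver_phantom: grid must be >= 16")
  rng <- make_rng(seed)
  x <- (seq_len(grid) - (grid + 1) / 2) / grid
  X <- matrix(x, grid, grid)
  Y <- matrix(x, grid, grid, byrow = TRUE)
  theta <- atan2(Y, X + 0.02)
  r <- sqrt((X / 0.38)^2 + (Y / 0.30)^2)
  amp <- rng(3) * 0.05
  pha <- rng(3) * 2 * pi
  wob <- 1 + amp[1] * cos(2 * theta + pha[1]) +
    amp[2] * cos(3 * theta + pha[2]) + amp[3] * cos(4 * theta + pha[3])
  liver <- r <= wob
  base <- matrix(0, grid, grid)
  gx <- rng(2) * 0.1 - 0.05
  base[liver] <- 1 + gx[1] * X[liver] + gx[2] * Y[liver]
  list(liver = liver, background = !liver, baseline = base)
}

# Seeded uniform generator that does not disturb the global RNG stream.
make_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
}

#' Generate a synthetic dynamic CEST study
#'
#' Renders a complete dynamic series for one subject following an
#' acquisition schedule: per image, the Bloch-McConnell CW steady-state Z
#' at the (drift-shifted) saturation offset with the uptake pool's fraction
#' scaled per the kinetics model, times the baseline map and the
#' multiplicative signal drift, minus the motion pseudo-CEST term (measure
#' images only), plus magnitude noise. S0 images (333 ppm) are simulated
#' through the identical physics. The ground truth (noiseless ROI-mean Z
#' and pre-injection-referenced MTR per retained entry) is returned
#' alongside.
#'
#' @param schedule An `acq_schedule`.
#' @param uptake An `uptake_model`.
#' @param artifacts An `artifact_model`.
#' @param noise A `noise_model`.
#' @param pools Pool list; must contain water and the uptake pool.
#' @param field A `field_params`.
#' @param phantom Output of [make_liver_phantom()]; built with
#'   `phantom_seed` when `NULL`.
#' @param b1_uT CW amplitude for the generation physics; defaults to the
#'   average-power equivalent of the 30 ms / 1.2 uT Gaussian train.
#' @param uptake_pool,uptake_offset_ppm Pool name carrying the uptake and
#'   the resonance at which its MTR target is calibrated.
#' @param render `"pixel"` renders full images; `"roi"` renders only the
#'   liver ROI mean per image (noise SD scaled by 1/sqrt(n pixels)), for
#'   fast cohort-level simulation.
#' @param grid Grid size for a default phantom.
#' @param phantom_seed Seed for a default phantom.
#' @return An object of class `dynamic_series`: `images` (grid x grid x n
#'   array, or 1 x 1 x n for ROI rendering), `entries` (the schedule),
#'   `masks`, `ground_truth` (data.frame: index, t_min, offset_ppm, z_true,
#'   mtr_true, mtr_target for retained measure entries), and the generation
#'   parameters.
#' @export
generate_series <- function(schedule, uptake = uptake_model(),
                            artifacts = artifact_model(),
                            noise = noise_model(),
                            pools = liver_pools(), field = field_params(),
                            phantom = NULL, b1_uT = NULL,
                            uptake_pool = "thiol", uptake_offset_ppm = -2.7,
                            render = c("pixel", "roi"),
                            grid = 96L, phantom_seed = 1L) {
  render <- match.arg(render)
  stopifnot(inherits(schedule, "acq_schedule"), inherits(uptake, "uptake_model"),
            inherits(artifacts, "artifact_model"), inherits(noise, "noise_model"))
  pools <- validate_pools(pools)
  ip <- which(vapply(pools, function(p) p$name == uptake_pool, TRUE))
  if (length(ip) != 1)
    stop("generate_series: pools must contain one pool named '", uptake_pool, "'")
  if (is.null(b1_uT)) b1_uT <- train_b1_rms(default_train())
  if (is.null(phantom)) phantom <- make_liver_phantom(grid, phantom_seed)

  n <- nrow(schedule)
  t_min <- schedule$t_mid_s / 60
  hpp <- hz_per_ppm(field)
  drift_ppm <- artifacts$drift_hz_per_min * t_min / hpp
  eff_offset <- schedule$offset_ppm - drift_ppm
  sdrift <- 1 + artifacts$signal_drift_frac_per_min * t_min

  mtr_target <- uptake_mtr_at(t_min, uptake)
  cal <- if (any(mtr_target > 0))
    calibrate_uptake(pools, field, b1_uT, uptake_pool, uptake_offset_ppm,
                     max_mtr = max(mtr_target) * 1.2)
  else function(m) rep(0, length(m))
  df_extra <- cal(mtr_target)

  z <- z_ref <- numeric(n)
  for (i in seq_len(n)) {
    p2 <- pools
    p2[[ip]]$fraction <- p2[[ip]]$fraction + df_extra[i]
    z[i] <- steady_state_cw(p2, eff_offset[i], b1_uT, field)
    # same-time S0 reference (also drift-shifted); the measured Z is S/S0
    z_ref[i] <- steady_state_cw(p2, S0_OFFSET_PPM - drift_ppm[i], b1_uT, field)
  }
  is_meas <- schedule$role == "measure"
  motion <- motion_mtr_at(t_min, artifacts) * is_meas
  z_eff <- z - motion

  liver <- phantom$liver
  n_px <- sum(liver)
  mean_base <- mean(phantom$baseline[liver])
  sigma <- noise$sigma_frac * mean_base

  set.seed(noise$seed)
  if (render == "pixel") {
    g <- nrow(phantom$baseline)
    images <- array(0, dim = c(g, g, n))
    for (i in seq_len(n)) {
      S <- phantom$baseline * (z_eff[i] * sdrift[i])
      if (sigma > 0) {
        if (noise$distribution == "rician") {
          S <- sqrt((S + stats::rnorm(g * g, 0, sigma))^2 +
                      stats::rnorm(g * g, 0, sigma)^2)
        } else {
          S <- S + stats::rnorm(g * g, 0, sigma)
        }
      }
      images[, , i] <- S
    }
    masks <- list(liver = liver, background = phantom$background)
  } else {
    s_roi <- mean_base * z_eff * sdrift
    if (sigma > 0) s_roi <- s_roi + stats::rnorm(n, 0, sigma / sqrt(n_px))
    images <- array(s_roi, dim = c(1, 1, n))
    masks <- list(liver = matrix(TRUE, 1, 1), background = matrix(FALSE, 1, 1))
  }

  # ground truth: per tracked offset, pre-injection-referenced noiseless MTR
  ri <- which(schedule$retain & is_meas)
  gt <- data.frame(index = ri, t_min = t_min[ri],
                   offset_ppm = schedule$offset_ppm[ri],
                   z_true = z_eff[ri] / z_ref[ri],
                   mtr_true = NA_real_, mtr_target = mtr_target[ri])
  for (off in unique(gt$offset_ppm)) {
    sel <- gt$offset_ppm == off
    pre <- sel & gt$t_min < uptake$injection_start_min
    if (any(pre))
      gt$mtr_true[sel] <- mean(gt$z_true[pre]) - gt$z_true[sel]
  }

  structure(list(images = images, entries = schedule, masks = masks,
                 ground_truth = gt,
                 params = list(uptake = uptake, artifacts = artifacts,
                               noise = noise, pools = pools, field = field,
                               b1_uT = b1_uT, uptake_pool = uptake_pool,
                               uptake_offset_ppm = uptake_offset_ppm,
                               render = render)),
            class = "dynamic_series")
}

#' Generate a cohort of synthetic subjects
#'
#' Convenience wrapper producing `n_subjects` independent subjects that
#' share every model setting but the noise seed (subject i uses seed
#' `base_seed + i - 1`).
#'
#' @param n_subjects Cohort size.
#' @param base_seed First noise seed; subject i uses `base_seed + i - 1`.
#' @param ... Passed to [generate_series()] (do not pass `noise$seed`).
#' @param noise A `noise_model` template.
#' @return List of `dynamic_series`.
#' @export
generate_group <- function(n_subjects, base_seed = 1L,
                           noise = noise_model(), ...) {
  lapply(seq_len(n_subjects), function(i) {
    ni <- noise; ni$seed <- as.integer(base_seed + i - 1)
    generate_series(noise = ni, ...)
  })
}
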