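#' Acquisition timing parameters
#'
#' Defaults reproduce the dynamic liver protocol: TR = 40.41 ms, 302
#' centre-out radial spokes per image (so one image takes 12.2 s), a 30 ms
#' saturation pulse before every spoke, and the injection starting 23 min
#' into the dynamic scan and lasting 1 min.
#'
#' @param tr_s Repetition time, seconds.
#' @param n_spokes Radial spokes per image.
#' @param sat_pulse_s Saturation pulse duration, seconds.
#' @param injection_start_min Injection start, minutes into the scan.
#' @param injection_duration_min Injection duration, minutes.
#' @return An object of class `timing_params`.
#' @export
timing_params <- function(tr_s = 0.04041, n_spokes = 302,
                          sat_pulse_s = 0.030, injection_start_min = 23,
                          injection_duration_min = 1) {
  vals <- c(tr_s, n_spokes, sat_pulse_s, injection_start_min,
            injection_duration_min)
  stopifnot(all(is.finite(vals)), tr_s > 0, n_spokes >= 1, sat_pulse_s > 0,
            injection_start_min > 0, injection_duration_min > 0)
  structure(list(tr_s = tr_s, n_spokes = as.integer(n_spokes),
                 sat_pulse_s = sat_pulse_s,
                 injection_start_min = injection_start_min,
                 injection_duration_min = injection_duration_min),
            class = "timing_params")
}

#' Total saturation time per image (one offset)
#'
#' One saturation pulse precedes every radial spoke, so a single image at a
#' single offset accumulates `sat_pulse_s * n_spokes` of saturation:
#' 30 ms x 302 = 9.06 s under the default protocol.
#'
#' @param timing A `timing_params`.
#' @return Seconds of saturation per image.
#' @export
saturation_time_per_offset <- function(timing) {
  stopifnot(inherits(timing, "timing_params"))
  timing$sat_pulse_s * timing$n_spokes
}

#' Time resolution of the retained dynamic curve
#'
#' Each retained point comes from the second of two consecutive same-offset
#' images, so consecutive retained points for a tracked offset are
#' `2 * tr_s * n_spokes` apart: 24.4 s under the default protocol (value
#' returned exactly; round to 0.1 s for reporting).
#'
#' @param timing A `timing_params`.
#' @return Seconds between retained points of one tracked offset.
#' @export
retained_time_resolution <- function(timing) {
  stopifnot(inherits(timing, "timing_params"))
  2 * timing$tr_s * timing$n_spokes
}

image_duration_s <- function(timing) timing$tr_s * timing$n_spokes

S0_OFFSET_PPM <- 333

# Assemble an acquisition schedule data.frame from per-image offsets/roles.
# Repeated-measure bookkeeping: within each consecutive same-offset pair of
# measure images, the first instance is discarded (retain = FALSE) because
# the saturation steady state is violated by the frequency switch; only the
# second is used. Dummies are never retained; S0 images are retained.
make_schedule <- function(offsets, roles, timing) {
  stopifnot(length(offsets) == length(roles))
  n <- length(offsets)
  instance <- integer(n)
  retain <- logical(n)
  prev_offset <- NA_real_; prev_role <- ""
  for (i in seq_len(n)) {
    if (roles[i] == "measure" && identical(prev_role, "measure") &&
        isTRUE(offsets[i] == prev_offset)) {
      instance[i] <- 2L; retain[i] <- TRUE
    } else if (roles[i] == "measure") {
      instance[i] <- 1L; retain[i] <- FALSE
    } else {
      instance[i] <- 1L; retain[i] <- roles[i] == "s0"
    }
    prev_offset <- offsets[i]; prev_role <- roles[i]
  }
  dur <- image_duration_s(timing)
  t_start <- (seq_len(n) - 1) * dur
  sched <- data.frame(index = seq_len(n), offset_ppm = offsets, role = roles,
                      instance = instance, retain = retain,
                      t_start_s = t_start, t_mid_s = t_start + dur / 2)
  class(sched) <- c("acq_schedule", "data.frame")
  attr(sched, "timing") <- timing
  sched
}

#' Frequency list FL1: alternating thiol/amide tracking
#'
#' Twelve dummy S0 images (saturation at 333 ppm) bring the system to a
#' saturation steady state, followed by repeating cycles that interleave S0
#' images with paired acquisitions at the two tracked resonances. The
#' default cycle is `S0, -2.7, -2.7, S0, 3.6, 3.6`; within each same-offset
#' pair the first image is discarded (retain = FALSE) and only the second
#' enters the dynamic MTR curve.
#'
#' @param timing A `timing_params`.
#' @param n_dummy Number of leading dummy S0 images.
#' @param n_cycles Number of cycles after the dummies (>= 1). The default 98
#'   gives a ~122 min scan.
#' @param cycle_offsets Offsets of one cycle; `NA` marks an S0 image.
#' @return An `acq_schedule` data.frame with columns index, offset_ppm,
#'   role, instance, retain, t_start_s, t_mid_s.
#' @export
build_fl1 <- function(timing = timing_params(), n_dummy = 12, n_cycles = 98,
                      cycle_offsets = c(NA, -2.7, -2.7, NA, 3.6, 3.6)) {
  stopifnot(n_dummy >= 0)
  if (n_cycles < 1) stop("build_fl1: n_cycles must be >= 1")
  cyc_roles <- ifelse(is.na(cycle_offsets), "s0", "measure")
  cyc_off <- ifelse(is.na(cycle_offsets), S0_OFFSET_PPM, cycle_offsets)
  offsets <- c(rep(S0_OFFSET_PPM, n_dummy), rep(cyc_off, n_cycles))
  roles <- c(rep("dummy", n_dummy), rep(cyc_roles, n_cycles))
  make_schedule(offsets, roles, timing)
}

#' Partial Z-spectrum frequency list (FL2 / FL3)
#'
#' Sweeps `n_offsets` evenly spaced offsets between the two endpoints
#' (inclusive), each acquired twice per sweep with the first instance
#' discarded, and one S0 image interleaved between consecutive sweeps.
#' FL2 covers -4.3 to -1.1 ppm (thiol side) and FL3 covers 4.2 to 3.0 ppm
#' (amide side). Nine dummy S0 images precede the sweeps.
#'
#' @param start_ppm,end_ppm Sweep endpoints (must differ).
#' @param n_offsets Offsets per sweep (>= 2).
#' @param timing A `timing_params`.
#' @param n_dummy Leading dummy S0 images.
#' @param n_cycles Number of sweeps (>= 1). The default 35 gives a ~80 min
#'   scan.
#' @return An `acq_schedule` data.frame.
#' @export
build_partial_list <- function(start_ppm, end_ppm, n_offsets = 5,
                               timing = timing_params(), n_dummy = 9,
                               n_cycles = 35) {
  if (start_ppm == end_ppm) stop("build_partial_list: start and end must differ")
  if (n_offsets < 2) stop("build_partial_list: n_offsets must be >= 2")
  if (n_cycles < 1) stop("build_partial_list: n_cycles must be >= 1")
  stopifnot(n_dummy >= 0)
  sweep <- seq(start_ppm, end_ppm, length.out = n_offsets)
  cyc_off <- c(S0_OFFSET_PPM, rep(sweep, each = 2))
  cyc_roles <- c("s0", rep("measure", 2 * n_offsets))
  offsets <- c(rep(S0_OFFSET_PPM, n_dummy), rep(cyc_off, n_cycles))
  roles <- c(rep("dummy", n_dummy), rep(cyc_roles, n_cycles))
  sched <- make_schedule(offsets, roles, timing)
  attr(sched, "sweep_offsets") <- sweep
  sched
}

#' Full Z-spectrum offset grid
#'
#' Symmetric inclusive grid `-half_range ... +half_range` in steps of
#' `step_ppm`; the defaults (+/-5 ppm, 0.2 ppm) give 51 offsets and always
#' contain 0.
#'
#' @param half_range_ppm Half sweep range, ppm.
#' @param step_ppm Frequency resolution, ppm (> 0, <= half range).
#' @return Numeric vector of offsets, ascending.
#' @export
build_full_zspec_list <- function(half_range_ppm = 5.0, step_ppm = 0.2) {
  stopifnot(half_range_ppm > 0)
  if (step_ppm <= 0) stop("build_full_zspec_list: step must be positive")
  if (step_ppm > half_range_ppm)
    stop("build_full_zspec_list: step exceeds the sweep range")
  n <- round(half_range_ppm / step_ppm)
  seq(-n, n) * step_ppm
}

#' Write / read an acquisition schedule as CSV
#' @param sched An `acq_schedule`.
#' @param path Output file.
#' @export
write_schedule_csv <- function(sched, path) {
  utils::write.csv(as.data.frame(sched), path, row.names = FALSE)
}

#' @rdname write_schedule_csv
#' @param timing Timing parameters to reattach on read.
#' @export
read_schedule_csv <- function(path, timing = timing_params()) {
  d <- utils::read.csv(path)
  d$role <- as.character(d$role)
  class(d) <- c("acq_schedule", "data.frame")
  attr(d, "timing") <- timing
  d
}
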