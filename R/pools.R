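#' Define an exchanging proton pool
#'
#' A pool is one exchangeable proton species in the Bloch-McConnell model:
#' water itself (chemical shift 0, fraction 1) or a dilute solute such as a
#' thiol (-2.7 ppm) or an amide (+3.6 ppm). Chemical shifts are in ppm
#' relative to water, upfield negative. The proton `fraction` is relative to
#' water protons and the exchange rate `k_exch_per_s` is the solute-to-water
#' rate; the reverse (water-to-solute) rate is `fraction * k_exch_per_s` by
#' detailed balance.
#'
#' @param name Label for the pool (e.g. `"water"`, `"thiol"`).
#' @param delta_ppm Chemical shift relative to water, ppm.
#' @param T1_s Longitudinal relaxation time, seconds.
#' @param T2_s Transverse relaxation time, seconds. Must not exceed `T1_s`.
#' @param fraction Proton fraction relative to water (>= 0; water has 1).
#' @param k_exch_per_s Solute-to-water exchange rate, 1/s (0 for water).
#' @return An object of class `cest_pool`.
#' @examples
#' thiol_pool <- cest_pool("thiol", -2.7, T1_s = 1.0, T2_s = 0.05,
#'                         fraction = 0.001, k_exch_per_s = 1000)
#' @export
cest_pool <- function(name, delta_ppm, T1_s, T2_s, fraction, k_exch_per_s) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(delta_ppm = delta_ppm, T1_s = T1_s, T2_s = T2_s,
            fraction = fraction, k_exch_per_s = k_exch_per_s)
  if (!all(is.finite(vals)))
    stop("cest_pool '", name, "': all parameters must be finite")
  if (T1_s <= 0 || T2_s <= 0)
    stop("cest_pool '", name, "': T1_s and T2_s must be positive")
  if (T2_s > T1_s)
    stop("cest_pool '", name, "': T2_s must not exceed T1_s")
  if (fraction < 0)
    stop("cest_pool '", name, "': fraction must be >= 0")
  if (k_exch_per_s < 0)
    stop("cest_pool '", name, "': k_exch_per_s must be >= 0")
  structure(list(name = name, delta_ppm = delta_ppm, T1_s = T1_s,
                 T2_s = T2_s, fraction = fraction,
                 k_exch_per_s = k_exch_per_s),
            class = "cest_pool")
}

#' Water pool constructor
#'
#' Water anchors the model: chemical shift 0 ppm, proton fraction 1, no
#' self-exchange term. Default relaxation times are representative of mouse
#' liver at 7 T and should be adjusted for other tissues.
#'
#' @param T1_s,T2_s Water relaxation times, seconds.
#' @return A `cest_pool` named `"water"`.
#' @export
water_pool <- function(T1_s = 1.4, T2_s = 0.03) {
  cest_pool("water", delta_ppm = 0, T1_s = T1_s, T2_s = T2_s,
            fraction = 1, k_exch_per_s = 0)
}

#' Default liver pool set
#'
#' Water plus a thiol pool at -2.7 ppm and an amide pool at +3.6 ppm.
#' The solute fractions and exchange rates are placeholder defaults chosen to
#' give MTR effects of a few tenths of a percent at 1.2 uT saturation, the
#' order observed in vivo; they are not authoritative literature values and
#' should be overridden when calibrated numbers are available. An optional
#' Lorentzian semi-solid MT pool can be appended with `mt = TRUE`.
#'
#' @param thiol_fraction,amide_fraction Solute proton fractions.
#' @param thiol_k,amide_k Solute-to-water exchange rates, 1/s.
#' @param mt Include a broad semi-solid MT pool (Lorentzian lineshape).
#' @return List of `cest_pool` objects, water first.
#' @export
liver_pools <- function(thiol_fraction = 0.0005, thiol_k = 1500,
                        amide_fraction = 0.0005, amide_k = 50,
                        mt = FALSE) {
  pools <- list(
    water_pool(),
    cest_pool("thiol", -2.7, T1_s = 1.0, T2_s = 0.02,
              fraction = thiol_fraction, k_exch_per_s = thiol_k),
    cest_pool("amide", 3.6, T1_s = 1.0, T2_s = 0.02,
              fraction = amide_fraction, k_exch_per_s = amide_k)
  )
  if (mt)
    pools <- c(pools, list(cest_pool("mt", -1.0, T1_s = 1.0, T2_s = 1e-5,
                                     fraction = 0.05, k_exch_per_s = 25)))
  pools
}

#' Static-field parameters
#'
#' @param B0_T Static field in tesla.
#' @param gamma_hz_per_T Gyromagnetic ratio over 2*pi in Hz/T. The proton
#'   value 42.577 MHz/T makes 1 ppm = 298.04 Hz at 7 T.
#' @param drift_hz_per_min Linear B0 drift rate in Hz/min (0 = stable field).
#' @return An object of class `field_params`.
#' @export
field_params <- function(B0_T = 7.0, gamma_hz_per_T = 42.577e6,
                         drift_hz_per_min = 0) {
  stopifnot(is.finite(B0_T), B0_T > 0, is.finite(gamma_hz_per_T),
            gamma_hz_per_T > 0, is.finite(drift_hz_per_min))
  structure(list(B0_T = B0_T, gamma_hz_per_T = gamma_hz_per_T,
                 drift_hz_per_min = drift_hz_per_min),
            class = "field_params")
}

#' Hz per ppm for a field
#'
#' The single conversion used everywhere: `gamma_hz_per_T * B0_T * 1e-6`.
#'
#' @param field A `field_params` object.
#' @return Hz per ppm (scalar).
#' @export
hz_per_ppm <- function(field) field$gamma_hz_per_T * field$B0_T * 1e-6

#' Saturation pulse
#'
#' @param shape `"cw"`, `"block"` or `"gaussian"`. For `cw`/`block` the
#'   envelope is constant at `b1_peak_uT`.
#' @param b1_peak_uT Peak amplitude of the envelope, microtesla.
#' @param duration_s Pulse duration, seconds.
#' @param truncation_sigma Gaussian truncation half-width in standard
#'   deviations; the envelope spans `+/- truncation_sigma` sigma over the
#'   pulse, so sigma = duration / (2 * truncation_sigma).
#' @return An object of class `sat_pulse`.
#' @export
sat_pulse <- function(shape = c("gaussian", "cw", "block"), b1_peak_uT,
                      duration_s, truncation_sigma = 2.5) {
  shape <- match.arg(shape)
  stopifnot(is.finite(b1_peak_uT), b1_peak_uT >= 0,
            is.finite(duration_s), duration_s > 0,
            is.finite(truncation_sigma), truncation_sigma > 0)
  structure(list(shape = shape, b1_peak_uT = b1_peak_uT,
                 duration_s = duration_s,
                 truncation_sigma = truncation_sigma),
            class = "sat_pulse")
}

#' Saturation pulse train
#'
#' In the dynamic liver protocol one 30 ms Gaussian pulse precedes each of
#' the 302 radial readout spokes, giving 9.06 s of saturation per image with
#' a TR-minus-pulse free-relaxation gap between pulses.
#'
#' @param pulse A `sat_pulse`.
#' @param n_pulses Number of pulses (>= 1).
#' @param interpulse_delay_s Free-relaxation gap between pulses, seconds.
#' @param flip_deg Optional readout excitation flip angle in degrees; when
#'   set, longitudinal magnetisation is scaled by `cos(flip)` once per
#'   interpulse gap. `NULL` (default) ignores the readout pulse.
#' @return An object of class `sat_train`.
#' @export
sat_train <- function(pulse, n_pulses, interpulse_delay_s = 0,
                      flip_deg = NULL) {
  stopifnot(inherits(pulse, "sat_pulse"),
            is.finite(n_pulses), n_pulses >= 1,
            is.finite(interpulse_delay_s), interpulse_delay_s >= 0)
  if (!is.null(flip_deg)) stopifnot(is.finite(flip_deg))
  structure(list(pulse = pulse, n_pulses = as.integer(n_pulses),
                 interpulse_delay_s = interpulse_delay_s,
                 flip_deg = flip_deg),
            class = "sat_train")
}

#' Default acquisition saturation train
#'
#' 30 ms Gaussian pulses at 1.2 uT peak, 302 pulses (one per radial spoke),
#' interpulse gap TR - pulse = 10.41 ms.
#'
#' @param b1_peak_uT Peak B1, microtesla.
#' @param tr_s Repetition time, seconds.
#' @param n_spokes Radial spokes (= pulses) per image.
#' @param sat_pulse_s Saturation pulse duration, seconds.
#' @return A `sat_train`.
#' @export
default_train <- function(b1_peak_uT = 1.2, tr_s = 0.04041, n_spokes = 302,
                          sat_pulse_s = 0.030) {
  sat_train(sat_pulse("gaussian", b1_peak_uT, sat_pulse_s),
            n_pulses = n_spokes,
            interpulse_delay_s = tr_s - sat_pulse_s)
}

#' Root-mean-square B1 of a pulse train
#'
#' The equivalent-average-power continuous-wave amplitude of the train:
#' the RMS of the envelope taken over the whole pulse + gap period. Useful
#' when a vendor's nominal amplitude refers to average rather than peak
#' power, and as the CW amplitude for steady-state approximations of the
#' pulsed experiment.
#'
#' @param train A `sat_train`.
#' @param n_env Number of envelope samples used for the RMS integral.
#' @return B1 RMS in microtesla.
#' @export
train_b1_rms <- function(train, n_env = 1000L) {
  p <- train$pulse
  env <- pulse_envelope(p, n_env)
  period <- p$duration_s + train$interpulse_delay_s
  sqrt(mean(env^2) * p$duration_s / period) * p$b1_peak_uT
}

# Normalised envelope samples (peak = 1) at midpoints of n equal sub-steps.
pulse_envelope <- function(pulse, n) {
  t <- (seq_len(n) - 0.5) / n            # in (0, 1)
  switch(pulse$shape,
         cw = rep(1, n),
         block = rep(1, n),
         gaussian = {
           sigma <- 1 / (2 * pulse$truncation_sigma)  # in pulse-duration units
           exp(-((t - 0.5)^2) / (2 * sigma^2))
         })
}

#' @export
print.cest_pool <- function(x, ...) {
  cat(sprintf("<pool %s> delta %+0.2f ppm, T1 %.3g s, T2 %.3g s, f %.3g, k %.3g /s\n",
              x$name, x$delta_ppm, x$T1_s, x$T2_s, x$fraction, x$k_exch_per_s))
  invisible(x)
}
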