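# Small shared fixtures: pools, field, quick schedules.

fx_field <- function(...) field_params(...)

fx_water <- function() water_pool(T1_s = 1.4, T2_s = 0.03)

fx_thiol <- function(fraction = 0.0005, k = 1500)
  cest_pool("thiol", -2.7, T1_s = 1.0, T2_s = 0.02,
            fraction = fraction, k_exch_per_s = k)

fx_amide <- function(fraction = 0.0005, k = 50)
  cest_pool("amide", 3.6, T1_s = 1.0, T2_s = 0.02,
            fraction = fraction, k_exch_per_s = k)

fx_two_pool <- function() list(fx_water(), fx_thiol())
fx_three_pool <- function() list(fx_water(), fx_thiol(), fx_amide())

# closed-form single-pool CW steady state (independent of the matrix code)
single_pool_ss <- function(pool, offset_ppm, b1_uT, field) {
  w1 <- 2 * pi * field$gamma_hz_per_T * b1_uT * 1e-6
  dw <- 2 * pi * hz_per_ppm(field) * (pool$delta_ppm - offset_ppm)
  R1 <- 1 / pool$T1_s; R2 <- 1 / pool$T2_s
  R1 * (R2^2 + dw^2) / (R1 * (R2^2 + dw^2) + w1^2 * R2)
}

# small noiseless study for pipeline tests
fx_series <- function(n_cycles = 30, grid = 24, sigma = 0, seed = 1,
                      uptake = uptake_model(), artifacts = artifact_model(),
                      render = "pixel", schedule = NULL) {
  if (is.null(schedule)) schedule <- build_fl1(n_cycles = n_cycles)
  generate_series(schedule, uptake = uptake, artifacts = artifacts,
                  noise = noise_model(sigma_frac = sigma, seed = seed),
                  render = render, grid = grid, phantom_seed = 7)
}
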