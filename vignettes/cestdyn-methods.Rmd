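---
title: "Methods: dynamic CEST-MRI quantification in cestdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic CEST-MRI quantification in cestdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chemical exchange saturation transfer (CEST) MRI detects dilute solutes
through their exchangeable protons: a frequency-selective saturation pulse
applied at the solute resonance is carried into the water pool by chemical
exchange, attenuating the water signal by far more than the solute's
concentration alone would allow. `cestdyn` implements the quantification
chain for *dynamic* CEST of hepatic solute uptake at 7 T — tracking the
thiol resonance of N-acetylcysteine (NAC) at −2.7 ppm (upfield of water)
and the amide resonance of glutathione at +3.6 ppm while the agent is
injected mid-scan — together with a physics-based synthetic-study
generator, so that every stage of the pipeline can be exercised and
validated without animal data.

# The physics core: multi-pool Bloch–McConnell

Each proton species (water; thiol; amide; optionally a broad semi-solid MT
pool) is a *pool* with chemical shift $\delta_i$ (ppm from water, upfield
negative), relaxation times $T_{1,i}, T_{2,i}$, proton fraction $f_i$
relative to water ($f_w = 1$), and solute→water exchange rate $k_i$. In
the frame rotating at the saturation frequency the magnetisations obey the
linear system $\dot M = A M + b$, with per-pool Bloch blocks (resonance
offset $\Delta\omega_i$, saturation amplitude
$\omega_1 = 2\pi\gamma B_1$) and exchange coupling that respects detailed
balance: the water→solute rate is $f_i k_i$. The state stacks
$(M_x, M_y, M_z)$ per pool, so $n$ pools give a $3n \times 3n$ matrix
(`build_exchange_matrix()`).

Two solvers are provided:

* `steady_state_cw()` — the fixed point $M = -A^{-1}b$ under continuous
  irradiation. Exact, fast, and the analytic oracle for everything else.
* `simulate_pulse_train()` — piecewise integration of a train of shaped
  pulses with free-relaxation gaps. Within each sub-step the envelope is
  held constant and the affine system propagated *exactly* by the matrix
  exponential of the augmented homogeneous system, so accuracy is governed
  solely by the envelope discretisation. Per-pulse propagators are
  precomputed and reused across the train.

Numerical choices: the matrix exponential uses `Matrix::expm` (Ward's
scaled Padé), which is stable for these stiff rotation-plus-relaxation
matrices; the default sub-step is 0.1 ms, at which halving the step
changes Z by less than $10^{-6}$ (asserted in the test suite); with a CW
shape, zero gaps and a long train the integrator matches the analytic
fixed point to better than $10^{-6}$ (in practice $\sim 10^{-12}$).

Unit conventions: the gyromagnetic ratio is fixed at
$\gamma/2\pi = 42.577$ MHz/T, so 1 ppm = 298.04 Hz at 7 T; every
ppm↔Hz conversion goes through `hz_per_ppm()`.

The saturation pulse is a 30 ms Gaussian with $B_1 = 1.2\,\mu$T
interpreted as the *peak* of the envelope, truncated at $\pm 2.5\sigma$
with $\sigma =$ duration/5. Because vendor nominal amplitudes sometimes
refer to average power instead, `train_b1_rms()` returns the
equivalent-average-power CW amplitude of the train (≈0.69 µT for the
default 30 ms pulse + 10.41 ms gap), and the CW-approximation entry points
accept an arbitrary amplitude. The 10° readout excitation is neglected by
default; it can be enabled as a per-gap cos-scaling of $M_z$
(`sat_train(flip_deg = 10)`).

Default pool parameters (`liver_pools()`: thiol $k = 1500$ s⁻¹,
$f = 5\times10^{-4}$; amide $k = 50$ s⁻¹; liver water $T_1 = 1.4$ s,
$T_2 = 30$ ms at 7 T) are **placeholder defaults**, chosen to give MTR
effects of a few tenths of a percent at 1.2 µT — the order observed in
vivo. They are deliberately exposed as plain constructor arguments and
should be overridden wherever calibrated values exist.

# The acquisition schedule

The dynamic protocol acquires one 2D radial image per saturation offset:
302 spokes, each preceded by one 30 ms pulse, TR = 40.41 ms. Hence

* saturation time per image: 30 ms × 302 = 9.06 s,
* image duration: 40.41 ms × 302 = 12.2 s,
* retained-curve time resolution: 2 × 12.2 s = 24.4 s,

because every tracked frequency is acquired *twice* in a row and only the
second image is kept — the first violates the saturation steady state
after a frequency switch. `build_fl1()` (alternating −2.7/+3.6 ppm with
interleaved 333 ppm S0 images, 12 leading dummy S0 images) and
`build_partial_list()` (5-offset partial Z-spectrum sweeps, −4.3…−1.1 or
4.2…3.0 ppm, 9 dummies) encode this bookkeeping, with `retain`,
`instance`, `role` and timestamps per entry.

Two points were genuinely open and are package decisions: the exact
placement of the interleaved S0 images inside an FL1 cycle is not pinned
down by the protocol text, so the default cycle is
`[S0, −2.7, −2.7, S0, 3.6, 3.6]` and the composition is a constructor
argument; and total scan durations are emergent from the cycle count
(defaults 98 cycles ≈ 122 min for FL1, 35 sweeps ≈ 80 min for FL2/FL3)
rather than hard-coded. Timestamps are assigned at the image midpoint —
the symmetric attribution of a 12.2 s acquisition window.

# The synthetic-study generator

`generate_series()` renders a complete dynamic study on a 96×96 liver
phantom (a seeded smoothly-perturbed ellipse covering 20–40% of the
grid). Per schedule entry, at time $t$:

$$S(x, t) = B(x)\,\bigl[Z(\omega_{tx} - \delta_{B_0}(t);\, f(t)) -
  m(t)\bigr]\,(1 + s\,t) \;\;(+\text{ noise}),$$

where $B(x)$ is the baseline intensity map, $Z$ the CW steady-state
Bloch–McConnell solution at the drift-shifted offset with the uptake
pool's fraction $f(t)$ time-varying, $m(t)$ the motion pseudo-CEST term
(measure images only), $s$ the multiplicative signal drift, and the noise
is Rician (magnitude of complex Gaussian). S0 images at 333 ppm run
through the identical physics. The CW steady state at the train's RMS
amplitude stands in for the full pulse train here because 9.06 s of
saturation per image is long compared with $T_1$; the full integrator
remains available for spectrum-level work.

Design choices worth stating:

* **Uptake enters through the pool fraction** (a concentration proxy);
  pH/temperature — hence exchange rate — are held fixed.
* **The injected time course is specified in MTR units** (a
  gamma-variate spike of default amplitude 0.64%, peaking 7 min after the
  23-min injection start — the in vivo group-mean scale — plus a linear
  accumulation of 0.005%/min) and converted to a fraction increment by
  inverting a tabulated MTR-vs-fraction response (`calibrate_uptake()`).
  This makes "the injected MTR curve" well defined despite the mildly
  nonlinear CEST response.
* **Ground truth is the measured quantity**: the noiseless ROI-mean
  $Z = S/S_0$ — the far-off-resonance S0 itself responds (at the
  $10^{-8}$ level) to the solute — referenced to the pre-injection mean
  per tracked offset. With artifacts and noise off, the analysis pipeline
  reproduces it to $\sim 10^{-13}$, well inside the $10^{-8}$ bound the
  test suite asserts.
* Gamma-variate shape parameter 2 by default (set via
  `spike_width_min`); the single-peak bolus-response form is standard and
  the in vivo curve was never parameterised.
* Motion pseudo-CEST is an additive signal-loss ramp applied to measure
  images only (default: 0 → 0.3% between 60 and 120 min in
  `default_artifacts()`) — the simplest mechanism that reproduces a
  late control-group MTR rise.
* Noise sigma defaults to 0.5% of the mean liver baseline, a calibration
  choice (plausible magnitude-image SNR), not a measured value.

What the generator does **not** emulate: radial k-space synthesis and
reconstruction artifacts, respiratory image deformation (motion enters
only as the intensity term above), chemical-shift artifacts from adipose
tissue, $T_2$-broadening of the water line under drift, and — importantly
— between-subject biological variability: synthetic "mice" differ only by
noise seed, so synthetic group SDs are noise-only and much smaller than
in vivo between-animal bands. Passing recovery tests therefore validate
the *pipeline arithmetic*, not the biological effect size. A second
generic upfield pool can be added to the pool list to mix detection
mechanisms, since thiol CEST cannot be separated from other upfield MT
contributions by this experiment alone.

# The quantification pipeline

For an ROI (or per pixel), the chain is:

1. **S0 baseline** — ROI-mean intensities of the non-dummy S0 images,
   Savitzky–Golay filtered (window 3, order 2), linearly interpolated to
   every image time; boundary values are held outside the S0 hull. Note
   that a window-3/order-2 Savitzky–Golay fit interpolates exactly
   through every 3 points — it is the *identity transform*. It is
   implemented faithfully (and asserted to be the identity in the tests),
   and the window/order are configurable for users who want actual
   smoothing; no attempt is made to guess a different intent.
2. **Normalisation** — $Z = S / S_{0,SG}$, cancelling multiplicative
   signal drift common to S and S0. The cancellation is exact for linear
   drift between S0 samples; trailing entries past the last S0 image keep
   a small boundary-hold residual.
3. **Pre-injection referencing** — $\text{MTR} = Z_{pre,avg} - Z$, with
   $Z_{pre,avg}$ the mean over pre-injection retained points. This forces
   the pre-injection MTR mean to zero exactly and makes signal loss
   positive. Early non-steady-state points can be excluded via
   `pre_start_min` (the pipeline default in `run_pipeline()` uses 8 min).
4. **AUC maps** — the same chain per pixel (per-pixel S0 baselines), then
   trapezoidal integration of MTR over closed windows in minutes with
   linear endpoint interpolation (`pixelwise_auc()`; the in vivo windows
   of interest were 8–23, 24–39, 65–80 and 105–120 min).
5. **Group curves** — pointwise mean and sample SD across subjects, plus
   a display-smoothed mean (Savitzky–Golay window 7, order 2 — here the
   window genuinely smooths).

# Z-spectra and B0 mapping

`fit_dws()` fits the inverted Lorentzian
$Z(\omega) = b - d\,(\Gamma/2)^2 / \bigl((\Gamma/2)^2 +
(\omega-\delta)^2\bigr)$ to the direct-water-saturation dip; the fitted
centre $\delta$ is the per-pixel B0 shift (`b0_map()`). The fit window
and bounds are nowhere stated in the source protocol, so the package
declares its own: $|\delta| \le 1$ ppm and FWHM ∈ [0.2, 4] ppm, with
initialisation at the grid argmin — unbounded fits chase the thiol dip.
Fits that fail, find no dip (grid depth < 0.05), or park at the centre
bound are *flagged*, not raised; a start exactly on a symmetric optimum
can give a singular initial gradient in the Levenberg–Marquardt solver,
so the fit retries from starts perturbed by a quarter grid step. No WASSR
correction is applied to the dynamic data (it does not transfer cleanly
to dynamic acquisitions); the B0 map is diagnostic.

`partial_map()` assembles the 5-offset sweeps into offsets × time
matrices of group-mean MTR (cell timestamp = midpoint of the sweep's
retained entries), and `significance_map()` runs Welch's t-test per cell.

# Statistics

`welch_t()` (Welch–Satterthwaite df) and `paired_t()` wrap the standard
t-machinery; both are cross-checked in the tests against direct textbook
formula evaluations. All tests are two-sided (the source analyses report
two-sided-style p values without stating sidedness). No multiplicity
correction is applied to significance maps by default, mirroring common
practice for these exploratory maps — a known limitation, noted here
deliberately; `adjust = "BH"` enables Benjamini–Hochberg. Under a seeded
null (two control cohorts, 1000 cells) the flagged fraction at
$\alpha = 0.05$ falls within [0.03, 0.07], asserted in the acceptance
tests.

# Problem sizes and determinism

The test suite runs the full-size protocol where the claim depends on it
(96×96 grid, 98-cycle FL1, 5-subject cohorts, 200-sweep null calibration
with 1000 cells, 100-repeat B0 recovery) and small grids (16–32 px,
2–20 cycles) for structural checks; the whole suite completes in well
under a minute. Every random quantity flows from explicit integer seeds
(noise seed per subject, phantom seed, test-level `set.seed`), and
identical configuration + seed reproduces datasets bit-for-bit.

# Known limitations

* The CW steady-state approximation in the generator slightly smooths
  pulsed-saturation structure; spectrum-level work should use
  `simulate_pulse_train()`.
* Solute pool defaults are placeholders, not literature calibrations.
* No between-subject biological variability, so synthetic group
  statistics (e.g. Welch p values) are far "cleaner" than in vivo ones.
* The semi-solid MT pool uses a Lorentzian line, not a super-Lorentzian.
* Adding an exchanging solute can *raise* water Z marginally at the
  exact DWS centre (back-exchange from the less-saturated solute); the
  "solute only removes signal" property holds everywhere water is not
  already ≳99% saturated.
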