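#' Fit an inverted Lorentzian to the direct-water-saturation dip
#'
#' Least-squares fit of `Z(w) = b - d * (G/2)^2 / ((G/2)^2 + (w - delta)^2)`
#' to a Z-spectrum; the fitted centre `delta` is the apparent water
#' resonance and hence the per-pixel B0 shift. Initialisation is taken from
#' the discrete grid minimum; the centre is bounded to +/-1 ppm and the
#' FWHM to 0.2-4 ppm so the fit locks onto the water dip rather than a
#' solute dip. Failures (no discernible dip, non-convergence, centre at the
#' search bound) are flagged rather than raised, so pixel loops can
#' continue.
#'
#' @param zspec A `zspectrum` (>= 5 offsets spanning the dip).
#' @param init Optional named list overriding initial values
#'   (`center_ppm`, `fwhm_ppm`, `depth`, `baseline`).
#' @param center_bound_ppm,fwhm_range_ppm Fit bounds.
#' @param min_depth Minimum grid dip depth below which the spectrum is
#'   declared flat and flagged.
#' @return Object of class `lorentzian_fit`: `center_ppm`, `fwhm_ppm`,
#'   `depth`, `baseline`, `residual_rms`, `ok` (FALSE = flagged).
#' @export
fit_dws <- function(zspec, init = NULL, center_bound_ppm = 1,
                    fwhm_range_ppm = c(0.2, 4), min_depth = 0.05) {
  stopifnot(inherits(zspec, "zspectrum"))
  w <- zspec$offsets_ppm; z <- zspec$z
  if (length(w) < 5) stop("fit_dws: need at least 5 offsets")
  flagged <- function() structure(
    list(center_ppm = NA_real_, fwhm_ppm = NA_real_, depth = NA_real_,
         baseline = NA_real_, residual_rms = NA_real_, ok = FALSE),
    class = "lorentzian_fit")
  base0 <- stats::quantile(z, 0.9, names = FALSE)
  depth0 <- base0 - min(z)
  if (!is.finite(depth0) || depth0 < min_depth) return(flagged())
  st <- list(center_ppm = w[which.min(z)], fwhm_ppm = 1,
             depth = depth0, baseline = base0)
  st[names(init)] <- init
  step <- stats::median(diff(sort(w)))
  fit <- NULL
  # a start exactly on a symmetric optimum can give a singular initial
  # gradient; retry from slightly perturbed starts
  for (jit in c(0, 0.25, -0.25) * step) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ baseline - depth * (fwhm / 2)^2 / ((fwhm / 2)^2 + (w - center)^2),
        data = data.frame(w = w, z = z),
        start = list(center = st$center_ppm + jit, fwhm = st$fwhm_ppm,
                     depth = st$depth, baseline = st$baseline),
        lower = c(-center_bound_ppm, fwhm_range_ppm[1], 0, 0),
        upper = c(center_bound_ppm, fwhm_range_ppm[2], 2, 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(flagged())
  cf <- stats::coef(fit)
  if (abs(cf["center"]) >= center_bound_ppm * 0.999 ||
      cf["center"] < min(w) || cf["center"] > max(w)) return(flagged())
  structure(list(center_ppm = unname(cf["center"]),
                 fwhm_ppm = unname(cf["fwhm"]),
                 depth = unname(cf["depth"]),
                 baseline = unname(cf["baseline"]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)), ok = TRUE),
            class = "lorentzian_fit")
}

#' Per-pixel Z-spectra from a full-sweep series
#'
#' Normalises each measure image of a full Z-spectrum acquisition by the
#' pixel-wise mean of the (non-dummy) S0 images, giving a Z cube.
#'
#' @param series A pixel-rendered `dynamic_series` whose schedule sweeps a
#'   full offset grid.
#' @return List: `offsets_ppm` (ascending), `z` (grid x grid x n_offsets).
#' @export
zspectra_from_series <- function(series) {
  e <- series$entries
  i_s0 <- which(e$role == "s0")
  if (length(i_s0) < 1) stop("zspectra_from_series: no S0 entries")
  keep <- which(e$role == "measure" & e$retain)
  if (length(keep) == 0) keep <- which(e$role == "measure")
  ord <- keep[order(e$offset_ppm[keep])]
  img <- series$images
  s0 <- apply(img[, , i_s0, drop = FALSE], c(1, 2), mean)
  z <- img[, , ord, drop = FALSE] / as.vector(s0)
  list(offsets_ppm = e$offset_ppm[ord], z = z)
}

#' B0-shift map from per-pixel Z-spectra
#'
#' Fits the inverted Lorentzian water dip pixel-by-pixel over a mask and
#' returns the fitted centre (ppm) as the B0 shift for that pixel. More
#' than 20% flagged pixels triggers a warning.
#'
#' @param zcube List as returned by [zspectra_from_series()], or a
#'   grid x grid x n_offsets array.
#' @param offsets_ppm Offsets for an array `zcube`.
#' @param mask Logical matrix of pixels to fit.
#' @param ... Passed to [fit_dws()].
#' @return Object of class `b0_map`: `shift_ppm` (matrix, NA outside mask
#'   and at flagged pixels), `flagged` (logical matrix), `frac_flagged`.
#' @export
b0_map <- function(zcube, offsets_ppm = NULL, mask = NULL, ...) {
  if (is.list(zcube) && !is.null(zcube$z)) {
    offsets_ppm <- zcube$offsets_ppm; zcube <- zcube$z
  }
  stopifnot(length(dim(zcube)) == 3, length(offsets_ppm) == dim(zcube)[3])
  g <- dim(zcube)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, g[1], g[2])
  shift <- matrix(NA_real_, g[1], g[2])
  flag <- matrix(FALSE, g[1], g[2])
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    zs <- structure(list(offsets_ppm = offsets_ppm,
                         z = zcube[idx[r, 1], idx[r, 2], ],
                         reference_offset_ppm = 333), class = "zspectrum")
    ft <- fit_dws(zs, ...)
    if (ft$ok) shift[idx[r, 1], idx[r, 2]] <- ft$center_ppm
    else flag[idx[r, 1], idx[r, 2]] <- TRUE
  }
  frac <- sum(flag[mask]) / sum(mask)
  if (frac > 0.2)
    warning(sprintf("b0_map: %.0f%% of masked pixels flagged", 100 * frac))
  structure(list(shift_ppm = shift, flagged = flag, frac_flagged = frac),
            class = "b0_map")
}

# sweep index of each retained entry of each offset (k-th retained
# occurrence of an offset belongs to sweep k)
sweep_index <- function(entries) {
  keep <- entries$retain & entries$role == "measure"
  idx <- integer(nrow(entries))
  for (off in unique(entries$offset_ppm[keep])) {
    sel <- which(keep & entries$offset_ppm == off)
    idx[sel] <- seq_along(sel)
  }
  idx
}

#' Partial Z-spectral time-offset map
#'
#' For a cohort acquired under a shared partial-sweep schedule, runs the
#' normalisation/MTR pipeline per subject and per tracked offset, arranges
#' the retained MTR values as an offsets x sweeps matrix per subject, and
#' averages across subjects. Each column is one sweep; its timestamp is
#' the midpoint of the sweep's retained entries (a cell spans the sweep
#' duration).
#'
#' @param series_list List of `dynamic_series` sharing one partial
#'   schedule.
#' @param roi ROI name or mask.
#' @param injection_start_min,pre_start_min See [mtr_curve()].
#' @return Object of class `partial_map`: `offsets_ppm` (in swept order),
#'   `times_min` (per sweep), `mtr_avg` (offsets x sweeps group mean),
#'   `sd`, `n`, `subject_maps` (list of per-subject matrices).
#' @export
partial_map <- function(series_list, roi = "liver",
                        injection_start_min = 23, pre_start_min = 0) {
  stopifnot(length(series_list) >= 1)
  e0 <- series_list[[1]]$entries
  for (s in series_list)
    if (nrow(s$entries) != nrow(e0) ||
        any(s$entries$offset_ppm != e0$offset_ppm))
      stop("partial_map: subjects do not share the schedule")
  keep <- e0$retain & e0$role == "measure"
  offs <- unique(e0$offset_ppm[keep])          # swept order
  swp <- sweep_index(e0)
  n_sweeps <- max(swp)
  t_mat <- matrix(NA_real_, length(offs), n_sweeps)
  for (i in seq_along(offs)) {
    sel <- which(keep & e0$offset_ppm == offs[i])
    t_mat[i, swp[sel]] <- e0$t_mid_s[sel] / 60
  }
  times_min <- colMeans(t_mat, na.rm = TRUE)

  subject_maps <- lapply(series_list, function(s) {
    curves <- dynamic_mtr_curves(s, roi, injection_start_min, pre_start_min)
    m <- matrix(NA_real_, length(offs), n_sweeps)
    for (i in seq_along(offs)) {
      cv <- curves[[sprintf("%g", offs[i])]]
      m[i, ] <- cv$mtr
    }
    m
  })
  arr <- simplify2array(subject_maps)          # offsets x sweeps x subjects
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(series_list) > 1) apply(arr, c(1, 2), stats::sd)
         else matrix(NA_real_, length(offs), n_sweeps)
  structure(list(offsets_ppm = offs, times_min = times_min, mtr_avg = mu,
                 sd = sdv, n = length(series_list),
                 subject_maps = subject_maps),
            class = "partial_map")
}

#' Extract one MTR profile from a partial map
#' @param pm A `partial_map`.
#' @param time_min Requested time; the nearest sweep is returned.
#' @return data.frame: offset_ppm, mtr_avg, sd, time_min.
#' @export
partial_profile <- function(pm, time_min) {
  stopifnot(inherits(pm, "partial_map"))
  j <- which.min(abs(pm$times_min - time_min))
  data.frame(offset_ppm = pm$offsets_ppm, mtr_avg = pm$mtr_avg[, j],
             sd = pm$sd[, j], time_min = pm$times_min[j])
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  if (!x$ok) cat("<lorentzian_fit> flagged (no fit)\n")
  else cat(sprintf("<lorentzian_fit> center %+.4f ppm, FWHM %.2f ppm, depth %.3f, baseline %.3f\n",
                   x$center_ppm, x$fwhm_ppm, x$depth, x$baseline))
  invisible(x)
}
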