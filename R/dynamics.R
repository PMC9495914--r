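#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with polynomial-fit edge handling
#' (the boundary rows of the Savitzky-Golay projection matrix). Note that
#' window 3 with order 2 — the S0-baseline setting of the protocol — fits a
#' quadratic exactly through every 3 points and is therefore the identity
#' transform; larger windows smooth.
#'
#' @param values Numeric vector (length >= `window`).
#' @param window Odd window size.
#' @param order Polynomial order (< `window`).
#' @return Filtered vector, same length.
#' @export
sg_filter <- function(values, window = 3, order = 2) {
  if (window %% 2 != 1) stop("sg_filter: window must be odd")
  if (order >= window) stop("sg_filter: order must be < window")
  if (length(values) < window)
    stop("sg_filter: need at least `window` values")
  as.numeric(signal::sgolayfilt(values, p = order, n = window))
}

roi_mask <- function(series, roi = "liver") {
  if (is.matrix(roi) || is.logical(roi)) return(roi)
  m <- series$masks[[roi]]
  if (is.null(m)) stop("unknown ROI '", roi, "'")
  m
}

# ROI-mean signal per entry: images is grid x grid x n
roi_means <- function(series, roi = "liver") {
  m <- roi_mask(series, roi)
  idx <- which(m)
  img <- series$images
  dim(img) <- c(prod(dim(img)[1:2]), dim(img)[3])
  colMeans(img[idx, , drop = FALSE])
}

#' S0 baseline curve
#'
#' ROI-mean intensities of the (non-dummy) S0 images, Savitzky-Golay
#' filtered, then linearly interpolated in time to every entry of the
#' series; beyond the first/last S0 image the boundary value is held. The
#' result is the normalisation denominator `S0,SG` for every image.
#'
#' @param series A `dynamic_series`.
#' @param roi ROI name or logical mask.
#' @param window,order Savitzky-Golay settings (protocol default 3 / 2).
#' @return Object of class `baseline_curve`: `times_s` (all entries),
#'   `s0_sg` (baseline at those times), `s0_times_s`, `s0_values`.
#' @export
build_s0_baseline <- function(series, roi = "liver", window = 3, order = 2) {
  e <- series$entries
  i_s0 <- which(e$role == "s0")
  if (length(i_s0) < 2)
    stop("build_s0_baseline: need at least 2 non-dummy S0 entries")
  s <- roi_means(series, roi)
  s0 <- s[i_s0]
  s0_f <- if (length(s0) >= window) sg_filter(s0, window, order) else s0
  base <- stats::approx(e$t_mid_s[i_s0], s0_f, xout = e$t_mid_s,
                        rule = 2)$y
  if (any(base <= 0)) stop("build_s0_baseline: non-positive baseline")
  structure(list(times_s = e$t_mid_s, s0_sg = base,
                 s0_times_s = e$t_mid_s[i_s0], s0_values = s0_f),
            class = "baseline_curve")
}

#' Normalise retained images against the S0 baseline
#'
#' `Z = S / S0,SG` at each retained measure entry, using the ROI-mean
#' signal. Because both numerator and denominator carry the same
#' multiplicative drift, this cancels slow signal drift.
#'
#' @param series A `dynamic_series`.
#' @param baseline A `baseline_curve` (built with [build_s0_baseline()]).
#' @param roi ROI name or logical mask.
#' @return data.frame: index, t_min, offset_ppm, Z (retained entries only).
#' @export
normalize_series <- function(series, baseline = NULL, roi = "liver") {
  if (is.null(baseline)) baseline <- build_s0_baseline(series, roi)
  if (any(baseline$s0_sg <= 0)) stop("normalize_series: non-positive baseline")
  e <- series$entries
  keep <- e$retain & e$role == "measure"
  s <- roi_means(series, roi)
  data.frame(index = e$index[keep], t_min = e$t_mid_s[keep] / 60,
             offset_ppm = e$offset_ppm[keep],
             Z = s[keep] / baseline$s0_sg[keep])
}

#' Pre-injection-referenced MTR curve
#'
#' `MTR = Z_pre,avg - Z`, where `Z_pre,avg` is the mean of Z over the
#' pre-injection retained points. Positive MTR means saturation-induced
#' signal loss. The pre-injection average may optionally skip early points
#' acquired before the saturation steady state settles.
#'
#' @param z Z values (one tracked offset).
#' @param times_min Times of the retained points, minutes.
#' @param injection_start_min Injection start, minutes.
#' @param pre_start_min Earliest time admitted to the pre-injection
#'   average (default 0 = use all pre-injection points).
#' @param label Curve label (ROI/pixel/offset).
#' @return Object of class `mtr_curve`: `times_min`, `z`, `z_pre_avg`,
#'   `mtr`, `label`.
#' @export
mtr_curve <- function(z, times_min, injection_start_min = 23,
                      pre_start_min = 0, label = "") {
  stopifnot(length(z) == length(times_min))
  pre <- times_min < injection_start_min & times_min >= pre_start_min
  if (!any(pre)) stop("mtr_curve: no pre-injection retained points")
  z_pre_avg <- mean(z[pre])
  structure(list(times_min = times_min, z = z, z_pre_avg = z_pre_avg,
                 mtr = z_pre_avg - z, label = label,
                 injection_start_min = injection_start_min),
            class = "mtr_curve")
}

#' Dynamic MTR curves of a series, per tracked offset
#'
#' Runs the full normalisation pipeline (S0 baseline, `Z = S/S0,SG`,
#' `MTR = Z_pre,avg - Z`) on the ROI-mean signal and splits the result by
#' tracked saturation offset.
#'
#' @param series A `dynamic_series`.
#' @param roi ROI name or logical mask.
#' @param injection_start_min,pre_start_min See [mtr_curve()].
#' @param window,order S0 Savitzky-Golay settings.
#' @return Named list of `mtr_curve`, one per tracked offset.
#' @export
dynamic_mtr_curves <- function(series, roi = "liver",
                               injection_start_min = 23, pre_start_min = 0,
                               window = 3, order = 2) {
  zs <- normalize_series(series,
                         build_s0_baseline(series, roi, window, order), roi)
  out <- list()
  for (off in unique(zs$offset_ppm)) {
    sel <- zs$offset_ppm == off
    out[[sprintf("%g", off)]] <-
      mtr_curve(zs$Z[sel], zs$t_min[sel], injection_start_min,
                pre_start_min, label = sprintf("%g ppm", off))
  }
  out
}

#' Tidy data.frame of MTR curves
#' @param curves Named list of `mtr_curve` (e.g. from
#'   [dynamic_mtr_curves()]).
#' @param group Optional group label column.
#' @return data.frame: time_min, offset_ppm, Z, MTR, label, group.
#' @export
mtr_curves_df <- function(curves, group = NA_character_) {
  do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(time_min = cv$times_min, offset_ppm = as.numeric(nm),
               Z = cv$z, MTR = cv$mtr, label = cv$label, group = group)
  }))
}

# trapezoid integral of curve (t, y) over [a, b] with linear endpoint
# interpolation; t ascending, [a, b] within range(t)
trapz_window <- function(t, y, a, b) {
  if (a >= b) stop("empty integration window")
  if (a < min(t) - 1e-9 || b > max(t) + 1e-9)
    stop("integration window outside the curve time range")
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(stats::approx(t, y, a, rule = 2)$y, y[inside],
          stats::approx(t, y, b, rule = 2)$y)
  pracma::trapz(tt, yy)
}

#' Area under an MTR curve within a time window
#'
#' @param curve An `mtr_curve`.
#' @param window_min Closed interval `c(t1, t2)` in minutes, within the
#'   curve's time range; endpoints are linearly interpolated.
#' @return AUC in MTR x minutes.
#' @export
mtr_auc <- function(curve, window_min) {
  stopifnot(inherits(curve, "mtr_curve"), length(window_min) == 2)
  trapz_window(curve$times_min, curve$mtr, window_min[1], window_min[2])
}

#' Pixel-wise AUC map
#'
#' Applies the normalisation/MTR pipeline per pixel — per-pixel S0
#' baseline (Savitzky-Golay + linear interpolation), `Z = S/S0,SG`,
#' `MTR = Z_pre,avg - Z` — for one tracked offset, then integrates MTR over
#' the requested window (trapezoidal, minutes).
#'
#' @param series A `dynamic_series` (pixel-rendered).
#' @param window_min `c(t1, t2)` minutes, within the scan.
#' @param offset_ppm Tracked offset whose curve is integrated.
#' @param roi ROI name or mask; pixels outside are NA.
#' @param injection_start_min,pre_start_min,window,order As elsewhere.
#' @return Object of class `auc_map`: `values` (matrix, NA outside ROI),
#'   `window_min`, `offset_ppm`.
#' @export
pixelwise_auc <- function(series, window_min, offset_ppm = -2.7,
                          roi = "liver", injection_start_min = 23,
                          pre_start_min = 0, window = 3, order = 2) {
  stopifnot(length(window_min) == 2)
  if (window_min[1] >= window_min[2]) stop("pixelwise_auc: empty window")
  e <- series$entries
  m <- roi_mask(series, roi)
  idx <- which(m)
  img <- series$images
  g <- dim(img)[1:2]
  dim(img) <- c(prod(g), dim(img)[3])
  S <- img[idx, , drop = FALSE]              # px x entries

  i_s0 <- which(e$role == "s0")
  if (length(i_s0) < 2) stop("pixelwise_auc: need >= 2 S0 entries")
  keep <- which(e$retain & e$role == "measure" & e$offset_ppm == offset_ppm)
  if (length(keep) == 0) stop("pixelwise_auc: offset not tracked in schedule")
  t_keep <- e$t_mid_s[keep] / 60
  if (window_min[1] < min(t_keep) || window_min[2] > max(t_keep))
    stop("pixelwise_auc: window outside the retained time range")
  pre <- t_keep < injection_start_min & t_keep >= pre_start_min
  if (!any(pre)) stop("pixelwise_auc: no pre-injection points")

  t_s0 <- e$t_mid_s[i_s0]
  vals <- matrix(NA_real_, g[1], g[2])
  auc <- numeric(length(idx))
  for (p in seq_along(idx)) {
    s0 <- S[p, i_s0]
    s0_f <- if (length(s0) >= window) sg_filter(s0, window, order) else s0
    base <- stats::approx(t_s0, s0_f, xout = e$t_mid_s[keep], rule = 2)$y
    z <- S[p, keep] / base
    mtr <- mean(z[pre]) - z
    auc[p] <- trapz_window(t_keep, mtr, window_min[1], window_min[2])
  }
  vals[idx] <- auc
  structure(list(values = vals, window_min = window_min,
                 offset_ppm = offset_ppm),
            class = "auc_map")
}

#' Group-average MTR curve
#'
#' Pointwise mean and sample standard deviation across subjects' curves
#' (common time grid required), plus a display-smoothed mean (Savitzky-
#' Golay window 7, order 2). With a single curve the SD is undefined and
#' returned as NA with a warning.
#'
#' @param curves List of `mtr_curve` on a common time grid.
#' @param smooth_window,smooth_order Display smoothing settings.
#' @return Object of class `mtr_group_curve`: `times_min`, `mean`, `sd`,
#'   `n`, `mean_smoothed`.
#' @export
group_average <- function(curves, smooth_window = 7, smooth_order = 2) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, what = "mtr_curve")))
  t0 <- curves[[1]]$times_min
  for (cv in curves)
    if (length(cv$times_min) != length(t0) || any(cv$times_min != t0))
      stop("group_average: curves are not on a common time grid")
  M <- do.call(cbind, lapply(curves, function(cv) cv$mtr))
  mu <- rowMeans(M)
  if (length(curves) == 1) {
    warning("group_average: single curve, SD undefined")
    sdv <- rep(NA_real_, length(mu))
  } else {
    sdv <- apply(M, 1, stats::sd)
  }
  sm <- if (length(mu) >= smooth_window)
    sg_filter(mu, smooth_window, smooth_order) else mu
  structure(list(times_min = t0, mean = mu, sd = sdv, n = length(curves),
                 mean_smoothed = sm),
            class = "mtr_group_curve")
}

#' @export
print.mtr_curve <- function(x, ...) {
  cat(sprintf("<mtr_curve %s> %d points, %.1f-%.1f min, Zpre %.4f, peak MTR %.3f%%\n",
              x$label, length(x$mtr), min(x$times_min), max(x$times_min),
              x$z_pre_avg, 100 * max(x$mtr)))
  invisible(x)
}
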