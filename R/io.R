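#' Write a dynamic series to disk
#'
#' One 4D NIfTI volume stack (one volume per schedule entry), a JSON
#' sidecar carrying the per-entry metadata (offset_ppm, role, instance,
#' retain, timestamps) — dynamic CEST metadata has no standard header slot
#' — an integer-label mask volume (1 = liver), and, when present, the
#' ground-truth table as CSV and the generation parameters as YAML.
#'
#' @param series A `dynamic_series`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_series <- function(series, dir, prefix = "series") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  RNifti::writeNifti(series$images, p(".nii.gz"))
  jsonlite::write_json(as.data.frame(series$entries), p(".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  lab <- matrix(0L, nrow(series$masks$liver), ncol(series$masks$liver))
  lab[series$masks$liver] <- 1L
  RNifti::writeNifti(lab, p("_masks.nii.gz"))
  paths <- c(p(".nii.gz"), p(".json"), p("_masks.nii.gz"))
  if (!is.null(series$ground_truth)) {
    utils::write.csv(series$ground_truth, p("_truth.csv"), row.names = FALSE)
    paths <- c(paths, p("_truth.csv"))
  }
  if (!is.null(series$params)) {
    yaml::write_yaml(rapply(series$params, unclass, how = "replace"),
                     p("_params.yaml"))
    paths <- c(paths, p("_params.yaml"))
  }
  invisible(paths)
}

#' Read a dynamic series from disk
#'
#' Inverse of [write_series()]: checks that the sidecar entry count
#' matches the number of volumes and that masks share the image grid.
#'
#' @param dir Directory written by [write_series()].
#' @param prefix File name prefix.
#' @param timing Timing parameters to reattach to the schedule.
#' @return A `dynamic_series`.
#' @export
read_series <- function(dir, prefix = "series", timing = timing_params()) {
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  for (f in c(p(".nii.gz"), p(".json"), p("_masks.nii.gz")))
    if (!file.exists(f)) stop("read_series: missing file ", f)
  img <- RNifti::readNifti(p(".nii.gz"))
  images <- array(as.numeric(img), dim = dim(img))
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1L)
  entries <- jsonlite::fromJSON(p(".json"))
  entries$role <- as.character(entries$role)
  if (nrow(entries) != dim(images)[3])
    stop(sprintf("read_series: %d sidecar entries but %d volumes (%s, %s)",
                 nrow(entries), dim(images)[3], p(".json"), p(".nii.gz")))
  class(entries) <- c("acq_schedule", "data.frame")
  attr(entries, "timing") <- timing
  lab <- RNifti::readNifti(p("_masks.nii.gz"))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (!all(dim(lab) == dim(images)[1:2]))
    stop("read_series: mask grid does not match image grid")
  gt <- if (file.exists(p("_truth.csv"))) utils::read.csv(p("_truth.csv"))
        else NULL
  structure(list(images = images, entries = entries,
                 masks = list(liver = lab == 1L, background = lab == 0L),
                 ground_truth = gt, params = NULL),
            class = "dynamic_series")
}

default_config <- function() {
  list(
    seed = 1L,
    outdir = "cestdyn_out",
    schedule = list(name = "fl1", n_cycles = 98),
    groups = list(test = 5L, control = 5L),
    render = "roi",
    grid = 96L,
    uptake = list(spike_amplitude_mtr = 0.0064, spike_peak_delay_min = 7,
                  accumulation_slope_mtr_per_min = 5e-5,
                  injection_start_min = 23),
    artifacts = list(drift_hz_per_min = 0.5,
                     signal_drift_frac_per_min = 2e-4,
                     motion_onset_min = 60, motion_amplitude_mtr = 0.003),
    noise = list(sigma_frac = 0.005, distribution = "rician"),
    auc_windows = list(c(8, 23), c(24, 39), c(65, 80), c(105, 120)),
    compare_time_min = 30,
    pre_start_min = 8
  )
}

config_schedule <- function(cfg) {
  sc <- cfg$schedule
  switch(sc$name,
         fl1 = build_fl1(n_cycles = sc$n_cycles %||% 98),
         fl2 = build_partial_list(-4.3, -1.1, n_cycles = sc$n_cycles %||% 35),
         fl3 = build_partial_list(4.2, 3.0, n_cycles = sc$n_cycles %||% 35),
         full = stop("full Z-spectrum schedules are handled by b0_map inputs"),
         stop("unknown schedule '", sc$name, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(cfg) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, cfg)
  if (!cfg$schedule$name %in% c("fl1", "fl2", "fl3"))
    stop("config: schedule$name must be fl1, fl2 or fl3")
  if (!cfg$render %in% c("roi", "pixel"))
    stop("config: render must be 'roi' or 'pixel'")
  stopifnot(cfg$groups$test >= 1, cfg$groups$control >= 1)
  cfg
}

#' Run the full synthetic study pipeline
#'
#' Simulates test and control cohorts under one configuration, then runs
#' the analysis chain: dynamic MTR curves and group averages, partial
#' Z-spectral maps and a cell-wise Welch significance map (for partial
#' schedules), AUC values, Welch and paired t-tests, and a run log. All
#' tables are written as CSV, figures as PNG, and the resolved
#' configuration as YAML next to the outputs, so every artifact is
#' regenerable from the stored config.
#'
#' @param config Path to a YAML config file, or a config list; omitted
#'   keys fall back to defaults (see the `cestdyn-methods` vignette).
#' @param seed Overrides the config seed.
#' @param outdir Overrides the config output directory.
#' @return Invisibly, a list with the cohorts, curves, maps and tests.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cfg <- stage("config", {
    if (is.character(config)) config <- yaml::read_yaml(config)
    validate_config(config)
  })
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config_resolved.yaml"))

  sched <- stage("schedule", config_schedule(cfg))
  inj <- cfg$uptake$injection_start_min

  sim <- stage("simulate", {
    up <- do.call(uptake_model, cfg$uptake)
    art <- do.call(artifact_model, cfg$artifacts)
    nz <- do.call(noise_model, c(cfg$noise, list(seed = cfg$seed)))
    list(test = generate_group(cfg$groups$test, base_seed = cfg$seed,
                               noise = nz, schedule = sched, uptake = up,
                               artifacts = art, render = cfg$render,
                               grid = cfg$grid),
         control = generate_group(cfg$groups$control,
                                  base_seed = cfg$seed + 1000L, noise = nz,
                                  schedule = sched,
                                  uptake = control_uptake_model(inj),
                                  artifacts = art, render = cfg$render,
                                  grid = cfg$grid))
  })

  res <- stage("dynamics", {
    curves <- lapply(sim, function(grp) lapply(grp, dynamic_mtr_curves,
                                               injection_start_min = inj,
                                               pre_start_min = cfg$pre_start_min))
    offs <- names(curves$test[[1]])
    groups <- lapply(curves, function(grp) {
      gl <- lapply(offs, function(o)
        group_average(lapply(grp, `[[`, o)))
      names(gl) <- offs
      gl
    })
    df <- rbind(
      do.call(rbind, lapply(seq_along(curves$test), function(i)
        transform(mtr_curves_df(curves$test[[i]], "test"), subject = i))),
      do.call(rbind, lapply(seq_along(curves$control), function(i)
        transform(mtr_curves_df(curves$control[[i]], "control"), subject = i))))
    utils::write.csv(df, file.path(cfg$outdir, "mtr_curves.csv"),
                     row.names = FALSE)
    list(curves = curves, groups = groups)
  })

  pmaps <- NULL
  if (cfg$schedule$name %in% c("fl2", "fl3")) {
    pmaps <- stage("zspec", {
      pm_t <- partial_map(sim$test, injection_start_min = inj,
                          pre_start_min = cfg$pre_start_min)
      pm_c <- partial_map(sim$control, injection_start_min = inj,
                          pre_start_min = cfg$pre_start_min)
      sg <- significance_map(pm_t, pm_c)
      utils::write.csv(pm_t$mtr_avg,
                       file.path(cfg$outdir, "partial_map_test.csv"),
                       row.names = FALSE)
      utils::write.csv(pm_c$mtr_avg,
                       file.path(cfg$outdir, "partial_map_control.csv"),
                       row.names = FALSE)
      utils::write.csv(sg$p_values,
                       file.path(cfg$outdir, "partial_map_pvalues.csv"),
                       row.names = FALSE)
      list(test = pm_t, control = pm_c, signif = sg)
    })
  }

  tests <- stage("stats", {
    off0 <- names(res$curves$test[[1]])[1]
    at_time <- function(grp, t) vapply(grp, function(cvs) {
      cv <- cvs[[off0]]
      cv$mtr[which.min(abs(cv$times_min - t))]
    }, 0)
    t_cmp <- cfg$compare_time_min
    out <- list()
    out[[sprintf("test_vs_control_%gmin", t_cmp)]] <-
      welch_t(at_time(res$curves$test, t_cmp),
              at_time(res$curves$control, t_cmp))
    # within-group comparisons against the 20-min pre-injection point,
    # only where the grid actually distinguishes the two times
    grid_t <- res$curves$test[[1]][[off0]]$times_min
    nearest <- function(t) grid_t[which.min(abs(grid_t - t))]
    pre_t <- at_time(res$curves$test, 20)
    for (t_post in c(30, 60)) {
      if (nearest(t_post) == nearest(20)) next
      nm <- sprintf("test_%gmin_vs_20min", t_post)
      out[[nm]] <- paired_t(pre_t, at_time(res$curves$test, t_post))
    }
    df <- tests_df(out)
    utils::write.csv(df, file.path(cfg$outdir, "tests.csv"),
                     row.names = FALSE)
    out
  })

  stage("report", {
    log <- c(sprintf("cestdyn %s", as.character(utils::packageVersion("cestdyn"))),
             sprintf("seed %d", cfg$seed),
             sprintf("schedule %s (%d entries)", cfg$schedule$name, nrow(sched)),
             sprintf("groups test=%d control=%d render=%s",
                     cfg$groups$test, cfg$groups$control, cfg$render),
             sprintf("R %s", as.character(getRversion())))
    writeLines(log, file.path(cfg$outdir, "run_log.txt"))
    off0 <- names(res$groups$test)[1]
    plot_group_curves(res$groups$test[[off0]], res$groups$control[[off0]],
                      file.path(cfg$outdir, "mtr_group_curves.png"), inj)
    if (!is.null(pmaps))
      plot_partial_map(pmaps$test,
                       file.path(cfg$outdir, "partial_map_test.png"))
  })

  invisible(list(config = cfg, cohorts = sim, curves = res$curves,
                 groups = res$groups, partial = pmaps, tests = tests))
}

plot_group_curves <- function(g_test, g_ctrl, path, injection_start_min) {
  grDevices::png(path, width = 900, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  yl <- range(c(g_test$mean, g_ctrl$mean)) * 100
  graphics::plot(g_test$times_min, 100 * g_test$mean, type = "l",
                 col = "firebrick", lwd = 2, ylim = yl,
                 xlab = "time (min)", ylab = "MTR (%)",
                 main = "Group-average dynamic MTR")
  graphics::lines(g_ctrl$times_min, 100 * g_ctrl$mean, col = "steelblue",
                  lwd = 2)
  graphics::abline(v = injection_start_min, lty = 2, col = "darkgreen")
  graphics::legend("topleft", c("test", "control"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
}

plot_partial_map <- function(pm, path) {
  grDevices::png(path, width = 900, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  graphics::image(pm$times_min, seq_along(pm$offsets_ppm),
                  t(pm$mtr_avg) * 100,
                  xlab = "time (min)", ylab = "offset (ppm)", yaxt = "n",
                  main = "Partial Z-spectral MTR map (%)",
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::axis(2, at = seq_along(pm$offsets_ppm),
                 labels = sprintf("%g", pm$offsets_ppm))
}

#' Render an AUC map as PNG
#' @param map An `auc_map`.
#' @param path Output PNG path.
#' @export
plot_auc_map <- function(map, path) {
  grDevices::png(path, width = 600, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  v <- map$values
  graphics::image(v, useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("AUC %g-%g min (MTR x min)",
                                 map$window_min[1], map$window_min[2]))
}
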