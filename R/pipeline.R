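#' Pipeline configuration
#'
#' Bundles the stage parameters with their standard defaults: threshold
#' multiplier 3, displacement grid 0.75 um, lifetime fit window 30-150 s,
#' autocorrelation fit window 10-80 s and maximum lag 480 s, MSD fit window
#' 2-200 s and maximum lag 900 s.
#'
#' @param sim a [sim_config()] describing the synthetic dataset (or NULL when
#'   reconstructing from images).
#' @param images optional path to a multi-page TIFF of bead images to
#'   reconstruct instead of simulating.
#' @param gprime,nu,E gel parameters (E derived from G' when not given).
#' @param grid_spacing displacement/traction grid spacing (um).
#' @param px_size pixel size for image input (um/pixel).
#' @param dt frame interval (s); defaults to the simulator's.
#' @param lambda FTTC Tikhonov parameter.
#' @param multiplier threshold-to-noise ratio.
#' @param t_smooth trajectory smoothing time (s).
#' @param link_dist peak linking distance (um).
#' @param peak_min_sep peak detection minimum separation (um).
#' @param lifetime_window,acorr_window,msd_window fit windows (s).
#' @param acorr_max_lag,msd_max_lag maximum lags (s).
#' @param seed seed for any stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), images = NULL,
                            gprime = 100, nu = 0.45, E = NULL,
                            grid_spacing = 0.75, px_size = 0.15, dt = NULL,
                            lambda = 0, multiplier = 3, t_smooth = 360,
                            link_dist = 2, peak_min_sep = 2,
                            lifetime_window = c(30, 150),
                            acorr_window = c(10, 80), msd_window = c(2, 200),
                            acorr_max_lag = 480, msd_max_lag = 900,
                            seed = 1L) {
  gel <- gel_substrate(gprime = gprime, nu = nu, E = E)
  if (is.null(dt)) dt <- if (!is.null(sim)) sim$dt else stop("dt required")
  stopifnot(grid_spacing > 0, dt > 0, lambda >= 0, multiplier > 0,
            link_dist > 0)
  structure(list(sim = sim, images = images, gel = gel,
                 grid_spacing = grid_spacing, px_size = px_size, dt = dt,
                 lambda = lambda, multiplier = multiplier,
                 t_smooth = t_smooth, link_dist = link_dist,
                 peak_min_sep = peak_min_sep,
                 lifetime_window = lifetime_window,
                 acorr_window = acorr_window, msd_window = msd_window,
                 acorr_max_lag = acorr_max_lag, msd_max_lag = msd_max_lag,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full growth-cone traction pipeline
#'
#' Stages: simulate (or reconstruct from bead images) -> localize ->
#' co-moving-frame average -> peak tracking and lifetimes -> tension
#' statistics. Every stage's output is written under `out_dir` together with
#' a run manifest (resolved configuration, package version, output checksums,
#' frames used/excluded). With a fixed seed the run is bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created). NULL skips all file output.
#' @return list with `maps`, `truth` (NULL for image input), `trajectory`,
#'   `average`, `tracks`, `lifetime_fit`, `tension`, `acorr`, `acorr_fit`,
#'   `msd`, `msd_fit`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  excluded <- list()
  if (!is.null(config$images)) {
    frames <- read_image_series(config$images)
    dc <- correct_drift(frames)
    ref <- compute_reference_image(dc$frames)
    maps <- lapply(seq_along(dc$frames), function(i) {
      disp <- measure_displacements(dc$frames[[i]], ref, config$px_size,
                                    grid_spacing = config$grid_spacing)
      disp$time <- (i - 1) * config$dt
      compute_traction(disp, config$gel, lambda = config$lambda)
    })
    truth <- NULL
  } else {
    sim <- simulate_traction_series(config$sim)
    maps <- sim$maps
    truth <- sim$truth
  }
  traj <- build_trajectory(maps, config$dt, multiplier = config$multiplier,
                           t_smooth = config$t_smooth)
  fr <- traj$frames
  usable <- which(!is.na(fr$valid) & fr$valid &
                    is.finite(fr$vx) & is.finite(fr$x_smooth))
  excluded$localization <- setdiff(seq_along(maps), usable)
  rotated <- lapply(usable, function(i)
    rotate_map_to_frame(maps[[i]], c(fr$x_smooth[i], fr$y_smooth[i]),
                        c(fr$vx[i], fr$vy[i])))
  average <- average_frames(rotated)

  detections <- lapply(maps, function(m)
    detect_peaks(m, estimate_noise(m, config$multiplier),
                 min_sep = config$peak_min_sep))
  tracks <- link_peaks(detections, config$dt, max_dist = config$link_dist)
  lifetime_fit <- tryCatch(
    fit_exponential_lifetime(lifetime_histogram(tracks),
                             window = config$lifetime_window),
    error = function(e) NULL)

  tens <- tension_series(maps, config$dt)
  acorr <- tryCatch(autocorrelation(tens, max_lag = config$acorr_max_lag),
                    error = function(e) NULL)
  acorr_fit <- if (!is.null(acorr))
    tryCatch(fit_autocorr_decay(acorr, window = config$acorr_window),
             error = function(e) NULL)
  msd_res <- tryCatch(suppressWarnings(msd(tens, max_lag = config$msd_max_lag)),
                      error = function(e) NULL)
  msd_fit <- if (!is.null(msd_res))
    tryCatch(fit_msd_exponent(msd_res, window = config$msd_window),
             error = function(e) NULL)

  manifest <- list(dt_s = config$dt, seed = config$seed,
                   gel = list(gprime_Pa = config$gel$gprime, nu = config$gel$nu,
                              E_Pa = config$gel$E),
                   lambda = config$lambda, multiplier = config$multiplier,
                   n_frames = length(maps),
                   frames_excluded = excluded$localization,
                   sign_convention = paste(
                     "traction is the stress exerted by the cell on the",
                     "substrate; axon tension is minus the net traction force"))
  res <- list(maps = maps, truth = truth, trajectory = traj, average = average,
              tracks = tracks, lifetime_fit = lifetime_fit, tension = tens,
              acorr = acorr, acorr_fit = acorr_fit, msd = msd_res,
              msd_fit = msd_fit, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_field_series(maps, file.path(out_dir, "traction"), "traction",
                       extra = list(seed = config$seed))
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    co <- field_coords(average)
    utils::write.csv(data.frame(x = rep(co$x, each = length(co$y)),
                                y = rep(co$y, times = length(co$x)),
                                tx_mean = as.vector(average$tx),
                                ty_mean = as.vector(average$ty),
                                count = as.vector(average$count)),
                     file.path(out_dir, "average_field.csv"), row.names = FALSE)
    .write_manifest(file.path(out_dir, "average_field.json"),
                    list(net_force_nN = average$net_force,
                         n_frames = average$n_frames))
    write_tracks(tracks, file.path(out_dir, "peaks"), fit = lifetime_fit)
    utils::write.csv(data.frame(t = tens$t, F = tens$F),
                     file.path(out_dir, "tension.csv"), row.names = FALSE)
    if (!is.null(acorr))
      utils::write.csv(data.frame(lag = acorr$lag, R = acorr$R),
                       file.path(out_dir, "autocorrelation.csv"),
                       row.names = FALSE)
    if (!is.null(msd_res))
      utils::write.csv(data.frame(lag = msd_res$lag, msd = msd_res$msd),
                       file.path(out_dir, "msd.csv"), row.names = FALSE)
    .write_manifest(file.path(out_dir, "fits.json"),
                    list(lifetime_tau_s = if (!is.null(lifetime_fit))
                           lifetime_fit$tau else NA,
                         acorr_decay_s = if (!is.null(acorr_fit))
                           acorr_fit$tau else NA,
                         msd_exponent = if (!is.null(msd_fit))
                           msd_fit$exponent else NA))
    outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(outputs))
    names(manifest$checksums) <- list.files(out_dir, recursive = TRUE)
    .write_manifest(file.path(out_dir, "run_manifest.json"), manifest)
    res$manifest <- manifest
  }
  invisible(res)
}

#' Render a summary report of a pipeline run
#'
#' Six panels: trajectory overlay, average co-moving stress field, lifetime
#' histogram with log-linear fit, tension trace, autocorrelation, and MSD.
#' Panels whose stage is missing are replaced by a notice.
#'
#' @param result return value of [run_pipeline()].
#' @param file output PNG path.
#' @return `file`, invisibly.
#' @export
report <- function(result, file = "gctfm_report.png") {
  grDevices::png(file, width = 1500, height = 1000, res = 120)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  blank <- function(msg) {
    graphics::plot.new(); graphics::title(main = msg)
  }
  fr <- result$trajectory$frames
  graphics::plot(fr$x_raw, fr$y_raw, col = "grey60", pch = 1, asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = "Growth-cone trajectory")
  graphics::lines(fr$x_smooth, fr$y_smooth, col = "red", lwd = 2)
  avg <- result$average
  if (!is.null(avg)) {
    co <- field_coords(avg)
    mag <- sqrt(avg$tx^2 + avg$ty^2)
    graphics::image(co$x, co$y, t(mag), col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (um)", ylab = "y (um)", asp = 1,
                    main = "Average co-moving stress (Pa)")
    ii <- seq(1, length(co$y), by = 4); jj <- seq(1, length(co$x), by = 4)
    sc <- 2 / max(mag, na.rm = TRUE)
    for (i in ii) for (j in jj)
      if (is.finite(avg$tx[i, j]) && mag[i, j] > 0.2 * max(mag, na.rm = TRUE))
        graphics::arrows(co$x[j], co$y[i], co$x[j] + sc * avg$tx[i, j],
                         co$y[i] + sc * avg$ty[i, j], length = 0.03, col = "white")
  } else blank("no average field")
  if (nrow(result$tracks$tracks) > 0) {
    lh <- lifetime_histogram(result$tracks)
    sel <- lh$display & lh$counts > 0
    if (any(sel)) {
      graphics::plot(lh$mids[sel], lh$counts[sel], log = "y", pch = 16,
                     xlab = "lifetime (s)", ylab = "count",
                     main = "Stress-peak lifetimes")
      if (!is.null(result$lifetime_fit) && result$lifetime_fit$valid)
        graphics::abline(result$lifetime_fit$intercept / log(10),
                         result$lifetime_fit$slope / log(10), col = "red")
    } else blank("no tracks in display range")
  } else blank("no tracks")
  graphics::plot(result$tension$t, result$tension$F, type = "l",
                 xlab = "t (s)", ylab = "net force (nN)", main = "Tension")
  if (!is.null(result$acorr)) {
    graphics::plot(result$acorr$lag, result$acorr$R, type = "l",
                   xlab = "lag (s)", ylab = "R", main = "Autocorrelation")
    graphics::abline(h = 0, lty = 3)
  } else blank("no autocorrelation")
  if (!is.null(result$msd)) {
    pos <- result$msd$lag > 0 & result$msd$msd > 0
    graphics::plot(result$msd$lag[pos], result$msd$msd[pos], log = "xy",
                   type = "l", xlab = "lag (s)", ylab = "MSD (normalized)",
                   main = "Tension MSD")
  } else blank("no MSD")
  invisible(file)
}
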