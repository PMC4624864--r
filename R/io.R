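## Plain-text interchange: one CSV per frame plus a JSON manifest carrying the
## grid geometry, units and provenance.

.write_manifest <- function(path, fields) {
  jsonlite::write_json(c(list(package = "gctfm",
                              version = as.character(utils::packageVersion("gctfm"))),
                         fields),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a traction or displacement series as per-frame CSV + JSON manifest
#'
#' Each frame becomes `<prefix>_<frame>.csv` with columns x, y and either
#' tx, ty (Pa) or ux, uy (um); grid spacing, frame interval, units and any
#' extra provenance go into `<prefix>_manifest.json`.
#'
#' @param series list of `traction_map` or `displacement_field`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param extra named list merged into the manifest (e.g. seed, E, nu, lambda).
#' @return the manifest path, invisibly.
#' @export
write_field_series <- function(series, dir, prefix = "frame", extra = list()) {
  stopifnot(length(series) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_traction <- inherits(series[[1]], "traction_map")
  comp <- if (is_traction) c("tx", "ty") else c("ux", "uy")
  files <- character(length(series))
  for (i in seq_along(series)) {
    f <- series[[i]]
    co <- field_coords(f)
    df <- data.frame(x = rep(co$x, each = length(co$y)),
                     y = rep(co$y, times = length(co$x)),
                     c1 = as.vector(f[[comp[1]]]),
                     c2 = as.vector(f[[comp[2]]]))
    names(df)[3:4] <- comp
    files[i] <- file.path(dir, sprintf("%s_%04d.csv", prefix, i))
    utils::write.csv(df, files[i], row.names = FALSE)
  }
  dts <- vapply(series, function(f) f$time, numeric(1))
  .write_manifest(file.path(dir, paste0(prefix, "_manifest.json")),
                  c(list(kind = if (is_traction) "traction" else "displacement",
                         units = if (is_traction)
                           list(stress = "Pa", length = "um")
                         else list(displacement = "um", length = "um"),
                         spacing_um = series[[1]]$spacing,
                         origin_um = series[[1]]$origin,
                         n_frames = length(series),
                         timestamps_s = dts,
                         files = basename(files)),
                    extra))
}

#' Read a field series written by [write_field_series()]
#'
#' @param dir directory holding the CSVs and manifest.
#' @param prefix file-name prefix used when writing.
#' @return list of `traction_map` or `displacement_field`.
#' @export
read_field_series <- function(dir, prefix = "frame") {
  man <- jsonlite::read_json(file.path(dir, paste0(prefix, "_manifest.json")),
                             simplifyVector = TRUE)
  comp <- if (man$kind == "traction") c("tx", "ty") else c("ux", "uy")
  ctor <- if (man$kind == "traction") traction_map else displacement_field
  lapply(seq_len(man$n_frames), function(i) {
    df <- utils::read.csv(file.path(dir, man$files[i]))
    ny <- length(unique(df$y)); nx <- length(unique(df$x))
    ctor(matrix(df[[comp[1]]], ny, nx), matrix(df[[comp[2]]], ny, nx),
         spacing = man$spacing_um, origin = as.numeric(man$origin_um),
         time = man$timestamps_s[i])
  })
}

#' Write a growth-cone trajectory as CSV
#'
#' Columns: frame, t (s), x_raw, y_raw, x_smooth, y_smooth (um), vx, vy
#' (um/s), valid.
#'
#' @param traj a `gc_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gc_trajectory"))
  utils::write.csv(traj$frames, path, row.names = FALSE)
  invisible(path)
}

#' Write peak tracks, lifetimes and the lifetime fit
#'
#' @param tracks a `peak_tracks`.
#' @param fit optional `lifetime_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tracks <- function(tracks, dir, fit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tracks$detections, file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(tracks$tracks, file.path(dir, "lifetimes.csv"),
                   row.names = FALSE)
  if (!is.null(fit))
    .write_manifest(file.path(dir, "lifetime_fit.json"),
                    list(tau_s = fit$tau, tau_se_s = fit$tau_se,
                         window_s = fit$window, n_tracks = nrow(tracks$tracks),
                         dt_s = tracks$dt, valid = fit$valid))
  invisible(dir)
}
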