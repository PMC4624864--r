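#' Detect localized stress peaks in a traction map
#'
#' Local maxima of the stress magnitude (8-neighborhood) at or above the
#' frame's detection threshold, with non-maximum suppression: any peak within
#' `min_sep` of a stronger peak is discarded (ties broken toward the lower
#' node index, column-major). Peak positions are refined to subgrid precision
#' by 1D quadratic interpolation along each axis.
#'
#' @param map a `traction_map`.
#' @param noise a `noise_estimate` for the map (computed if missing).
#' @param min_sep minimum separation between reported peaks (um).
#' @return data.frame with columns x, y (um) and stress (Pa); zero rows if
#'   nothing is suprathreshold.
#' @export
detect_peaks <- function(map, noise = estimate_noise(map), min_sep = 2) {
  mag <- stress_magnitude(map)
  nr <- nrow(mag); nc <- ncol(mag)
  co <- field_coords(map)
  ## strict local maxima wrt shifted copies (ties kept, resolved by suppression)
  P <- matrix(-Inf, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- mag
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- P[2:(nr + 1) + di, 2:(nc + 1) + dj]
    is_max <- is_max & (mag >= nb)
  }
  cand <- which(is_max & mag >= noise$s_threshold)
  if (length(cand) == 0)
    return(data.frame(x = numeric(), y = numeric(), stress = numeric()))
  ord <- cand[order(-mag[cand], cand)]
  idx <- arrayInd(ord, dim(mag))
  xs <- co$x[idx[, 2]]; ys <- co$y[idx[, 1]]
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    if (k == 1) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (xs[kept] - xs[k])^2 + (ys[kept] - ys[k])^2
    keep[k] <- all(d2 >= min_sep^2)
  }
  sel <- which(keep)
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (!is.finite(den) || den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  h <- map$spacing
  out <- data.frame(x = numeric(length(sel)), y = numeric(length(sel)),
                    stress = numeric(length(sel)))
  for (k in seq_along(sel)) {
    i <- idx[sel[k], 1]; j <- idx[sel[k], 2]
    dx <- if (j > 1 && j < nc) refine(mag[i, j - 1], mag[i, j], mag[i, j + 1]) else 0
    dy <- if (i > 1 && i < nr) refine(mag[i - 1, j], mag[i, j], mag[i + 1, j]) else 0
    out$x[k] <- co$x[j] + dx * h
    out$y[k] <- co$y[i] + dy * h
    out$stress[k] <- mag[i, j]
  }
  out
}

#' Link per-frame peak detections into tracks
#'
#' A peak A in one frame is associated with a peak B in the next frame if the
#' distance between them is at most `max_dist` and B is the closest of all
#' peaks detected in the next frame to A. Associations are resolved in order
#' of increasing A-to-nearest-B distance and each B is consumed at most once;
#' unmatched detections start new tracks and a track ends as soon as it finds
#' no match (no gap closing). The lifetime of a track with k detections is
#' (k - 1) x dt, so a single-frame appearance has lifetime 0.
#'
#' @param detections list of per-frame data.frames from [detect_peaks()]
#'   (consecutive frames at constant interval).
#' @param dt frame interval (s).
#' @param max_dist largest allowed frame-to-frame peak displacement (um);
#'   default 2 um, appropriate at dt = 2 s.
#' @return object of class `peak_tracks`: data.frame `detections`
#'   (track_id, frame, t, x, y, stress) and data.frame `tracks`
#'   (track_id, birth_frame, death_frame, n_detections, birth_time,
#'   death_time, lifetime).
#' @export
link_peaks <- function(detections, dt, max_dist = 2) {
  stopifnot(is.list(detections), dt > 0, max_dist > 0)
  n_frames <- length(detections)
  rows <- list()
  next_id <- 1L
  active <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  for (f in seq_len(n_frames)) {
    det <- detections[[f]]
    det <- if (is.null(det)) data.frame(x = numeric(), y = numeric(),
                                        stress = numeric()) else det
    assigned <- rep(NA_integer_, nrow(det))      # track id per detection
    if (nrow(active) > 0 && nrow(det) > 0) {
      ## nearest detection for every active track
      nb <- vapply(seq_len(nrow(active)), function(a) {
        d2 <- (det$x - active$x[a])^2 + (det$y - active$y[a])^2
        j <- which.min(d2)
        c(j, sqrt(d2[j]))
      }, numeric(2))
      ord <- order(nb[2, ], active$track_id)
      used <- logical(nrow(det))
      for (a in ord) {
        j <- nb[1, a]; dist <- nb[2, a]
        if (dist <= max_dist && !used[j]) {
          used[j] <- TRUE
          assigned[j] <- active$track_id[a]
        }
      }
    }
    if (nrow(det) > 0) {
      new <- which(is.na(assigned))
      if (length(new) > 0) {
        assigned[new] <- seq.int(next_id, length.out = length(new))
        next_id <- next_id + length(new)
      }
      rows[[f]] <- data.frame(track_id = assigned, frame = f, t = (f - 1) * dt,
                              x = det$x, y = det$y, stress = det$stress)
    }
    active <- if (nrow(det) > 0)
      data.frame(track_id = assigned, x = det$x, y = det$y)
    else active[0, ]
  }
  all_det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), t = numeric(),
               x = numeric(), y = numeric(), stress = numeric())
  if (nrow(all_det)) {
    sp <- split(all_det$frame, all_det$track_id)
    tracks <- data.frame(track_id = as.integer(names(sp)),
                         birth_frame = vapply(sp, min, numeric(1)),
                         death_frame = vapply(sp, max, numeric(1)),
                         n_detections = lengths(sp))
    tracks <- tracks[order(tracks$track_id), ]
    rownames(tracks) <- NULL
    tracks$birth_time <- (tracks$birth_frame - 1) * dt
    tracks$death_time <- (tracks$death_frame - 1) * dt
    tracks$lifetime <- (tracks$n_detections - 1) * dt
  } else {
    tracks <- data.frame(track_id = integer(), birth_frame = numeric(),
                         death_frame = numeric(), n_detections = integer(),
                         birth_time = numeric(), death_time = numeric(),
                         lifetime = numeric())
  }
  structure(list(detections = all_det, tracks = tracks, dt = dt,
                 max_dist = max_dist),
            class = "peak_tracks")
}

#' Histogram of stress-peak lifetimes
#'
#' Full counts are retained internally; the display range (default 15-600 s)
#' only restricts which bins a plot shows, mirroring the usual presentation
#' that omits very short- and very long-lived peaks.
#'
#' @param lifetimes numeric lifetimes (s), or a `peak_tracks` object.
#' @param bin_width histogram bin width (s).
#' @param display_range lifetimes outside this window are hidden from display.
#' @return object of class `lifetime_histogram`: `breaks`, `mids`, `counts`,
#'   `display` (logical per bin), `bin_width`, `n`.
#' @export
lifetime_histogram <- function(lifetimes, bin_width = 10,
                               display_range = c(15, 600)) {
  if (inherits(lifetimes, "peak_tracks")) lifetimes <- lifetimes$tracks$lifetime
  stopifnot(length(lifetimes) >= 1, bin_width > 0)
  breaks <- seq(0, (floor(max(lifetimes) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(lifetimes, breaks = breaks, plot = FALSE, right = FALSE)
  lo <- h$breaks[-length(h$breaks)]; hi <- h$breaks[-1]
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 display = lo >= display_range[1] & hi <= display_range[2],
                 bin_width = bin_width, n = length(lifetimes)),
            class = "lifetime_histogram")
}

#' Exponential fit to the lifetime histogram
#'
#' Least-squares line on (bin center, log count) over the fit window (default
#' 30-150 s, the exponentially decaying regime); zero-count bins are excluded.
#' The decay time is -1/slope. A non-negative slope is flagged invalid.
#'
#' @param hist a `lifetime_histogram`.
#' @param window fit window \[s\].
#' @return object of class `lifetime_fit`: `tau` (s), `tau_se`, `slope`,
#'   `intercept`, `window`, `n_bins`, `valid`.
#' @export
fit_exponential_lifetime <- function(hist, window = c(30, 150)) {
  stopifnot(inherits(hist, "lifetime_histogram"))
  keep <- hist$mids >= window[1] & hist$mids <= window[2] & hist$counts > 0
  if (sum(keep) < 3) stop("need at least 3 nonzero bins in the fit window")
  x <- hist$mids[keep]; y <- log(hist$counts[keep])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  valid <- is.finite(slope) && slope < -1e-10   # flat or rising: no decay
  structure(list(tau = if (valid) -1 / slope else NA_real_,
                 tau_se = if (valid) se / slope^2 else NA_real_,
                 slope = slope, intercept = unname(stats::coef(fit)[1]),
                 window = window, n_bins = sum(keep), valid = valid),
            class = "lifetime_fit")
}

#' Maximum-likelihood exponential decay time on a lifetime window
#'
#' Cross-check for [fit_exponential_lifetime()]: MLE of the decay time of an
#' exponential truncated to the fit window, computed from the raw lifetimes
#' (no binning). Solves the truncated-exponential score equation numerically.
#'
#' @param lifetimes numeric lifetimes (s) or a `peak_tracks` object.
#' @param window truncation window (s).
#' @return decay time estimate (s).
#' @export
fit_exponential_lifetime_ml <- function(lifetimes, window = c(30, 150)) {
  if (inherits(lifetimes, "peak_tracks")) lifetimes <- lifetimes$tracks$lifetime
  x <- lifetimes[lifetimes >= window[1] & lifetimes <= window[2]]
  if (length(x) < 3) stop("need at least 3 lifetimes inside the window")
  a <- window[1]; b <- window[2]; m <- mean(x)
  nll <- function(tau) {
    z <- exp(-a / tau) - exp(-b / tau)
    length(x) * (log(tau) + log(z)) + sum(x) / tau
  }
  stats::optimize(nll, c(1, 50 * (b - a)))$minimum
}

#' @export
print.lifetime_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("exponential lifetime fit: tau = %.3g +/- %.2g s (window %g-%g s, %d bins)\n",
                x$tau, x$tau_se, x$window[1], x$window[2], x$n_bins))
  else cat("lifetime fit invalid: non-decaying histogram in fit window\n")
  invisible(x)
}
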