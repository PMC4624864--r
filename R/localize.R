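#' Per-frame stress noise and detection threshold
#'
#' The stress noise S_noise of a traction map is the median of the maximum
#' stress magnitudes in the four corner regions (1/5 x 1/5 of the grid), which
#' sit outside the growth cone's footprint; the detection threshold is
#' S_threshold = multiplier x S_noise (multiplier 3 by default).
#'
#' @param map a `traction_map` with at least 10 x 10 nodes.
#' @param multiplier threshold-to-noise ratio (default 3).
#' @return object of class `noise_estimate`: `s_noise`, `s_threshold`,
#'   `corner_max` (4 values, Pa), `multiplier`.
#' @export
estimate_noise <- function(map, multiplier = 3) {
  stopifnot(inherits(map, "traction_map"))
  mag <- stress_magnitude(map)
  nr <- nrow(mag); nc <- ncol(mag)
  if (nr < 10 || nc < 10) stop("map must be at least 10 x 10 nodes")
  hc <- floor(nr / 5); wc <- floor(nc / 5)
  cm <- c(max(mag[1:hc, 1:wc]),
          max(mag[1:hc, (nc - wc + 1):nc]),
          max(mag[(nr - hc + 1):nr, 1:wc]),
          max(mag[(nr - hc + 1):nr, (nc - wc + 1):nc]))
  s_noise <- stats::median(cm)
  structure(list(s_noise = s_noise, s_threshold = multiplier * s_noise,
                 corner_max = cm, multiplier = multiplier),
            class = "noise_estimate")
}

## Area centroid of the convex hull of a point set (um). Fewer than 3
## non-collinear points fall back to the point mean.
.hull_centroid <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(colMeans(pts))
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nxt <- c(2:length(hx), 1)
  cr <- hx * hy[nxt] - hx[nxt] * hy
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(c(mean(pts[, 1]), mean(pts[, 2])))
  c(sum((hx + hx[nxt]) * cr), sum((hy + hy[nxt]) * cr)) / (6 * A)
}

#' Locate the growth cone from a thresholded traction map
#'
#' All nodes whose stress magnitude reaches the threshold form the traction
#' "footprint"; the growth-cone position is the area centroid of the convex
#' hull of those nodes. Frames with an empty suprathreshold set are invalid
#' (position NA).
#'
#' @param map a `traction_map`.
#' @param noise a `noise_estimate` for the same map (computed if missing).
#' @return length-2 position (um), or c(NA, NA) for an invalid frame.
#' @export
locate_growth_cone <- function(map, noise = estimate_noise(map)) {
  mag <- stress_magnitude(map)
  idx <- which(mag >= noise$s_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  co <- field_coords(map)
  unname(.hull_centroid(co$x[idx[, 2]], co$y[idx[, 1]]))
}

.round_to_odd <- function(x) {
  w <- round(x)
  if (w %% 2 == 0) w + 1 else w
}

#' Moving-window smoothing of a growth-cone trajectory
#'
#' Centered moving average with window W = max(3, odd(T_smooth / dt)); the
#' window is chosen as a function of the frame interval so that acquisitions
#' at different time resolutions are smoothed over a comparable physical time
#' (default 360 s, i.e. a 3-point window at dt = 120-180 s). Edges use
#' symmetrically shrunken windows; NA positions are ignored within a window.
#'
#' @param R n x 2 matrix of positions (um).
#' @param dt frame interval (s).
#' @param t_smooth smoothing time scale (s).
#' @return n x 2 matrix of smoothed positions.
#' @export
smooth_trajectory <- function(R, dt, t_smooth = 360) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (sum(stats::complete.cases(R)) < 3) stop("need at least 3 valid positions")
  W <- max(3, .round_to_odd(t_smooth / dt))
  if (W > n) {
    warning("smoothing window (", W, ") exceeds series length; clipped")
    W <- if (n %% 2 == 1) n else n - 1
  }
  hw <- (W - 1) / 2
  out <- R
  for (i in seq_len(n)) {
    h <- min(hw, i - 1, n - i)
    idx <- (i - h):(i + h)
    out[i, 1] <- mean(R[idx, 1], na.rm = TRUE)
    out[i, 2] <- mean(R[idx, 2], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Growth-cone velocities by forward difference
#'
#' v_n = (r_{n+1} - r_n) / dt, defined for n = 1..N-1.
#'
#' @param R n x 2 matrix of (smoothed) positions (um).
#' @param dt frame interval (s).
#' @return (n-1) x 2 matrix of velocities (um/s).
#' @export
compute_velocities <- function(R, dt) {
  R <- as.matrix(R)
  if (nrow(R) < 2) stop("need at least 2 positions")
  diff(R) / dt
}

#' Stall filter on a velocity series
#'
#' Steps where consecutive velocity vectors oppose each other
#' (v_n . v_{n+1} < 0, strict) indicate a stalled or reversing growth cone;
#' both steps involved are marked invalid and excluded from downstream
#' averages. A zero dot product is kept (strict inequality).
#'
#' @param V m x 2 matrix of velocities.
#' @return logical vector of length m, TRUE = valid step.
#' @export
stall_filter <- function(V) {
  V <- as.matrix(V)
  m <- nrow(V)
  if (m < 2) return(rep(TRUE, m))
  valid <- rep(TRUE, m)
  dots <- rowSums(V[-m, , drop = FALSE] * V[-1, , drop = FALSE])
  bad <- which(dots < 0 & !is.na(dots))
  valid[bad] <- FALSE
  valid[bad + 1] <- FALSE
  valid[!stats::complete.cases(V)] <- FALSE
  valid
}

#' Extract, smooth and stall-filter a growth-cone trajectory
#'
#' Runs [locate_growth_cone()] on every map, smooths the raw positions,
#' differentiates, and applies the stall filter.
#'
#' @param maps list of `traction_map` at constant frame interval.
#' @param dt frame interval (s).
#' @param multiplier threshold-to-noise ratio.
#' @param t_smooth smoothing time scale (s).
#' @return object of class `gc_trajectory`: data.frame `frames`
#'   (frame, t, x_raw, y_raw, x_smooth, y_smooth, vx, vy, valid) plus `dt`.
#'   `vx`, `vy` and `valid` describe the step starting at each frame (NA for
#'   the last frame).
#' @export
build_trajectory <- function(maps, dt, multiplier = 3, t_smooth = 360) {
  stopifnot(length(maps) >= 3)
  raw <- t(vapply(maps, function(m)
    locate_growth_cone(m, estimate_noise(m, multiplier)), numeric(2)))
  sm <- smooth_trajectory(raw, dt, t_smooth)
  V <- compute_velocities(sm, dt)
  valid <- stall_filter(V)
  n <- length(maps)
  df <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1) * dt,
                   x_raw = raw[, 1], y_raw = raw[, 2],
                   x_smooth = sm[, 1], y_smooth = sm[, 2],
                   vx = c(V[, 1], NA), vy = c(V[, 2], NA),
                   valid = c(valid, NA))
  structure(list(frames = df, dt = dt), class = "gc_trajectory")
}
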