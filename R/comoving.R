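#' Rotate a traction map into the growth cone's co-moving frame
#'
#' The grid is translated so the growth-cone centroid is the origin and
#' rotated by the (positive) angle that maps the velocity direction onto the
#' negative x-axis; stress vectors are rotated by the same angle, so the
#' growth cone advances along -x in the output frame with the axon trailing
#' toward +x. The rotated field is resampled onto a regular grid at the
#' original spacing by bilinear interpolation of the stress components; output
#' nodes whose source position falls outside the input grid are NA (they carry
#' no sample, never a zero fill).
#'
#' @param map a `traction_map`.
#' @param centroid length-2 growth-cone position (um), inside the map.
#' @param velocity length-2 velocity (um/s); must be non-zero (stalled frames
#'   are excluded upstream).
#' @return a `traction_map` on a grid centered at the origin (same dimensions
#'   and spacing as the input), with NA outside the rotated footprint.
#' @export
rotate_map_to_frame <- function(map, centroid, velocity) {
  stopifnot(inherits(map, "traction_map"), length(centroid) == 2,
            length(velocity) == 2)
  sp <- sqrt(sum(velocity^2))
  if (!is.finite(sp) || sp == 0) stop("zero or non-finite velocity")
  co <- field_coords(map)
  if (centroid[1] < min(co$x) || centroid[1] > max(co$x) ||
      centroid[2] < min(co$y) || centroid[2] > max(co$y))
    stop("centroid outside map bounds")
  theta <- pi - atan2(velocity[2], velocity[1])   # rotates v onto (-1, 0)
  R <- .rot2(theta)
  nr <- nrow(map$tx); nc <- ncol(map$tx)
  h <- map$spacing
  xo <- (seq_len(nc) - (nc + 1) / 2) * h
  yo <- (seq_len(nr) - (nr + 1) / 2) * h
  X <- matrix(xo, nr, nc, byrow = TRUE)
  Y <- matrix(yo, nr, nc)
  ## source position of each output node: q = centroid + R^T p
  qx <- centroid[1] + R[1, 1] * X + R[2, 1] * Y
  qy <- centroid[2] + R[1, 2] * X + R[2, 2] * Y
  sx <- .interp_at(map$tx, map$origin, h, as.vector(qx), as.vector(qy))
  sy <- .interp_at(map$ty, map$origin, h, as.vector(qx), as.vector(qy))
  tx <- matrix(R[1, 1] * sx + R[1, 2] * sy, nr, nc)
  ty <- matrix(R[2, 1] * sx + R[2, 2] * sy, nr, nc)
  structure(list(tx = tx, ty = ty, spacing = h,
                 origin = c(xo[1], yo[1]), time = map$time),
            class = "traction_map")
}

#' Average traction maps in the co-moving frame
#'
#' Per-node running sum and count over the valid frames; nodes are averaged
#' by their own counts so partially covered borders stay unbiased. The net
#' force of the mean field is reported alongside.
#'
#' @param rotated list of co-moving-frame `traction_map` (congruent grids; NA
#'   marks uncovered nodes).
#' @param valid logical vector of frame validity (default all valid).
#' @return object of class `average_stress_field`: `tx`, `ty` (mean stress,
#'   Pa; NA where count is 0), `count`, `spacing`, `origin`, `net_force`
#'   (nN), `n_frames` (valid frames used).
#' @export
average_frames <- function(rotated, valid = rep(TRUE, length(rotated))) {
  stopifnot(length(rotated) == length(valid))
  use <- which(valid %in% TRUE)
  if (length(use) == 0) stop("no valid frames to average")
  d <- dim(rotated[[use[1]]]$tx)
  sx <- matrix(0, d[1], d[2]); sy <- sx; cnt <- sx
  for (i in use) {
    m <- rotated[[i]]
    stopifnot(all(dim(m$tx) == d))
    ok <- is.finite(m$tx) & is.finite(m$ty)
    sx[ok] <- sx[ok] + m$tx[ok]
    sy[ok] <- sy[ok] + m$ty[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  tx <- ifelse(cnt > 0, sx / pmax(cnt, 1), NA_real_)
  ty <- ifelse(cnt > 0, sy / pmax(cnt, 1), NA_real_)
  m1 <- rotated[[use[1]]]
  avg <- structure(list(tx = tx, ty = ty, count = cnt, spacing = m1$spacing,
                        origin = m1$origin, time = NA_real_,
                        n_frames = length(use)),
                   class = c("average_stress_field", "traction_map"))
  avg$net_force <- net_force(avg)
  avg
}

#' @export
print.average_stress_field <- function(x, ...) {
  cat(sprintf("average_stress_field: %d x %d nodes over %d frames\n",
              nrow(x$tx), ncol(x$tx), x$n_frames))
  cat(sprintf("  net force = (%.3g, %.3g) nN\n",
              x$net_force[1], x$net_force[2]))
  invisible(x)
}

#' Flank stress maxima of an average field
#'
#' Largest local maximum of the mean stress magnitude in each half-plane
#' (y > 0 and y < 0), with its position and mean stress vector; used to test
#' that the average field's flank maxima point inward toward the neck.
#'
#' @param avg an `average_stress_field`.
#' @param min_count ignore nodes averaged over fewer frames than this.
#' @return data.frame with columns half (+1/-1), x, y, tx, ty, magnitude.
#' @export
find_flank_peaks <- function(avg, min_count = 1) {
  mag <- sqrt(avg$tx^2 + avg$ty^2)
  mag[avg$count < min_count] <- NA
  co <- field_coords(avg)
  out <- list()
  for (s in c(1, -1)) {
    rows <- if (s > 0) which(co$y > 0) else which(co$y < 0)
    sub <- mag[rows, , drop = FALSE]
    if (all(!is.finite(sub))) next
    pk <- arrayInd(which.max(sub), dim(sub))
    i <- rows[pk[1]]; j <- pk[2]
    out[[length(out) + 1]] <- data.frame(
      half = s, x = co$x[j], y = co$y[i],
      tx = avg$tx[i, j], ty = avg$ty[i, j], magnitude = mag[rows[pk[1]], j])
  }
  do.call(rbind, out)
}
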