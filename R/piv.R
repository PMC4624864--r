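#' Measure bead displacements between a frame and the reference image
#'
#' Bead displacements are detected on a regular 2D grid (default 0.75 um) by
#' windowed cross-correlation between the frame and the zero-stress reference:
#' at each grid node, the mean-subtracted interrogation window from the frame
#' is correlated against the reference window over integer shifts up to
#' `max_disp`, the peak is refined to subpixel precision by parabolic
#' interpolation, and the normalized peak height is kept as a quality score.
#' The scattered estimates are then smoothed onto the grid by Gaussian-weighted
#' interpolation (quality-weighted), which also fills nodes whose window had
#' too little texture.
#'
#' @param frame,reference equal-size image matrices.
#' @param px_size pixel size (um/pixel).
#' @param grid_spacing displacement grid spacing (um), default 0.75.
#' @param window interrogation window side (um); default 4 x grid spacing.
#' @param max_disp largest detectable displacement (um); must exceed the true
#'   displacements, default equal to the grid spacing.
#' @param kernel_width Gaussian interpolation kernel sigma (um); default
#'   1.5 x grid spacing.
#' @param min_quality nodes with normalized correlation below this are flagged
#'   and interpolated from their neighbors.
#' @return a `displacement_field` (um) with per-node `quality`.
#' @export
measure_displacements <- function(frame, reference, px_size,
                                  grid_spacing = 0.75,
                                  window = 4 * grid_spacing,
                                  max_disp = grid_spacing,
                                  kernel_width = 1.5 * grid_spacing,
                                  min_quality = 0.25) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            all(dim(frame) == dim(reference)), px_size > 0, grid_spacing > 0)
  if (window <= 2 * max_disp)
    stop("window must exceed twice the maximum expected displacement")
  nr <- nrow(frame); nc <- ncol(frame)
  w <- max(4L, round(window / px_size))            # window side, px
  m <- max(1L, ceiling(max_disp / px_size))        # search radius, px
  hw <- floor(w / 2)
  ## grid node positions (um), inset so windows fit
  inset <- (hw + m + 1) * px_size
  gx <- seq(inset, (nc - 1) * px_size - inset, by = grid_spacing)
  gy <- seq(inset, (nr - 1) * px_size - inset, by = grid_spacing)
  if (length(gx) < 2 || length(gy) < 2)
    stop("image too small for the requested grid/window")
  est_x <- matrix(NA_real_, length(gy), length(gx))
  est_y <- est_x; qual <- est_x
  shifts <- expand.grid(dx = -m:m, dy = -m:m)
  par1 <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (!is.finite(den) || den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  for (iy in seq_along(gy)) {
    ic <- round(gy[iy] / px_size) + 1
    for (jx in seq_along(gx)) {
      jc <- round(gx[jx] / px_size) + 1
      ri <- (ic - hw):(ic + hw); rj <- (jc - hw):(jc + hw)
      a <- frame[ri, rj]; a <- a - mean(a)
      na <- sqrt(sum(a^2))
      if (na == 0) next
      cc <- matrix(NA_real_, 2 * m + 1, 2 * m + 1)  # [dy, dx]
      for (s in seq_len(nrow(shifts))) {
        dx <- shifts$dx[s]; dy <- shifts$dy[s]
        b <- reference[ri - dy, rj - dx]
        b <- b - mean(b)
        nb <- sqrt(sum(b^2))
        cc[dy + m + 1, dx + m + 1] <- if (nb == 0) 0 else sum(a * b) / (na * nb)
      }
      pk <- arrayInd(which.max(cc), dim(cc))
      i0 <- pk[1]; j0 <- pk[2]
      ddy <- if (i0 > 1 && i0 < nrow(cc))
        par1(cc[i0 - 1, j0], cc[i0, j0], cc[i0 + 1, j0]) else 0
      ddx <- if (j0 > 1 && j0 < ncol(cc))
        par1(cc[i0, j0 - 1], cc[i0, j0], cc[i0, j0 + 1]) else 0
      est_x[iy, jx] <- ((j0 - m - 1) + ddx) * px_size
      est_y[iy, jx] <- ((i0 - m - 1) + ddy) * px_size
      qual[iy, jx] <- max(cc, na.rm = TRUE)
    }
  }
  ## Gaussian-weighted smoothing/interpolation onto the grid
  ok <- is.finite(qual) & qual >= min_quality
  if (!any(ok)) stop("no window produced a usable correlation peak")
  px <- rep(gx, each = length(gy))[ok]
  py <- rep(gy, times = length(gx))[ok]
  vx <- est_x[ok]; vy <- est_y[ok]; qw <- qual[ok]
  sm_x <- est_x; sm_y <- est_y
  two_s2 <- 2 * kernel_width^2
  for (iy in seq_along(gy)) for (jx in seq_along(gx)) {
    d2 <- (px - gx[jx])^2 + (py - gy[iy])^2
    wgt <- qw * exp(-d2 / two_s2)
    sw <- sum(wgt)
    if (sw > 0) {
      sm_x[iy, jx] <- sum(wgt * vx) / sw
      sm_y[iy, jx] <- sum(wgt * vy) / sw
    }
  }
  displacement_field(sm_x, sm_y, spacing = grid_spacing,
                     origin = c(gx[1], gy[1]), quality = qual)
}
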