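## Image-domain preprocessing: median filtering, z-projection, drift
## correction against the first frame, and the temporal-median reference
## image. Images are numeric matrices (rows = y, cols = x).

.sort2 <- function(env, i, j) {
  a <- env$v[[i]]; b <- env$v[[j]]
  env$v[[i]] <- pmin(a, b)
  env$v[[j]] <- pmax(a, b)
}

#' 3x3 median filter
#'
#' Vectorized median-of-nine via a minimax exchange network; borders use
#' replicate padding.
#'
#' @param img numeric matrix.
#' @return filtered matrix of the same size.
#' @export
median_filter3 <- function(img) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(img)
  P <- img[c(1, 1:nr, nr), c(1, 1:nc, nc)]     # replicate-padded
  e <- new.env()
  e$v <- vector("list", 9)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    e$v[[k]] <- P[di + seq_len(nr), dj + seq_len(nc)]
  }
  ## Paeth's 19-exchange median-of-9 network (1-based indices)
  net <- list(c(2,3), c(5,6), c(8,9), c(1,2), c(4,5), c(7,8), c(2,3), c(5,6),
              c(8,9), c(1,4), c(6,9), c(5,8), c(4,7), c(2,5), c(3,6), c(5,8),
              c(5,3), c(7,5), c(5,3))
  for (p in net) .sort2(e, p[1], p[2])
  e$v[[5]]
}

#' Maximum-intensity projection of a median-filtered z-stack
#'
#' Each slice is median filtered (3x3) to reduce shot noise, then the stack is
#' reduced to a single 2D image by pixelwise maximum.
#'
#' @param zstack a list of matrices or a 3D array (rows, cols, slices).
#' @param filter_size 3 for the default 3x3 median, 1 to skip filtering.
#' @return 2D image matrix.
#' @export
project_stack <- function(zstack, filter_size = 3) {
  if (is.array(zstack) && length(dim(zstack)) == 3)
    zstack <- lapply(seq_len(dim(zstack)[3]), function(k) zstack[, , k])
  if (!is.list(zstack) || length(zstack) == 0)
    stop("zstack must contain at least one slice")
  stopifnot(filter_size %in% c(1, 3))
  slices <- if (filter_size == 3) lapply(zstack, median_filter3) else zstack
  Reduce(pmax, slices)
}

## Cross-correlation peak between two equal-size images (zero-padded to twice
## the size, so the correlation is linear rather than circular). Returns the
## shift s = (dx, dy) (in pixels, subpixel by parabolic interpolation) such
## that a(x) ~ b(x - s), plus the normalized peak height.
.xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NULL)
  nr <- 2 * nrow(a); nc <- 2 * ncol(a)
  A <- .pad_matrix(a, nr, nc); B <- .pad_matrix(b, nr, nc)
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (nr * nc)
  ## normalize by the overlap area per shift (unbiased average product) and
  ## ignore shifts with less than half overlap
  sx <- .fft_freq(nc); sy <- .fft_freq(nr)
  ov <- outer(pmax(nrow(a) - abs(sy), 0), pmax(ncol(a) - abs(sx), 0))
  cc <- ifelse(ov >= 0.5 * length(a), cc / pmax(ov, 1), -Inf)
  pk <- arrayInd(which.max(cc), dim(cc))
  i <- pk[1]; j <- pk[2]
  wrap <- function(idx, n) ((idx - 1) %% n) + 1
  par1 <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (!is.finite(den) || den >= 0) 0
    else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  di <- par1(cc[wrap(i - 1, nr), j], cc[i, j], cc[wrap(i + 1, nr), j])
  dj <- par1(cc[i, wrap(j - 1, nc)], cc[i, j], cc[i, wrap(j + 1, nc)])
  sy <- (i - 1) + di; sx <- (j - 1) + dj
  if (sy > nr / 2) sy <- sy - nr
  if (sx > nc / 2) sx <- sx - nc
  list(shift = c(sx, sy), quality = cc[i, j] * length(a) / (na * nb))
}

## Translate an image by (dx, dy) pixels (content moves by -dx, -dy so that
## img_corrected(x) = img(x + dx)); bilinear, border replicate.
.translate_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  jx <- pmin(pmax(seq_len(nc) + dx, 1), nc)
  iy <- pmin(pmax(seq_len(nr) + dy, 1), nr)
  J <- matrix(jx, nr, nc, byrow = TRUE)
  I <- matrix(iy, nr, nc)
  matrix(.interp_bilinear(img, as.vector(J), as.vector(I)), nr, nc)
}

#' Drift-correct an image series against its first frame
#'
#' The rigid shift of each frame with respect to frame 1 is measured in each
#' of the four corner regions (1/5 x 1/5 of the image) from the peak of the
#' cross-correlation; the componentwise median of the four corner shifts is
#' used, and the frame is translated by the negated shift. Corners without
#' texture are excluded with a warning; if all four are flat the frame is left
#' unshifted.
#'
#' @param frames list of equal-size image matrices (>= 2).
#' @return list with `frames` (corrected series) and `shifts` (n x 2 matrix of
#'   detected (dx, dy) shifts in pixels; frame 1 is (0, 0)).
#' @export
correct_drift <- function(frames) {
  if (!is.list(frames) || length(frames) < 2)
    stop("need at least 2 frames")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), logical(1))))
    stop("frames must have equal size")
  nr <- d[1]; nc <- d[2]
  hc <- max(2, floor(nr / 5)); wc <- max(2, floor(nc / 5))
  corners <- list(list(1:hc, 1:wc), list(1:hc, (nc - wc + 1):nc),
                  list((nr - hc + 1):nr, 1:wc),
                  list((nr - hc + 1):nr, (nc - wc + 1):nc))
  ref <- frames[[1]]
  shifts <- matrix(0, length(frames), 2, dimnames = list(NULL, c("dx", "dy")))
  out <- frames
  for (n in 2:length(frames)) {
    sh <- list()
    for (cr in corners) {
      r <- .xcorr_shift(frames[[n]][cr[[1]], cr[[2]]], ref[cr[[1]], cr[[2]]])
      if (is.null(r)) {
        warning("flat corner region excluded from drift estimate (frame ", n, ")")
      } else sh[[length(sh) + 1]] <- r$shift
    }
    if (length(sh) == 0) {
      warning("all corner regions flat; assuming zero drift (frame ", n, ")")
      s <- c(0, 0)
    } else {
      M <- do.call(rbind, sh)
      s <- c(stats::median(M[, 1]), stats::median(M[, 2]))
    }
    shifts[n, ] <- s
    out[[n]] <- .translate_image(frames[[n]], s[1], s[2])
  }
  list(frames = out, shifts = shifts)
}

#' Zero-stress reference image by temporal median
#'
#' The pixelwise median of the intensity time course across the (drift
#' corrected) series estimates the bead configuration of the unstressed gel:
#' a bead transiently displaced in fewer than half of the frames appears at
#' its rest position.
#'
#' @param frames list of >= 3 equal-size image matrices.
#' @return 2D reference image.
#' @export
compute_reference_image <- function(frames) {
  if (!is.list(frames) || length(frames) < 3)
    stop("need at least 3 frames for a meaningful temporal median")
  arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  apply(arr, c(1, 2), stats::median)
}

#' Read a multi-page TIFF as a list of image matrices
#'
#' Single-channel 8/16-bit stacks; multi-channel pages are reduced to their
#' first channel. Rows are y (down), columns x, as stored.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices with intensities in \[0, 1\].
#' @export
read_image_series <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}

#' Write a list of image matrices as a multi-page 16-bit TIFF
#'
#' @param frames list of numeric matrices; rescaled jointly to \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  hi <- max(vapply(frames, max, numeric(1)), 1e-12)
  lo <- min(vapply(frames, min, numeric(1)), 0)
  frames <- lapply(frames, function(f) (f - lo) / (hi - lo))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}
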