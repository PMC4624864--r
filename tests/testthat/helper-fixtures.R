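## Fixture builders shared across test files. All fixtures are generated in
## code; nothing is read from disk.

## Traction map from a list of Gaussian foci: each focus is
## list(x, y, amp, width, dir = c(dx, dy)) with |dir| = 1.
gaussian_map <- function(n = 64, spacing = 0.75, foci = list(), base = 0,
                         time = 0) {
  xs <- (seq_len(n) - 1) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  tx <- matrix(base, n, n)
  ty <- matrix(base, n, n)
  for (f in foci) {
    g <- f$amp * exp(-((X - f$x)^2 + (Y - f$y)^2) / (2 * f$width^2))
    tx <- tx + g * f$dir[1]
    ty <- ty + g * f$dir[2]
  }
  traction_map(tx, ty, spacing = spacing, time = time)
}

## Map whose four corner-region maxima take prescribed values; the rest of
## the field is `fill`.
corner_map <- function(corner_values = c(10, 12, 14, 16), n = 20,
                       spacing = 0.75, fill = 0) {
  tx <- matrix(fill, n, n)
  cs <- floor(n / 5)
  mid <- ceiling(cs / 2)
  tx[mid, mid] <- corner_values[1]
  tx[mid, n - mid + 1] <- corner_values[2]
  tx[n - mid + 1, mid] <- corner_values[3]
  tx[n - mid + 1, n - mid + 1] <- corner_values[4]
  traction_map(tx, matrix(0, n, n), spacing = spacing)
}

## Smooth random test image built from scattered Gaussian spots (texture in
## every corner, suitable for cross-correlation).
textured_image <- function(nr = 100, nc = 100, n_spots = 160, seed = 1,
                           width = 2) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  px <- runif(n_spots, 1, nc)
  py <- runif(n_spots, 1, nr)
  for (k in seq_len(n_spots)) {
    j0 <- max(1, floor(px[k]) - 4 * width); j1 <- min(nc, floor(px[k]) + 4 * width)
    i0 <- max(1, floor(py[k]) - 4 * width); i1 <- min(nr, floor(py[k]) + 4 * width)
    jj <- j0:j1; ii <- i0:i1
    img[ii, jj] <- img[ii, jj] +
      outer(exp(-(ii - py[k])^2 / (2 * width^2)),
            exp(-(jj - px[k])^2 / (2 * width^2)))
  }
  img
}

## Integer-pixel drift oracle: content moves by (+dx, +dy) pixels, so the
## drifted frame satisfies frame(x) = ref(x - d). Zero fill at the edges.
shift_int <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  src_i <- seq_len(nr) - dy; src_j <- seq_len(nc) - dx
  ok_i <- src_i >= 1 & src_i <= nr; ok_j <- src_j >= 1 & src_j <= nc
  out[which(ok_i), which(ok_j)] <- img[src_i[ok_i], src_j[ok_j]]
  out
}

## Independent polygon-area centroid (shoelace), used as the oracle for
## convex-hull centroid tests.
shoelace_centroid <- function(xs, ys) {
  k <- grDevices::chull(xs, ys)
  x <- xs[k]; y <- ys[k]
  nxt <- c(2:length(x), 1)
  cr <- x * y[nxt] - x[nxt] * y
  A <- sum(cr) / 2
  c(sum((x + x[nxt]) * cr), sum((y + y[nxt]) * cr)) / (6 * A)
}

## 90-degree counterclockwise rotation of a square gridded field about its
## center, in the (x right, y up) analysis convention: (x, y) -> (-y, x).
rot90_field <- function(map) {
  tx <- map$tx; ty <- map$ty
  ## value at new position (i', j') comes from old (x, y) = (y', -x')
  rot_mat <- function(M) t(M)[, rev(seq_len(nrow(M)))]
  ## new vector = (-ty, tx) rotated into place
  traction_map(rot_mat(-map$ty), rot_mat(map$tx),
               spacing = map$spacing, origin = map$origin, time = map$time)
}
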