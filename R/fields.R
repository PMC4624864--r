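#' Gridded vector fields
#'
#' Traction maps and displacement fields live on the same regular 2D grid.
#' Matrices are stored image-style: rows index y, columns index x, so a field
#' with `ny` rows and `nx` columns covers node positions
#' `x = origin[1] + (0:(nx-1)) * spacing`, `y = origin[2] + (0:(ny-1)) * spacing`
#' (node-centered, microns). The analysis layer works in a right-handed frame
#' with y increasing upward; conversion from image storage (y down) happens
#' once, at the TIFF boundary.
#'
#' @param tx,ty numeric matrices, x/y stress components in Pa.
#' @param spacing grid spacing in microns.
#' @param origin length-2 numeric, position of node `[1,1]` in microns.
#' @param time timestamp in seconds.
#' @return An object of class `traction_map`.
#' @export
traction_map <- function(tx, ty, spacing, origin = c(0, 0), time = 0) {
  stopifnot(is.matrix(tx), is.matrix(ty), all(dim(tx) == dim(ty)),
            length(spacing) == 1, spacing > 0, length(origin) == 2)
  if (!all(is.finite(tx)) || !all(is.finite(ty)))
    stop("traction components must be finite")
  structure(list(tx = tx, ty = ty, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), time = as.numeric(time)),
            class = "traction_map")
}

#' @param ux,uy numeric matrices, displacement components in microns. NA marks
#'   nodes with no measurement.
#' @param quality optional matrix of per-node correlation quality in \[0, 1\].
#' @rdname traction_map
#' @export
displacement_field <- function(ux, uy, spacing, origin = c(0, 0), time = 0,
                               quality = NULL) {
  stopifnot(is.matrix(ux), is.matrix(uy), all(dim(ux) == dim(uy)),
            length(spacing) == 1, spacing > 0, length(origin) == 2)
  structure(list(ux = ux, uy = uy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), time = as.numeric(time),
                 quality = quality),
            class = "displacement_field")
}

#' Node coordinates of a gridded field
#'
#' @param field a `traction_map` or `displacement_field`.
#' @return list with vectors `x` (length ncol) and `y` (length nrow), microns.
#' @export
field_coords <- function(field) {
  d <- dim(field[[1]])
  list(x = field$origin[1] + (seq_len(d[2]) - 1) * field$spacing,
       y = field$origin[2] + (seq_len(d[1]) - 1) * field$spacing)
}

#' Stress magnitude of a traction map
#' @param map a `traction_map`.
#' @return matrix of |t| in Pa.
#' @export
stress_magnitude <- function(map) sqrt(map$tx^2 + map$ty^2)

#' Net traction force of a map
#'
#' Vector sum of the stress vectors times the grid-cell area. With stresses in
#' Pa and lengths in microns, 1 Pa um^2 = 1 pN; the result is reported in nN.
#' Traction is the stress the cell exerts on the substrate; the axon tension
#' is equal and opposite to the growth cone's net traction force.
#'
#' @param map a `traction_map` (or an `average_stress_field`).
#' @return length-2 numeric, net force in nN, in the map's current frame.
#' @export
net_force <- function(map) {
  a <- map$spacing^2
  tx <- map$tx; ty <- map$ty
  c(sum(tx[is.finite(tx)]), sum(ty[is.finite(ty)])) * a / 1000
}

#' @export
print.traction_map <- function(x, ...) {
  d <- dim(x$tx)
  f <- net_force(x)
  cat(sprintf("traction_map: %d x %d nodes, spacing %.3g um, t = %g s\n",
              d[1], d[2], x$spacing, x$time))
  cat(sprintf("  max |t| = %.3g Pa, net force = (%.3g, %.3g) nN\n",
              max(stress_magnitude(x)), f[1], f[2]))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$ux)
  cat(sprintf("displacement_field: %d x %d nodes, spacing %.3g um, t = %g s\n",
              d[1], d[2], x$spacing, x$time))
  invisible(x)
}

## Bilinear interpolation of matrix M (rows = y, cols = x) at query points
## given in grid-index units (1-based, fractional). Queries outside the grid
## return NA.
.interp_bilinear <- function(M, jx, iy) {
  nr <- nrow(M); nc <- ncol(M)
  out <- rep(NA_real_, length(jx))
  ok <- jx >= 1 & jx <= nc & iy >= 1 & iy <= nr &
    is.finite(jx) & is.finite(iy)
  if (!any(ok)) return(out)
  jx <- jx[ok]; iy <- iy[ok]
  j0 <- pmin(floor(jx), nc - 1L); i0 <- pmin(floor(iy), nr - 1L)
  fx <- jx - j0; fy <- iy - i0
  v00 <- M[cbind(i0, j0)];     v01 <- M[cbind(i0, j0 + 1)]
  v10 <- M[cbind(i0 + 1, j0)]; v11 <- M[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

## Interpolate a field component at physical coordinates (um).
.interp_at <- function(M, origin, spacing, xq, yq) {
  .interp_bilinear(M, (xq - origin[1]) / spacing + 1, (yq - origin[2]) / spacing + 1)
}
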