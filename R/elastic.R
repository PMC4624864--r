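#' Young's modulus from the measured storage modulus
#'
#' Polyacrylamide substrate stiffness is characterized by shear rheology; the
#' Young's modulus entering the traction calculation is E = 2 G'(1 + nu).
#'
#' @param gprime storage modulus G' in Pa (>= 0).
#' @param nu Poisson ratio, 0 <= nu < 0.5 (default 0.45 for polyacrylamide).
#' @return Young's modulus in Pa.
#' @export
youngs_modulus_from_storage <- function(gprime, nu = 0.45) {
  if (any(!is.finite(gprime)) || any(gprime < 0))
    stop("G' must be finite and non-negative")
  .check_nu(nu)
  2 * gprime * (1 + nu)
}

.check_nu <- function(nu) {
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio must satisfy 0 <= nu < 0.5 ",
         "(the incompressible limit is singular in this formulation)")
  invisible(nu)
}

#' Elastic substrate description
#'
#' Either `gprime` (with `E` derived as 2 G'(1 + nu)) or `E` directly.
#'
#' @param gprime storage modulus in Pa.
#' @param nu Poisson ratio.
#' @param E Young's modulus in Pa (overrides `gprime` if given).
#' @return object of class `gel_substrate` with fields `gprime`, `nu`, `E`.
#' @export
gel_substrate <- function(gprime = NULL, nu = 0.45, E = NULL) {
  .check_nu(nu)
  if (is.null(E)) {
    if (is.null(gprime)) stop("supply gprime or E")
    E <- youngs_modulus_from_storage(gprime, nu)
  } else {
    if (!is.finite(E) || E < 0) stop("E must be finite and non-negative")
    if (is.null(gprime)) gprime <- E / (2 * (1 + nu))
  }
  structure(list(gprime = gprime, nu = nu, E = E), class = "gel_substrate")
}

## Spectral Boussinesq transfer tensor on the padded DFT grid.
## For angular wavevector k = (kx, ky), |k| = k:
##   G(k) = 2 (1 + nu) / (E k^3) *
##          [ (1-nu) k^2 + nu ky^2 ,  -nu kx ky        ]
##          [ -nu kx ky             , (1-nu) k^2 + nu kx^2 ]
## maps the Fourier transform of the surface traction (Pa) to the Fourier
## transform of the surface displacement (um) of an elastic half-space.
## Returns the three distinct entries as matrices over the DFT grid; the k = 0
## entry is left 0 (the uniform mode is unobservable and is always zeroed).
.boussinesq_kernel <- function(nr, nc, spacing, E, nu) {
  kx1 <- 2 * pi * .fft_freq(nc) / (nc * spacing)
  ky1 <- 2 * pi * .fft_freq(nr) / (nr * spacing)
  kx <- matrix(kx1, nr, nc, byrow = TRUE)
  ky <- matrix(ky1, nr, nc)
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  pre <- 2 * (1 + nu) / (E * k^3)
  pre[1, 1] <- 0                       # k = 0: handled separately
  list(g11 = pre * ((1 - nu) * k2 + nu * ky^2),
       g12 = pre * (-nu * kx * ky),
       g22 = pre * ((1 - nu) * k2 + nu * kx^2))
}

.fft_freq <- function(n) {
  half <- floor(n / 2)
  c(0:half, if (n > 1) -(ceiling(n / 2) - 1):-1 else NULL)[1:n]
}

.pad_matrix <- function(M, nr, nc) {
  P <- matrix(0, nr, nc)
  P[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  P
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

#' Forward Boussinesq displacement of a traction field
#'
#' Convolves a surface traction field with the Boussinesq half-space surface
#' Green's tensor by spectral-domain multiplication, with zero-padding to
#' suppress wrap-around. The uniform (k = 0) mode is zero: an absolute rigid
#' translation of the substrate surface is not defined for a half-space and is
#' unobservable after drift correction.
#'
#' @param traction a `traction_map` (Pa).
#' @param gel a `gel_substrate`, or give `E` and `nu` directly.
#' @param E,nu Young's modulus (Pa) and Poisson ratio, used if `gel` missing.
#' @param pad_factor linear zero-padding factor (>= 2; padded size is rounded
#'   up to a power of two).
#' @return a `displacement_field` (um) on the same grid.
#' @export
forward_displacement <- function(traction, gel = NULL, E = NULL, nu = 0.45,
                                 pad_factor = 2) {
  stopifnot(inherits(traction, "traction_map"), pad_factor >= 1)
  if (!is.null(gel)) { E <- gel$E; nu <- gel$nu }
  if (is.null(E) || !is.finite(E) || E <= 0) stop("E must be positive")
  .check_nu(nu)
  nr <- nrow(traction$tx); nc <- ncol(traction$tx)
  NR <- .next_pow2(nr * pad_factor); NC <- .next_pow2(nc * pad_factor)
  G <- .boussinesq_kernel(NR, NC, traction$spacing, E, nu)
  TX <- stats::fft(.pad_matrix(traction$tx, NR, NC))
  TY <- stats::fft(.pad_matrix(traction$ty, NR, NC))
  UX <- G$g11 * TX + G$g12 * TY
  UY <- G$g12 * TX + G$g22 * TY
  ux <- Re(stats::fft(UX, inverse = TRUE)) / (NR * NC)
  uy <- Re(stats::fft(UY, inverse = TRUE)) / (NR * NC)
  displacement_field(ux[seq_len(nr), seq_len(nc)], uy[seq_len(nr), seq_len(nc)],
                     spacing = traction$spacing, origin = traction$origin,
                     time = traction$time)
}

#' Fourier-transform traction cytometry (FTTC)
#'
#' Recovers the surface traction field from a measured displacement field by
#' inverting the Boussinesq transfer tensor per wavevector in the spectral
#' domain (zero-padded), with optional zeroth-order Tikhonov regularization.
#' The uniform mode is set to zero and the padding is cropped after the
#' inverse transform.
#'
#' @param displacements a `displacement_field` (um); must be NA-free (fill
#'   gaps with [measure_displacements()]'s interpolation first).
#' @param gel a `gel_substrate`.
#' @param lambda Tikhonov regularization parameter (>= 0; units um/Pa, the
#'   scale of the transfer tensor entries). `lambda = 0` gives the direct
#'   inverse, appropriate for low-noise fields.
#' @param pad_factor linear zero-padding factor.
#' @return a `traction_map` (Pa) on the same grid.
#' @export
compute_traction <- function(displacements, gel, lambda = 0, pad_factor = 2) {
  stopifnot(inherits(displacements, "displacement_field"),
            inherits(gel, "gel_substrate"))
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  if (anyNA(displacements$ux) || anyNA(displacements$uy))
    stop("displacement field contains NA; interpolate gaps first")
  nr <- nrow(displacements$ux); nc <- ncol(displacements$ux)
  NR <- .next_pow2(nr * pad_factor); NC <- .next_pow2(nc * pad_factor)
  G <- .boussinesq_kernel(NR, NC, displacements$spacing, gel$E, gel$nu)
  UX <- stats::fft(.pad_matrix(displacements$ux, NR, NC))
  UY <- stats::fft(.pad_matrix(displacements$uy, NR, NC))
  a <- G$g11; b <- G$g12; cc <- G$g22
  if (lambda == 0) {
    det <- a * cc - b^2
    det[1, 1] <- Inf                   # uniform mode -> zero traction
    TX <- (cc * UX - b * UY) / det
    TY <- (-b * UX + a * UY) / det
  } else {
    ## (G'G + lambda^2 I)^{-1} G' U, G symmetric
    m11 <- a^2 + b^2 + lambda^2
    m12 <- b * (a + cc)
    m22 <- b^2 + cc^2 + lambda^2
    det <- m11 * m22 - m12^2
    det[1, 1] <- Inf
    v1 <- a * UX + b * UY
    v2 <- b * UX + cc * UY
    TX <- (m22 * v1 - m12 * v2) / det
    TY <- (-m12 * v1 + m11 * v2) / det
  }
  TX[1, 1] <- 0; TY[1, 1] <- 0
  tx <- Re(stats::fft(TX, inverse = TRUE)) / (NR * NC)
  ty <- Re(stats::fft(TY, inverse = TRUE)) / (NR * NC)
  traction_map(tx[seq_len(nr), seq_len(nc)], ty[seq_len(nr), seq_len(nc)],
               spacing = displacements$spacing, origin = displacements$origin,
               time = displacements$time)
}

#' Closed-form Boussinesq surface displacement of a tangential point force
#'
#' Surface displacement at (x, y) of an elastic half-space loaded by a
#' tangential point force `force = c(fx, fy)` (pN) at the origin:
#'   u_i(r) = (1 + nu) / (pi E r^3) * \[ (1-nu) r^2 delta_ij + nu x_i x_j \] f_j
#' Used as the independent analytic reference for the spectral forward model.
#'
#' @param x,y evaluation coordinates (um), vectorized.
#' @param force length-2 force vector in pN.
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @return list with vectors `ux`, `uy` in um.
#' @export
boussinesq_point_displacement <- function(x, y, force, E, nu = 0.45) {
  .check_nu(nu)
  r2 <- x^2 + y^2
  r <- sqrt(r2)
  pre <- (1 + nu) / (pi * E * r^3)
  list(ux = pre * (((1 - nu) * r2 + nu * x^2) * force[1] + nu * x * y * force[2]),
       uy = pre * (nu * x * y * force[1] + ((1 - nu) * r2 + nu * y^2) * force[2]))
}

#' Elastic strain energy stored in the substrate
#'
#' U = 1/2 sum(u . t) * h^2, in units of Pa um^3 = fJ * 1e-3 (1 pN um).
#' With `domain = "spectral"` the same quantity is evaluated from the DFTs of
#' the two fields (Parseval), a consistency check on the spectral conventions.
#'
#' @param displacements a `displacement_field` (um).
#' @param traction a congruent `traction_map` (Pa).
#' @param domain "real" or "spectral".
#' @return scalar energy in pN um.
#' @export
strain_energy <- function(displacements, traction, domain = c("real", "spectral")) {
  domain <- match.arg(domain)
  stopifnot(all(dim(displacements$ux) == dim(traction$tx)))
  h2 <- traction$spacing^2
  if (domain == "real")
    return(0.5 * h2 * sum(displacements$ux * traction$tx +
                          displacements$uy * traction$ty))
  n <- length(traction$tx)
  0.5 * h2 * Re(sum(stats::fft(displacements$ux) * Conj(stats::fft(traction$tx)) +
                    stats::fft(displacements$uy) * Conj(stats::fft(traction$ty)))) / n
}
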