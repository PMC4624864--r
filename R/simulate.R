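#' Configuration for the synthetic growth-cone simulator
#'
#' The simulator emulates an advancing growth cone whose traction field is a
#' superposition of localized contractile stress foci on its flanks (pointing
#' inward toward the neck), a rearward tension-carrying component at the neck,
#' and observation noise. Foci are born by a Poisson process, live for
#' exponentially distributed times, and ride along with the growth cone at the
#' flank offset where they were born. The net traction force of every frame is
#' made to equal the prescribed tension vector exactly (the neck component
#' absorbs the focus imbalance and the residual mean of the noise is removed),
#' so the ground truth is an exact areal-integral identity.
#'
#' Units: lengths um, times s, stresses Pa, forces nN.
#'
#' @param field_size side length of the square field of view (um).
#' @param spacing grid spacing (um); the displacement/traction grid default.
#' @param dt frame interval (s). Low-time-resolution acquisitions are 120-180 s,
#'   high-time-resolution 1-2 s.
#' @param n_frames number of frames.
#' @param speed growth-cone advance speed (um/s).
#' @param heading_angle direction of travel (radians, 0 = +x), constant.
#' @param birth_rate focus birth rate (foci/s).
#' @param tau_life mean focus lifetime (s).
#' @param peak_stress nominal focus peak stress (Pa); per-focus amplitudes get
#'   mild lognormal variability (sd 0.2 in log).
#' @param focus_width isotropic Gaussian focus width sigma (um).
#' @param flank_forward,flank_lateral flank anchor offsets from the centroid in
#'   the co-moving frame (um): foci are seeded near
#'   (flank_forward, +/- flank_lateral).
#' @param flank_scatter sd of the Gaussian scatter of birth positions about the
#'   flank anchors (um).
#' @param neck_offset distance of the neck behind the centroid (um).
#' @param neck_width Gaussian width of the tension-carrying neck patch (um).
#' @param tension_mean mean axon tension (nN).
#' @param tension_sd stationary sd of the tension fluctuations (nN).
#' @param tension_tau correlation time of the mean-reverting tension (s).
#' @param tension_model "ou" (mean-reverting Ornstein-Uhlenbeck, default) or
#'   "fgn" (fractional Gaussian noise increments, for anomalous-exponent
#'   studies).
#' @param hurst Hurst exponent for `tension_model = "fgn"`.
#' @param noise_sd i.i.d. observation noise per stress component (Pa).
#' @param seed integer seed fixing the entire realization.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(field_size = 72, spacing = 0.75, dt = 120, n_frames = 60,
                       speed = 0.006, heading_angle = 0,
                       birth_rate = 0.15, tau_life = 38,
                       peak_stress = 60, focus_width = 1.5,
                       flank_forward = 1.5, flank_lateral = 3.5,
                       flank_scatter = 1.0,
                       neck_offset = 3.5, neck_width = 2,
                       tension_mean = 2, tension_sd = 0.6, tension_tau = 95,
                       tension_model = c("ou", "fgn"), hurst = 3 / 14,
                       noise_sd = 2, seed = 1L) {
  tension_model <- match.arg(tension_model)
  cfg <- list(field_size = field_size, spacing = spacing, dt = dt,
              n_frames = as.integer(n_frames), speed = speed,
              heading_angle = heading_angle, birth_rate = birth_rate,
              tau_life = tau_life, peak_stress = peak_stress,
              focus_width = focus_width, flank_forward = flank_forward,
              flank_lateral = flank_lateral, flank_scatter = flank_scatter,
              neck_offset = neck_offset, neck_width = neck_width,
              tension_mean = tension_mean, tension_sd = tension_sd,
              tension_tau = tension_tau, tension_model = tension_model,
              hurst = hurst, noise_sd = noise_sd, seed = seed)
  pos <- c("field_size", "spacing", "dt", "n_frames", "speed", "tau_life",
           "peak_stress", "focus_width", "neck_width", "tension_tau")
  for (nm in pos)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be finite and strictly positive")
  nonneg <- c("birth_rate", "tension_mean", "tension_sd", "noise_sd",
              "flank_scatter", "flank_lateral", "neck_offset")
  for (nm in nonneg)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(nm, " must be finite and non-negative")
  if (!is.finite(cfg$hurst) || cfg$hurst <= 0 || cfg$hurst >= 1)
    stop("hurst must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' Draw focus lifetimes from the generator's law
#'
#' Focus engagement times are exponentially distributed; this is the law the
#' lifetime histogram and its log-linear fit are meant to recover.
#'
#' @param n number of draws.
#' @param tau_life mean lifetime (s).
#' @return numeric vector of lifetimes (s).
#' @export
sample_focus_lifetimes <- function(n, tau_life = 38) {
  stopifnot(tau_life > 0)
  stats::rexp(n, rate = 1 / tau_life)
}

## Exact-covariance fractional Gaussian noise via Cholesky factorization of the
## Toeplitz autocovariance (exact for any H, adequate for the series lengths
## used here).
.fgn <- function(n, hurst) {
  g <- function(k) 0.5 * ((abs(k) + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                            abs(abs(k) - 1)^(2 * hurst))
  L <- chol(stats::toeplitz(g(0:(n - 1))))
  as.vector(crossprod(L, stats::rnorm(n)))
}

#' Simulate an axon-tension time series
#'
#' Mean-reverting ("ou") tension with stationary mean `mean`, sd `sd` and
#' correlation time `tau` (exact discretization, stationary start), or a
#' fractional-Brownian-motion tension `mean + sd * B_H(t)` (unit-variance
#' per-step increments) whose mean squared displacement grows as tau^(2H).
#'
#' @param n number of samples.
#' @param dt sampling interval (s).
#' @param model "ou" or "fgn".
#' @param mean,sd mean tension and fluctuation scale (nN).
#' @param tau correlation time for "ou" (s).
#' @param hurst Hurst exponent for "fgn".
#' @param seed optional integer seed.
#' @return numeric vector of tension magnitudes (nN), floored at 0.
#' @export
simulate_tension <- function(n, dt, model = c("ou", "fgn"), mean = 2, sd = 0.6,
                             tau = 95, hurst = 3 / 14, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2, dt > 0, sd >= 0, tau > 0)
  if (!is.null(seed)) set.seed(seed)
  if (model == "ou") {
    a <- exp(-dt / tau)
    x <- numeric(n)
    x[1] <- mean + sd * stats::rnorm(1)
    innov <- sd * sqrt(1 - a^2) * stats::rnorm(n - 1)
    for (i in 2:n) x[i] <- mean + (x[i - 1] - mean) * a + innov[i - 1]
  } else {
    x <- mean + sd * cumsum(.fgn(n, hurst))
  }
  pmax(x, 0)
}

.rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Simulate a ground-truthed traction-map time series
#'
#' @param config a [sim_config()].
#' @return list with components
#'   \describe{
#'     \item{maps}{list of `traction_map`, one per frame.}
#'     \item{truth}{ground truth: `centroid` and `velocity` (n x 2 matrices,
#'       um and um/s), `tension` (nN magnitudes), `net_force` (n x 2, nN,
#'       equal to the areal integral of each map), and `foci`
#'       (data.frame: id, birth_time, death_time, lifetime, side, amplitude,
#'       offset_x, offset_y in the co-moving frame).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_traction_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  h <- config$spacing
  n_nodes <- max(2L, round(config$field_size / h))
  xs <- (seq_len(n_nodes) - 1) * h
  ys <- xs
  Xg <- matrix(xs, n_nodes, n_nodes, byrow = TRUE)
  Yg <- matrix(ys, n_nodes, n_nodes)
  n <- config$n_frames
  t_total <- n * config$dt
  times <- (seq_len(n) - 1) * config$dt
  heading <- c(cos(config$heading_angle), sin(config$heading_angle))
  Rh <- .rot2(config$heading_angle)     # co-moving -> lab
  ## trajectory centered in the field
  ctr <- c(config$field_size, config$field_size) / 2
  start <- ctr - heading * config$speed * t_total / 2
  centroid <- cbind(start[1] + heading[1] * config$speed * times,
                    start[2] + heading[2] * config$speed * times)
  margin <- config$neck_offset + 2 * config$neck_width
  if (any(centroid < margin) || any(centroid > config$field_size - margin))
    warning("trajectory leaves the field of view; reduce speed, n_frames or dt, ",
            "or enlarge field_size")
  velocity <- matrix(rep(heading * config$speed, each = n), n, 2)

  ## focus birth-death bookkeeping
  n_foci <- stats::rpois(1, config$birth_rate * t_total)
  if (n_foci > 0) {
    birth <- sort(stats::runif(n_foci, 0, t_total))
    life <- sample_focus_lifetimes(n_foci, config$tau_life)
    side <- sample(c(-1, 1), n_foci, replace = TRUE)
    amp <- config$peak_stress * exp(stats::rnorm(n_foci, 0, 0.2))
    off_x <- config$flank_forward + stats::rnorm(n_foci, 0, config$flank_scatter)
    off_y <- side * config$flank_lateral + stats::rnorm(n_foci, 0, config$flank_scatter)
    foci <- data.frame(id = seq_len(n_foci), birth_time = birth,
                       death_time = birth + life, lifetime = life,
                       side = side, amplitude = amp,
                       offset_x = off_x, offset_y = off_y)
  } else {
    foci <- data.frame(id = integer(), birth_time = numeric(),
                       death_time = numeric(), lifetime = numeric(),
                       side = numeric(), amplitude = numeric(),
                       offset_x = numeric(), offset_y = numeric())
  }

  tension <- simulate_tension(max(n, 2), config$dt, config$tension_model,
                              mean = config$tension_mean, sd = config$tension_sd,
                              tau = config$tension_tau, hurst = config$hurst)[seq_len(n)]
  f_target <- -cbind(tension * heading[1], tension * heading[2]) * 1000  # pN, rearward

  cell_area <- h^2
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    tx <- matrix(0, n_nodes, n_nodes); ty <- tx
    ci <- centroid[i, ]
    neck <- ci + Rh %*% c(-config$neck_offset, 0)
    if (n_foci > 0) {
      act <- which(foci$birth_time <= times[i] & times[i] < foci$death_time)
      for (j in act) {
        p <- ci + Rh %*% c(foci$offset_x[j], foci$offset_y[j])
        d <- c(neck) - c(p)
        nd <- sqrt(sum(d^2))
        dir <- if (nd > 0) d / nd else c(-heading)
        g <- foci$amplitude[j] *
          exp(-((Xg - p[1])^2 + (Yg - p[2])^2) / (2 * config$focus_width^2))
        tx <- tx + g * dir[1]
        ty <- ty + g * dir[2]
      }
    }
    ## neck patch carries the prescribed tension; the focus imbalance and the
    ## noise mean are removed as a uniform offset below, so the areal integral
    ## of every frame equals the prescribed tension vector exactly
    gneck <- exp(-((Xg - neck[1])^2 + (Yg - neck[2])^2) / (2 * config$neck_width^2))
    gneck <- gneck / (sum(gneck) * cell_area)
    tx <- tx + gneck * f_target[i, 1]
    ty <- ty + gneck * f_target[i, 2]
    if (config$noise_sd > 0) {
      tx <- tx + matrix(stats::rnorm(n_nodes^2, 0, config$noise_sd), n_nodes)
      ty <- ty + matrix(stats::rnorm(n_nodes^2, 0, config$noise_sd), n_nodes)
    }
    ## remove the residual mean so the areal integral equals the target exactly
    resid <- c(sum(tx), sum(ty)) * cell_area - f_target[i, ]
    tx <- tx - resid[1] / (n_nodes^2 * cell_area)
    ty <- ty - resid[2] / (n_nodes^2 * cell_area)
    maps[[i]] <- traction_map(tx, ty, spacing = h, time = times[i])
  }
  list(maps = maps,
       truth = list(centroid = centroid, velocity = velocity,
                    tension = tension, net_force = f_target / 1000,
                    foci = foci),
       config = config)
}

#' Render synthetic fluorescent-bead images under a displacement series
#'
#' Bead rest positions are drawn uniformly over the field; each frame renders
#' the beads advected by the (bilinearly interpolated) displacement field as
#' isotropic Gaussian spots on a pixel grid, plus additive Gaussian noise. The
#' noise-free zero-stress reference image is returned alongside the frames.
#'
#' @param displacements list of `displacement_field` (um).
#' @param density bead density (beads/um^2), default 0.6.
#' @param spot_width Gaussian spot sigma (um).
#' @param px_size pixel size (um/pixel).
#' @param noise_sd additive image noise sd (images have unit bead amplitude).
#' @param seed optional integer seed.
#' @return list with `frames` (list of matrices), `reference` (matrix),
#'   `beads` (rest positions, um), `px_size`.
#' @export
render_bead_images <- function(displacements, density = 0.6, spot_width = 0.3,
                               px_size = 0.15, noise_sd = 0.02, seed = NULL) {
  stopifnot(length(displacements) >= 1, density > 0, spot_width > 0, px_size > 0)
  if (!is.null(seed)) set.seed(seed)
  f1 <- displacements[[1]]
  co <- field_coords(f1)
  x_max <- max(co$x); y_max <- max(co$y)
  n_beads <- stats::rpois(1, density * x_max * y_max)
  if (n_beads < 4 * length(co$x))
    warning("bead density too low to constrain the displacement grid")
  bx <- stats::runif(n_beads, 0, x_max)
  by <- stats::runif(n_beads, 0, y_max)
  npx <- ceiling(x_max / px_size); npy <- ceiling(y_max / px_size)
  render <- function(px, py) {
    img <- matrix(0, npy, npx)
    half <- ceiling(4 * spot_width / px_size)
    for (b in seq_along(px)) {
      jc <- px[b] / px_size + 1; ic <- py[b] / px_size + 1
      j0 <- max(1, floor(jc) - half); j1 <- min(npx, floor(jc) + half)
      i0 <- max(1, floor(ic) - half); i1 <- min(npy, floor(ic) + half)
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      gx <- exp(-(((jj - 1) * px_size - px[b])^2) / (2 * spot_width^2))
      gy <- exp(-(((ii - 1) * px_size - py[b])^2) / (2 * spot_width^2))
      img[ii, jj] <- img[ii, jj] + outer(gy, gx)
    }
    img
  }
  reference <- render(bx, by)
  frames <- lapply(displacements, function(f) {
    ux <- .interp_at(f$ux, f$origin, f$spacing, bx, by)
    uy <- .interp_at(f$uy, f$origin, f$spacing, bx, by)
    ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
    img <- render(bx + ux, by + uy)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
    pmax(img, 0)
  })
  list(frames = frames, reference = reference,
       beads = cbind(x = bx, y = by), px_size = px_size)
}
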