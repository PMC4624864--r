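#' Axon-tension time series from traction maps
#'
#' F(t) is the magnitude of the net traction force of each map (nN); the axon
#' tension is equal and opposite to this net force. The series mean and
#' standard deviation (denominator n, so that R(0) = 1 exactly) are computed
#' from F.
#'
#' @param maps list of congruent `traction_map` at constant frame interval,
#'   or a numeric vector of force magnitudes.
#' @param dt frame interval (s).
#' @return object of class `tension_series`: `F` (nN), `t` (s), `dt`, `mu`,
#'   `sigma`.
#' @export
tension_series <- function(maps, dt) {
  if (is.numeric(maps)) {
    F <- as.numeric(maps)
  } else {
    stopifnot(length(maps) >= 2)
    d <- dim(maps[[1]]$tx)
    if (!all(vapply(maps, function(m) all(dim(m$tx) == d), logical(1))))
      stop("maps must share one grid")
    F <- vapply(maps, function(m) sqrt(sum(net_force(m)^2)), numeric(1))
  }
  stopifnot(length(F) >= 2, dt > 0)
  structure(list(F = F, t = (seq_along(F) - 1) * dt, dt = dt,
                 mu = mean(F), sigma = sqrt(mean((F - mean(F))^2))),
            class = "tension_series")
}

#' @export
print.tension_series <- function(x, ...) {
  cat(sprintf("tension_series: n = %d, dt = %g s, mu = %.3g nN, sigma = %.3g nN\n",
              length(x$F), x$dt, x$mu, x$sigma))
  invisible(x)
}

#' Autocorrelation of the tension series
#'
#' R(tau) = < (F(t) - mu)(F(t + tau) - mu) > / sigma^2, the centered product
#' averaged over all available pairs at each lag; R(0) = 1 by construction.
#' Lags are integer multiples of dt up to `max_lag` (default 480 s).
#'
#' @param series a `tension_series` with sigma > 0.
#' @param max_lag largest lag (s).
#' @return object of class `autocorrelation_result`: `lag` (s), `R`.
#' @export
autocorrelation <- function(series, max_lag = 480) {
  stopifnot(inherits(series, "tension_series"))
  if (series$sigma == 0) stop("autocorrelation undefined for a constant series")
  n <- length(series$F)
  K <- floor(max_lag / series$dt)
  if (n <= K) stop("series shorter than the requested maximum lag")
  d <- series$F - series$mu
  R <- vapply(0:K, function(k)
    mean(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / series$sigma^2,
    numeric(1))
  structure(list(lag = (0:K) * series$dt, R = R, dt = series$dt),
            class = "autocorrelation_result")
}

#' Exponential decay time of the autocorrelation
#'
#' Least-squares line on (lag, log R) over the fit window (default 10-80 s,
#' the regime past the initial rapid drop); lags with non-positive R are
#' excluded from the log fit (negative excursions are legitimate and reported
#' by [autocorrelation()], they just cannot enter a log).
#'
#' @param ac an `autocorrelation_result`.
#' @param window fit window (s).
#' @return object of class `decay_fit`: `tau` (s), `slope`, `n_lags`,
#'   `window`, `valid`.
#' @export
fit_autocorr_decay <- function(ac, window = c(10, 80)) {
  stopifnot(inherits(ac, "autocorrelation_result"))
  keep <- ac$lag >= window[1] & ac$lag <= window[2] & ac$R > 0
  if (sum(keep) < 3) stop("need at least 3 positive R values in the fit window")
  fit <- stats::lm(log(ac$R[keep]) ~ ac$lag[keep])
  slope <- unname(stats::coef(fit)[2])
  valid <- is.finite(slope) && slope < 0
  structure(list(tau = if (valid) -1 / slope else NA_real_, slope = slope,
                 n_lags = sum(keep), window = window, valid = valid),
            class = "decay_fit")
}

#' Mean squared displacement of the tension series
#'
#' MSD(tau) = < (F(t + tau) - F(t))^2 > over all available pairs, for lags up
#' to `max_lag` (default 900 s) but never beyond half the series duration
#' (clipped with a warning). With `normalize = TRUE` the curve is divided by
#' mu^2, making the saturation level of a bounded series 2 sigma^2 / mu^2 —
#' greater than unity exactly when the fluctuations are large relative to the
#' average tension.
#'
#' @param series a `tension_series`.
#' @param max_lag largest lag (s).
#' @param normalize divide by the squared series mean (default TRUE).
#' @return object of class `msd_result`: `lag` (s, starting at 0), `msd`,
#'   `normalized`.
#' @export
msd <- function(series, max_lag = 900, normalize = TRUE) {
  stopifnot(inherits(series, "tension_series"))
  n <- length(series$F)
  K <- floor(max_lag / series$dt)
  half <- floor((n - 1) / 2)
  if (K > half) {
    warning("max lag exceeds half the series duration; clipped to ",
            half * series$dt, " s")
    K <- half
  }
  if (K < 1) stop("series too short for any lag")
  F <- series$F
  m <- vapply(seq_len(K), function(k)
    mean((F[seq_len(n - k) + k] - F[seq_len(n - k)])^2), numeric(1))
  m <- c(0, m)
  if (normalize) {
    if (series$mu == 0) stop("cannot normalize: series mean is zero")
    m <- m / series$mu^2
  }
  structure(list(lag = (0:K) * series$dt, msd = m, normalized = normalize,
                 dt = series$dt),
            class = "msd_result")
}

#' Power-law exponent of the MSD
#'
#' Least-squares slope of log MSD vs log lag over the fit window (default
#' 2-200 s). An exponent of 1 is normal diffusion; the bounded, sub-diffusive
#' tension fluctuations give exponents well below 1. Non-positive MSD values
#' are excluded.
#'
#' @param m an `msd_result`.
#' @param window fit window (s).
#' @return object of class `msd_fit`: `exponent`, `n_lags`, `window`, plus
#'   `saturation_lag` (first lag where the curve reaches 90% of its long-lag
#'   plateau, NA if it never does).
#' @export
fit_msd_exponent <- function(m, window = c(2, 200)) {
  stopifnot(inherits(m, "msd_result"))
  keep <- m$lag >= window[1] & m$lag <= window[2] & m$msd > 0
  if (sum(keep) < 3) stop("need at least 3 positive MSD values in the fit window")
  fit <- stats::lm(log(m$msd[keep]) ~ log(m$lag[keep]))
  K <- length(m$lag)
  tail_idx <- seq(max(2, K - max(1, floor(K / 5))), K)
  plateau <- mean(m$msd[tail_idx])
  hit <- which(m$msd >= 0.9 * plateau & m$lag > 0)
  structure(list(exponent = unname(stats::coef(fit)[2]), n_lags = sum(keep),
                 window = window,
                 saturation_lag = if (length(hit)) m$lag[min(hit)] else NA_real_),
            class = "msd_fit")
}

#' Ensemble average of autocorrelation or MSD curves
#'
#' Averages curves from several datasets lag-by-lag (curves are truncated to
#' the shortest common lag range), the black ensemble line of the usual
#' presentation.
#'
#' @param curves list of `autocorrelation_result` or `msd_result`.
#' @return object of the same class with the averaged curve.
#' @export
ensemble_average <- function(curves) {
  stopifnot(length(curves) >= 1)
  cls <- class(curves[[1]])[1]
  stopifnot(all(vapply(curves, function(c) class(c)[1] == cls, logical(1))))
  K <- min(vapply(curves, function(c) length(c$lag), integer(1)))
  val_name <- if (cls == "autocorrelation_result") "R" else "msd"
  V <- rowMeans(vapply(curves, function(c) c[[val_name]][seq_len(K)],
                       numeric(K)))
  out <- curves[[1]]
  out$lag <- out$lag[seq_len(K)]
  out[[val_name]] <- V
  out
}
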