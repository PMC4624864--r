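test_that("tension series and its moments come from the maps", {
  z <- traction_map(matrix(0, 12, 12), matrix(0, 12, 12), spacing = 1)
  ts <- tension_series(list(z, z, z), dt = 2)
  expect_equal(ts$F, c(0, 0, 0))
  expect_equal(ts$sigma, 0)
  expect_error(autocorrelation(ts), "constant")

  tx <- matrix(0, 12, 12); tx[6, 6] <- 10
  m <- traction_map(tx, matrix(0, 12, 12), spacing = 1)
  ts2 <- tension_series(list(m, m, m, m), dt = 2)
  expect_equal(ts2$F, rep(0.01, 4))    # 10 Pa um^2 = 10 pN
  expect_equal(ts2$sigma, 0)
})

test_that("simulated tension ground truth is reproduced by the map series", {
  cfg <- sim_config(n_frames = 12, seed = 27)
  sim <- simulate_traction_series(cfg)
  ts <- tension_series(sim$maps, cfg$dt)
  expect_lt(sqrt(mean((ts$F - sim$truth$tension)^2)) /
              sqrt(mean(sim$truth$tension^2)), 0.05)
})

test_that("R(0) = 1 and white noise decorrelates at the sampling bound", {
  set.seed(3)
  ts <- tension_series(rnorm(900, 10, 1), dt = 1)
  ac <- autocorrelation(ts, max_lag = 100)
  expect_equal(ac$R[1], 1, tolerance = 1e-9)
  frac <- mean(abs(ac$R[-1]) < 2 / sqrt(900))
  expect_gte(frac, 0.95)
})

test_that("a sine has autocorrelation +1 at its period and -1 at half period", {
  P <- 100; dt <- 1
  ts <- tension_series(5 + sin(2 * pi * (0:999) * dt / P), dt = dt)
  ac <- autocorrelation(ts, max_lag = 300)
  expect_equal(ac$R[ac$lag == P], 1, tolerance = 0.02)
  expect_equal(ac$R[ac$lag == P / 2], -1, tolerance = 0.02)
})

test_that("exact exponential autocorrelation yields its decay time", {
  dt <- 2
  lags <- seq(0, 480, by = dt)
  ## build a series whose sample ACF is irrelevant: test the fit directly
  ac <- structure(list(lag = lags, R = exp(-lags / 95), dt = dt),
                  class = "autocorrelation_result")
  fit <- fit_autocorr_decay(ac, window = c(10, 80))
  expect_true(fit$valid)
  expect_equal(fit$tau, 95, tolerance = 1e-10)

  ## negative excursions inside the window are excluded, fit proceeds
  ac$R[ac$lag == 40] <- -0.05
  fit2 <- fit_autocorr_decay(ac, window = c(10, 80))
  expect_true(fit2$valid)
  expect_equal(fit2$tau, 95, tolerance = 0.02)
  ## fewer than 3 positive lags: error
  ac$R[ac$lag >= 10 & ac$lag <= 80] <- -1
  expect_error(fit_autocorr_decay(ac, window = c(10, 80)), "positive")
})

test_that("the autocorrelation fit recovers long-series mean reversion", {
  ## estimator check under negligible finite-length bias
  taus <- vapply(51:53, function(s) {
    x <- simulate_tension(1e5, 2, "ou", mean = 2, sd = 0.6, tau = 95, seed = s)
    ac <- autocorrelation(tension_series(x, 2), max_lag = 480)
    fit_autocorr_decay(ac, window = c(10, 80))$tau
  }, numeric(1))
  expect_equal(median(taus), 95, tolerance = 0.1)
})

test_that("MSD identities: constant, white noise, and ballistic ramp", {
  expect_equal(msd(tension_series(rep(3, 100), 1), max_lag = 20)$msd,
               rep(0, 21))

  set.seed(5)
  x <- rnorm(4000, 10, 2)
  ts <- tension_series(x, 1)
  m <- msd(ts, max_lag = 50, normalize = FALSE)
  expect_equal(mean(m$msd[-1]), 2 * ts$sigma^2, tolerance = 0.02)

  ramp <- tension_series(0.1 * (0:999), 1)
  mr <- msd(ramp, max_lag = 100, normalize = FALSE)
  expect_equal(mr$msd[-1], (0.1 * mr$lag[-1])^2, tolerance = 1e-10)
  fit <- fit_msd_exponent(mr, window = c(2, 100))
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
})

test_that("MSD lag range is clipped to half the duration with a warning", {
  ts <- tension_series(rnorm(100, 5), 1)
  expect_warning(m <- msd(ts, max_lag = 90), "clipped")
  expect_equal(max(m$lag), 49)
})

test_that("exact power laws give their exponent to machine precision", {
  lags <- (0:450) * 2
  m <- structure(list(lag = lags, msd = c(0, (lags[-1])^0.5), normalized = FALSE,
                      dt = 2), class = "msd_result")
  expect_equal(fit_msd_exponent(m, c(2, 200))$exponent, 0.5, tolerance = 1e-10)
})

test_that("white-noise MSD is flat (exponent near zero)", {
  set.seed(9)
  ts <- tension_series(rnorm(2000, 10, 1), 2)
  m <- msd(ts, max_lag = 400)
  expect_lt(abs(fit_msd_exponent(m, c(2, 200))$exponent), 0.05)
})

test_that("MSD and autocorrelation satisfy MSD/(2 sigma^2) + R = 1", {
  x <- simulate_tension(6000, 2, "ou", mean = 3, sd = 0.5, tau = 40, seed = 15)
  ts <- tension_series(x, 2)
  ac <- autocorrelation(ts, max_lag = 200)
  m <- msd(ts, max_lag = 200, normalize = FALSE)
  resid <- m$msd / (2 * ts$sigma^2) + ac$R - 1
  expect_lt(max(abs(resid)), 0.1)
})

test_that("estimators respect shift and scale symmetries", {
  set.seed(21)
  x <- 5 + cumsum(rnorm(500, 0, 0.05))
  ts1 <- tension_series(x, 1)
  ts2 <- tension_series(x + 7, 1)      # shift
  ts3 <- tension_series(3 * x, 1)      # scale
  a1 <- autocorrelation(ts1, 100); a2 <- autocorrelation(ts2, 100)
  a3 <- autocorrelation(ts3, 100)
  expect_equal(a1$R, a2$R, tolerance = 1e-9)
  expect_equal(a1$R, a3$R, tolerance = 1e-9)
  m1 <- msd(ts1, 100, normalize = FALSE)
  m2 <- msd(ts2, 100, normalize = FALSE)
  m3 <- msd(ts3, 100, normalize = FALSE)
  expect_equal(m1$msd, m2$msd, tolerance = 1e-9)
  expect_equal(m3$msd, 9 * m1$msd, tolerance = 1e-9)
})

test_that("bounded mean-reverting tension saturates the normalized MSD", {
  x <- simulate_tension(8000, 2, "ou", mean = 3, sd = 0.6, tau = 40, seed = 19)
  ts <- tension_series(x, 2)
  m <- msd(ts, max_lag = 600)
  plateau <- 2 * ts$sigma^2 / ts$mu^2
  sel <- m$lag >= 5 * 40
  expect_lt(max(abs(m$msd[sel] / plateau - 1)), 0.1)
  fit <- fit_msd_exponent(m, c(2, 200))
  expect_lt(fit$saturation_lag, 600)
})

test_that("ensemble averaging combines curves lag-by-lag", {
  ts1 <- tension_series(rnorm(300, 10), 2)
  ts2 <- tension_series(rnorm(400, 10), 2)
  a1 <- autocorrelation(ts1, 100); a2 <- autocorrelation(ts2, 100)
  av <- ensemble_average(list(a1, a2))
  expect_equal(av$R, (a1$R + a2$R) / 2)
  m1 <- msd(ts1, 100); m2 <- msd(ts2, 100)
  mv <- ensemble_average(list(m1, m2))
  expect_equal(mv$msd, (m1$msd + m2$msd) / 2)
})
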