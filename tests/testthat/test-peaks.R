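noise3 <- function(map) estimate_noise(map)

test_that("peak detection finds isolated foci with subgrid accuracy", {
  m <- gaussian_map(40, spacing = 0.75,
                    foci = list(list(x = 11.6, y = 14.3, amp = 50, width = 1.5,
                                     dir = c(1, 0))),
                    base = 0.01)
  pk <- detect_peaks(m, noise3(m), min_sep = 2)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x - 11.6), 0.5 * m$spacing)
  expect_lt(abs(pk$y - 14.3), 0.5 * m$spacing)

  ## two foci separated by 3 x min_sep stay separate
  m2 <- gaussian_map(40, spacing = 0.75, base = 0.01,
                     foci = list(list(x = 10, y = 15, amp = 50, width = 1,
                                      dir = c(1, 0)),
                                 list(x = 16, y = 15, amp = 45, width = 1,
                                      dir = c(0, 1))))
  expect_equal(nrow(detect_peaks(m2, noise3(m2), min_sep = 2)), 2)
})

test_that("non-maximum suppression keeps the stronger of close peaks", {
  ## two nodes of equal height 0.5 x min_sep apart -> one peak, and the tie
  ## breaks toward the lower node index
  n <- 24
  tx <- matrix(0.01, n, n)
  tx[12, 12] <- 30; tx[12, 13] <- 30   # 0.75 um apart, min_sep 1.5
  m <- traction_map(tx, matrix(0, n, n), spacing = 0.75)
  pk <- detect_peaks(m, noise3(m), min_sep = 1.5)
  expect_equal(nrow(pk), 1)
  co <- field_coords(m)
  ## column-major: node [12,12] has the lower index
  expect_lt(abs(pk$x - co$x[12]), 0.5)
  expect_equal(nrow(detect_peaks(m, noise3(m), min_sep = 0.5)), 2)
})

test_that("empty maps give an empty detection list", {
  m <- traction_map(matrix(1, 12, 12), matrix(0, 12, 12), spacing = 0.75)
  expect_equal(nrow(detect_peaks(m, noise3(m))), 0)
})

test_that("a stationary peak yields one track with lifetime (k-1) dt", {
  det <- lapply(1:30, function(f) {
    if (f >= 5 && f <= 25) data.frame(x = 10, y = 10, stress = 50)
    else data.frame(x = numeric(), y = numeric(), stress = numeric())
  })
  tr <- link_peaks(det, dt = 2, max_dist = 2)
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$tracks$lifetime, 40)            # (21 - 1) x 2
  expect_equal(tr$tracks$birth_time, 8)           # frame 5 at dt = 2
})

test_that("distant peaks form parallel tracks that never merge", {
  det <- lapply(1:10, function(f)
    data.frame(x = c(5, 25), y = c(10, 10), stress = c(40, 45)))
  tr <- link_peaks(det, dt = 2, max_dist = 2)
  expect_equal(nrow(tr$tracks), 2)
  expect_equal(sort(tr$tracks$lifetime), c(18, 18))
})

test_that("a jump beyond the link distance ends the track and starts a new one", {
  det <- lapply(1:10, function(f) {
    x <- if (f <= 5) 10 else 13        # 3 um jump, link distance 2
    data.frame(x = x, y = 10, stress = 40)
  })
  tr <- link_peaks(det, dt = 2, max_dist = 2)
  expect_equal(nrow(tr$tracks), 2)
  expect_equal(sort(tr$tracks$n_detections), c(5, 5))
})

test_that("linking does not depend on detection enumeration order", {
  set.seed(31)
  det <- lapply(1:12, function(f) {
    data.frame(x = c(5, 11, 20) + 0.2 * rnorm(3),
               y = c(10, 10, 10) + 0.2 * rnorm(3),
               stress = c(40, 42, 44))
  })
  shuffled <- lapply(det, function(d) d[sample(nrow(d)), ])
  t1 <- link_peaks(det, dt = 2, max_dist = 2)
  t2 <- link_peaks(shuffled, dt = 2, max_dist = 2)
  expect_equal(nrow(t1$tracks), 3)
  key <- function(tr) {
    d <- tr$detections[order(tr$detections$frame, tr$detections$x), ]
    sp <- split(paste(d$frame, round(d$x, 6)), d$track_id)
    sort(vapply(sp, paste, character(1), collapse = ";"))
  }
  expect_equal(unname(key(t1)), unname(key(t2)))
})

test_that("simulated foci are recovered as single unfragmented tracks", {
  ## sparse foci, high time resolution, spacing >> link distance
  cfg <- sim_config(field_size = 48, dt = 2, n_frames = 900,
                    birth_rate = 0.006, tau_life = 38, flank_scatter = 3,
                    flank_lateral = 6, speed = 0.002, noise_sd = 1, seed = 33)
  sim <- simulate_traction_series(cfg)
  det <- lapply(sim$maps, function(m) detect_peaks(m, estimate_noise(m)))
  tr <- link_peaks(det, dt = cfg$dt, max_dist = 2)
  f <- sim$truth$foci
  t_end <- (cfg$n_frames - 1) * cfg$dt
  f <- f[f$lifetime >= 3 * cfg$dt & f$death_time < t_end, ]
  expect_gt(nrow(f), 3)
  hit <- 0
  for (k in seq_len(nrow(f))) {
    cand <- tr$tracks[abs(tr$tracks$birth_time - f$birth_time[k]) <= 2 * cfg$dt &
                        abs(tr$tracks$lifetime - f$lifetime[k]) <=
                          pmax(0.25 * f$lifetime[k], 2 * cfg$dt), ]
    if (nrow(cand) >= 1) hit <- hit + 1
  }
  expect_gte(hit / nrow(f), 0.9)
})

test_that("lifetime histogram bins and display range behave as specified", {
  lh <- lifetime_histogram(c(40, 40, 80), bin_width = 20)
  expect_equal(lh$counts[lh$mids == 50], 2)        # [40, 60)
  expect_equal(lh$counts[lh$mids == 90], 1)        # [80, 100)
  expect_equal(sum(lh$counts), 3)

  lh2 <- lifetime_histogram(c(2, 5, 11), bin_width = 10)
  expect_equal(sum(lh2$counts[lh2$display]), 0)    # nothing displayed
  expect_equal(sum(lh2$counts), 3)                 # but all retained
})

test_that("log-linear fit recovers exact and sampled exponential decays", {
  ## exact counts c(t) = 1000 exp(-t / 50): tau = 50 to machine precision
  mids <- seq(5, 295, by = 10)
  counts <- 1000 * exp(-mids / 50)
  h <- structure(list(breaks = seq(0, 300, 10), mids = mids, counts = counts,
                      display = rep(TRUE, length(mids)), bin_width = 10,
                      n = sum(counts)),
                 class = "lifetime_histogram")
  fit <- fit_exponential_lifetime(h, window = c(30, 150))
  expect_true(fit$valid)
  expect_equal(fit$tau, 50, tolerance = 1e-10)

  ## 5000 draws from Exponential(38 s): tau = 38 +/- 4
  set.seed(7)
  life <- sample_focus_lifetimes(5000, 38)
  fit2 <- fit_exponential_lifetime(lifetime_histogram(life, 10))
  expect_equal(fit2$tau, 38, tolerance = 4 / 38)
  ## maximum-likelihood cross-check agrees
  expect_equal(fit_exponential_lifetime_ml(life), 38, tolerance = 4 / 38)

  ## flat counts: slope 0 -> invalid
  hf <- h; hf$counts <- rep(100, length(mids))
  expect_false(fit_exponential_lifetime(hf)$valid)
})

test_that("recovered decay time is insensitive to bin width", {
  set.seed(13)
  life <- sample_focus_lifetimes(6000, 38)
  taus <- vapply(c(5, 10, 20), function(bw)
    fit_exponential_lifetime(lifetime_histogram(life, bw))$tau, numeric(1))
  expect_lt(max(abs(taus / taus[2] - 1)), 0.1)
})
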