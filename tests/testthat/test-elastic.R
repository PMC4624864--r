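test_that("Young's modulus follows E = 2 G'(1 + nu)", {
  expect_equal(youngs_modulus_from_storage(100, 0.45), 290)
  expect_equal(youngs_modulus_from_storage(50, 0), 100)
  expect_equal(youngs_modulus_from_storage(0, 0.45), 0)
  expect_error(youngs_modulus_from_storage(-1), "non-negative")
  expect_error(youngs_modulus_from_storage(100, 0.5), "Poisson")
  expect_error(gel_substrate(gprime = 100, nu = 0.6), "Poisson")
})

test_that("forward displacement is linear and scales inversely with E", {
  z <- traction_map(matrix(0, 16, 16), matrix(0, 16, 16), spacing = 0.75)
  dz <- forward_displacement(z, E = 290, nu = 0.45)
  expect_equal(max(abs(dz$ux)), 0)
  expect_equal(max(abs(dz$uy)), 0)

  tm <- gaussian_map(32, foci = list(list(x = 12, y = 12, amp = 40,
                                          width = 1.5, dir = c(0.6, 0.8))))
  d1 <- forward_displacement(tm, E = 290, nu = 0.45)
  d2 <- forward_displacement(tm, E = 580, nu = 0.45)
  expect_equal(d2$ux, d1$ux / 2, tolerance = 1e-12)
  expect_equal(d2$uy, d1$uy / 2, tolerance = 1e-12)
  expect_error(forward_displacement(tm, E = 290, nu = 0.5), "Poisson")
})

test_that("point-force displacement matches the closed-form Boussinesq solution", {
  h <- 0.75; n <- 64
  tx <- matrix(0, n, n); ty <- tx
  ic <- 32; jc <- 32; F <- 500  # pN
  tx[ic, jc] <- F / h^2
  tm <- traction_map(tx, ty, spacing = h)
  disp <- forward_displacement(tm, E = 290, nu = 0.45, pad_factor = 16)
  co <- field_coords(tm)
  X <- matrix(co$x, n, n, byrow = TRUE) - co$x[jc]
  Y <- matrix(co$y, n, n) - co$y[ic]
  r <- sqrt(X^2 + Y^2)
  cf <- boussinesq_point_displacement(as.vector(X), as.vector(Y),
                                      c(F, 0), 290, 0.45)
  cfx <- matrix(cf$ux, n, n); cfy <- matrix(cf$uy, n, n)
  ## the uniform mode of the spectral solution is zero by construction and
  ## unobservable; align it before comparing
  ann <- r >= 3 * h & r <= 10 * h
  ax <- disp$ux - (mean(disp$ux[ann]) - mean(cfx[ann]))
  ay <- disp$uy - (mean(disp$uy[ann]) - mean(cfy[ann]))
  mnum <- sqrt(ax^2 + ay^2); mcf <- sqrt(cfx^2 + cfy^2)
  ## azimuthally averaged radial profile of |u| agrees to < 2% beyond 3 h
  for (rr in 3:9) {
    s <- r >= rr * h & r < (rr + 1) * h
    expect_lt(abs(mean(mnum[s]) / mean(mcf[s]) - 1), 0.02)
  }
  ## and the decay is 1/r: profile ratio between radii matches closed form
  s3 <- r >= 3 * h & r < 4 * h; s8 <- r >= 8 * h & r < 9 * h
  expect_equal(mean(mnum[s3]) / mean(mnum[s8]),
               mean(mcf[s3]) / mean(mcf[s8]), tolerance = 0.04)
})

test_that("FTTC round trip recovers a known traction patch", {
  h <- 0.75; n <- 64
  xs <- (0:(n - 1)) * h
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  g <- 40 * exp(-((X - 20)^2 + (Y - 25)^2) / 8) -
    40 * exp(-((X - 28)^2 + (Y - 23)^2) / 8)
  tm <- traction_map(g, 0.5 * g, spacing = h)
  gel <- gel_substrate(E = 290, nu = 0.45)
  d <- forward_displacement(tm, gel, pad_factor = 4)
  rec <- compute_traction(d, gel, lambda = 0, pad_factor = 4)
  idx <- 5:(n - 4)                     # away from boundaries
  rel <- sqrt(mean((rec$tx[idx, idx] - tm$tx[idx, idx])^2 +
                   (rec$ty[idx, idx] - tm$ty[idx, idx])^2)) /
    sqrt(mean(tm$tx^2 + tm$ty^2))
  expect_lt(rel, 0.05)

  ## doubling E with fixed displacements doubles all tractions
  rec2 <- compute_traction(d, gel_substrate(E = 580, nu = 0.45), lambda = 0,
                           pad_factor = 4)
  expect_equal(rec2$tx, 2 * rec$tx, tolerance = 1e-10)

  ## zero displacement -> zero traction; invalid inputs rejected
  z <- displacement_field(matrix(0, 16, 16), matrix(0, 16, 16), spacing = h)
  expect_equal(max(abs(compute_traction(z, gel)$tx)), 0)
  expect_error(compute_traction(d, gel, lambda = -1), "lambda")
  dna <- d; dna$ux[3, 3] <- NA
  expect_error(compute_traction(dna, gel), "NA")
})

test_that("Tikhonov regularization damps but approximates the direct inverse", {
  tm <- gaussian_map(32, foci = list(list(x = 12, y = 12, amp = 40,
                                          width = 2, dir = c(1, 0))))
  gel <- gel_substrate(E = 290, nu = 0.45)
  d <- forward_displacement(tm, gel, pad_factor = 4)
  t_small <- compute_traction(d, gel, lambda = 1e-6, pad_factor = 4)
  t_large <- compute_traction(d, gel, lambda = 1e-1, pad_factor = 4)
  idx <- 5:28                          # away from crop boundaries
  rel <- sqrt(mean((t_small$tx[idx, idx] - tm$tx[idx, idx])^2)) /
    sqrt(mean(tm$tx^2))
  expect_lt(rel, 0.05)
  expect_lt(max(abs(t_large$tx)), max(abs(tm$tx)))  # heavy damping shrinks
})

test_that("strain energy agrees between real and spectral domains", {
  tm <- gaussian_map(32, foci = list(list(x = 10, y = 14, amp = 30,
                                          width = 2, dir = c(0.8, -0.6))))
  d <- forward_displacement(tm, E = 290, nu = 0.45)
  er <- strain_energy(d, tm, "real")
  es <- strain_energy(d, tm, "spectral")
  expect_gt(er, 0)
  expect_equal(er, es, tolerance = 1e-6)
})

test_that("traction reconstruction is equivariant under 90-degree rotation", {
  tm <- gaussian_map(48, foci = list(
    list(x = 14, y = 20, amp = 40, width = 2, dir = c(0.6, 0.8)),
    list(x = 22, y = 15, amp = 25, width = 1.5, dir = c(-1, 0))))
  gel <- gel_substrate(E = 290, nu = 0.45)
  u <- forward_displacement(tm, gel, pad_factor = 4)
  u_of_rot <- forward_displacement(rot90_field(tm), gel, pad_factor = 4)
  rot_of_u <- rot90_field(structure(list(tx = u$ux, ty = u$uy,
                                         spacing = u$spacing, origin = u$origin,
                                         time = 0), class = "traction_map"))
  expect_equal(u_of_rot$ux, rot_of_u$tx, tolerance = 1e-8)
  expect_equal(u_of_rot$uy, rot_of_u$ty, tolerance = 1e-8)
})

test_that("translating the displacement field translates the traction field", {
  n <- 48
  tm <- gaussian_map(n, foci = list(list(x = 14, y = 14, amp = 40, width = 2,
                                         dir = c(0.6, 0.8))))
  gel <- gel_substrate(E = 290, nu = 0.45)
  d <- forward_displacement(tm, gel, pad_factor = 4)
  s <- 6  # nodes
  shift_mat <- function(M) { out <- matrix(0, n, n)
    out[(1 + s):n, (1 + s):n] <- M[1:(n - s), 1:(n - s)]; out }
  d_sh <- displacement_field(shift_mat(d$ux), shift_mat(d$uy), spacing = tm$spacing)
  r1 <- compute_traction(d, gel, pad_factor = 4)
  r2 <- compute_traction(d_sh, gel, pad_factor = 4)
  idx <- (1 + s + 4):(n - 4)
  expect_lt(max(abs(r2$tx[idx, idx] - r1$tx[idx - s, idx - s])),
            0.02 * max(abs(tm$tx)))
})
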