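test_that("optical train enforces thin-lens conjugacy and paraxial NA", {
  tr <- reference_train()
  expect_equal(tr$numerical_aperture, 0.25)
  expect_equal(tr$magnification, 1)
  expect_equal(tr$object_distance, 2000)
  expect_error(optical_train(250, 1000, object_distance = 1500, image_distance = 2000),
               "thin-lens")
  expect_error(optical_train(2000, 1000), "NA")
})

test_that("hyperboloid phase matches the exact closed form", {
  g <- sampled_grid(9, pixel_pitch = 1)   # odd grid: a pixel sits on axis
  expect_equal(hyperboloid_phase(g, 1000, 530)[5, 5], 0, tolerance = 1e-12)

  # pixel at exactly r = 250 um on a coarse odd grid
  gc <- sampled_grid(9, pixel_pitch = 125)
  co <- grid_coords(gc)
  i <- which(abs(co$r - 250) < 1e-9)[1]
  expect_false(is.na(i))
  expect_equal(hyperboloid_phase(gc, 1000, 530)[i], 364.856348166, tolerance = 1e-9)
  # paraxial expansion overshoots the exact profile by ~1.6% at NA 0.25
  paraxial <- (2 * pi / 0.53) * 250^2 / 2000
  expect_equal(paraxial, 370.470831791, tolerance = 1e-9)
  expect_lt(abs(paraxial / 364.856348166 - 1), 0.016)

  # strictly increasing with radius away from the axis, zero on axis
  ph <- hyperboloid_phase(sampled_grid(65), 500, 530)
  expect_true(all(diff(ph[33, 33:65]) > 0))
  expect_error(hyperboloid_phase(g, -1, 530), "focal_length")
  expect_error(hyperboloid_phase(g, 1000, 0), "wavelength")
})

test_that("chromatic focal law conserves the lambda-f product", {
  expect_equal(focal_at_wavelength(1150, 530, 530), 1150)
  expect_equal(focal_at_wavelength(1150, 530, 625), 975.2)
  # product conservation is exact
  f2 <- focal_at_wavelength(1000, 530, 625)
  expect_identical(625 * f2, 530 * 1000)
  # linearized red-green shift at the f = 1 mm reference geometry: ~180 um
  expect_equal(chromatic_focal_shift(1000, 530, 95), 179.245283019, tolerance = 1e-9)
  expect_equal(signif(chromatic_focal_shift(1000, 530, 95), 2), 180)
  # measured focal triplet: lambda*f products pairwise within 4%
  prods <- c(625 * 0.95, 530 * 1.15, 455 * 1.35)
  expect_lt(diff(range(prods)) / min(prods), 0.04)
  expect_error(focal_at_wavelength(1000, 530, -1), "lambda")
})

test_that("Fresnel propagation: identity, plane wave, quadrature oracle", {
  g <- sampled_grid(64, pixel_pitch = 4)
  f <- complex_field(g, matrix(1 + 0i, 64, 64), 530)
  expect_identical(fresnel_propagate(f, 0), f)
  # plane wave is an eigenfunction: uniform intensity, global phase kz
  p <- fresnel_propagate(f, 300, pad = FALSE)
  expect_equal(intensity(p), matrix(1, 64, 64), tolerance = 1e-9)
  expect_equal(Arg(p$amplitude[1, 1]),
               ((2 * pi / 0.53) * 300 + pi) %% (2 * pi) - pi, tolerance = 1e-6)

  # smooth 64x64 aperture vs direct Fresnel quadrature on an 8x finer grid
  co <- grid_coords(g)
  ap <- function(x, y) exp(-(sqrt(x^2 + y^2) / 40)^4)
  fh <- complex_field(g, ap(co$x, co$y) + 0i, 530)
  lam <- 0.53; k <- 2 * pi / lam; z <- 500
  fine <- (seq_len(512) - 256.5) * 0.5
  E <- matrix(0, 512, 512)
  for (i in seq_len(512)) E[i, ] <- ap(fine, fine[i])
  xs <- co$x[1, ]; ys <- co$y[, 1]
  Kx <- exp(1i * k * outer(xs, fine, function(a, b) (a - b)^2) / (2 * z))
  Ky <- exp(1i * k * outer(ys, fine, function(a, b) (a - b)^2) / (2 * z))
  oracle <- Mod(0.5^2 * exp(1i * k * z) / (1i * lam * z) * (Ky %*% E %*% t(Kx)))^2
  tf <- fresnel_propagate(fh, z, method = "tf")
  expect_lt(spectralTIE:::rms(intensity(tf) - oracle) /
              spectralTIE:::rms(oracle), 1e-4)
  # impulse-response path reproduces the same-grid discrete convolution sum
  hat <- matrix(0 + 0i, 64, 64)
  hat[abs(co$x) <= 32 & abs(co$y) <= 32] <- 1
  fhat <- complex_field(g, hat, 530)
  coarse <- fresnel_quadrature(fhat, 500)
  ir <- suppressWarnings(fresnel_propagate(fhat, 500, method = "ir"))
  expect_lt(spectralTIE:::rms(intensity(ir) - intensity(coarse)) /
              spectralTIE:::rms(intensity(coarse)), 1e-8)
})

test_that("propagator conserves energy, inverts, and composes", {
  scr <- smooth_phase_screen(64, corr_px = 8, amplitude = 1.5, seed = 4)
  g <- sampled_grid(64, pixel_pitch = 1)
  f <- complex_field(g, exp(1i * scr), 530)
  p <- fresnel_propagate(f, 40, pad = FALSE)
  expect_lt(abs(sum(intensity(p)) - sum(intensity(f))) / sum(intensity(f)), 1e-6)
  # z then -z recovers the input
  b <- fresnel_propagate(p, -40, pad = FALSE)
  expect_lt(spectralTIE:::rms(Mod(b$amplitude - f$amplitude)), 1e-8)
  # group property
  p12 <- fresnel_propagate(fresnel_propagate(f, 15, pad = FALSE), 25, pad = FALSE)
  expect_lt(spectralTIE:::rms(Mod(p12$amplitude - p$amplitude)), 1e-7)
})

test_that("propagation warns when the selected kernel is under-sampled", {
  g <- sampled_grid(32, pixel_pitch = 1)
  f <- complex_field(g, matrix(1 + 0i, 32, 32), 530)
  expect_warning(fresnel_propagate(f, 1e5, method = "tf"), "under-sampled")
  expect_warning(fresnel_propagate(f, 5, method = "ir"), "under-sampled")
})

test_that("tie_rhs matches analytic and Fresnel finite-difference oracles", {
  g <- sampled_grid(128, pixel_pitch = 1)
  co <- grid_coords(g)
  # uniform phase: zero rate
  expect_equal(tie_rhs(matrix(1, 128, 128), matrix(0.7, 128, 128), 530),
               matrix(0, 128, 128))
  # cosine phase on unit intensity: (lambda/2pi) a k^2 cos, up to the
  # central-difference sinc^2 attenuation
  q <- 2 * pi * 2 / 128
  a <- 0.1
  phs <- a * cos(q * co$x)
  rhs <- tie_rhs(matrix(1, 128, 128), phs, 530)
  expected <- (0.53 / (2 * pi)) * a * q^2 * cos(q * co$x)
  expect_lt(rel_rms(rhs, expected), 0.01)
  # against (I(+dz) - I(-dz)) / 2dz from the propagator; the screen is
  # FFT-periodic, so the unpadded propagation is its exact evolution
  scr <- smooth_phase_screen(128, corr_px = 12, amplitude = 0.2, seed = 3)
  f <- complex_field(g, exp(1i * scr), 530)
  fd <- (intensity(fresnel_propagate(f, 1, pad = FALSE)) -
           intensity(fresnel_propagate(f, -1, pad = FALSE))) / 2
  expect_lt(rel_rms(tie_rhs(intensity(f), scr, 530), fd), 0.02)
  expect_error(tie_rhs(matrix(1, 8, 8), matrix(0, 9, 9), 530), "share one grid")
})

test_that("tpe_rhs reproduces analytic rates and flags floored pixels", {
  g <- sampled_grid(64, pixel_pitch = 1)
  co <- grid_coords(g)
  I1 <- matrix(1, 64, 64)
  expect_equal(tpe_rhs(I1, matrix(2, 64, 64), 530), matrix(0, 64, 64))
  # tilt phase: constant -(1/2k) alpha^2 (interior; edges one-sided)
  alpha <- 0.3
  rate <- tpe_rhs(I1, alpha * co$x, 530)
  expect_equal(rate[20:45, 20:45],
               matrix(-(0.53 / (4 * pi)) * alpha^2, 26, 26), tolerance = 1e-9)
  # matches the Fresnel phase finite difference at a plane where the
  # intensity has developed structure (periodic screen, unpadded oracle)
  scr <- smooth_phase_screen(128, corr_px = 12, amplitude = 0.2, seed = 3)
  g128 <- sampled_grid(128, pixel_pitch = 1)
  f0 <- complex_field(g128, exp(1i * scr), 530)
  k <- 2 * pi / 0.53
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  z0 <- 50
  fz <- fresnel_propagate(f0, z0, pad = FALSE)
  phz <- wrap(field_phase(fz) - k * z0)
  fd <- wrap(field_phase(fresnel_propagate(f0, z0 + 1, pad = FALSE)) -
               field_phase(fresnel_propagate(f0, z0 - 1, pad = FALSE)) - 2 * k) / 2
  expect_lt(rel_rms(tpe_rhs(intensity(fz), phz, 530), fd), 0.02)
  # flooring is reported
  I0 <- I1; I0[1:3, 1:3] <- 0
  expect_message(tpe_rhs(I0, co$x * 0.1, 530), "clamped 9 pixels")
  # strong gradients (spoke edges) dominate the rate map of a binary star
  star <- siemens_star(sampled_grid(128), 8, 0.25, 0.52)
  phs <- phantom_phase(star, 530)
  rate <- tpe_rhs(matrix(1, 128, 128), phs, 530)
  gx <- spectralTIE:::diff_central(phs, 1, 2L)
  gy <- spectralTIE:::diff_central(phs, 1, 1L)
  edge <- sqrt(gx^2 + gy^2) > 0.1
  expect_gt(mean(abs(rate[edge])), 5 * mean(abs(rate[!edge])))
})

test_that("refocus_stack respects the zeta = lambda z equivalence", {
  scr <- smooth_phase_screen(64, corr_px = 6, amplitude = 2, seed = 9)
  g <- sampled_grid(64, pixel_pitch = 1)
  f <- complex_field(g, exp(1i * scr), 530)
  stack <- refocus_stack(f, list(list(wavelength = 530, distance = 0),
                                 list(wavelength = 530, distance = 400),
                                 list(wavelength = 625, distance = 530 * 400 / 625)))
  expect_equal(stack[[1]], intensity(f), tolerance = 1e-12)
  n1 <- stack[[2]] / mean(stack[[2]])
  n2 <- stack[[3]] / mean(stack[[3]])
  expect_lt(spectralTIE:::rms(n1 - n2), 1e-6)
})

test_that("aperture filter truncates the angular spectrum at the NA cutoff", {
  g <- sampled_grid(64, pixel_pitch = 1)
  co <- grid_coords(g)
  q_lo <- 2 * pi * 2 / 64   # within cutoff
  q_hi <- 2.4               # beyond 2*pi*NA/lambda for NA 0.25 at 530 nm
  f <- complex_field(g, exp(1i * (0.2 * cos(q_lo * co$x) + 0.2 * cos(q_hi * co$x))), 530)
  filt <- aperture_filter(f, 0.25)
  spec <- Mod(spectralTIE:::fft2(filt$amplitude))
  fr <- grid_freqs(g)
  expect_equal(max(spec[sqrt(fr$k2) > 2 * pi * 0.25 / 0.53]), 0, tolerance = 1e-8)
})
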