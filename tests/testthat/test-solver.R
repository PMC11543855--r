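test_that("spectral_to_defocus implements lambda dz = -z dlambda", {
  chs <- channel_specs_from_train(reference_train())
  dz <- spectral_to_defocus(chs, nominal_z = 1150, nominal_lambda = 530)
  expect_equal(unname(dz["G"]), 0)
  expect_equal(unname(dz["R"]), -206.132075472, tolerance = 1e-9)
  expect_equal(unname(dz["B"]), 1150 * 75 / 530, tolerance = 1e-9)
  expect_error(spectral_to_defocus(chs, -1, 530), "nominal_z")
})

test_that("estimate_dI recovers exact slopes for linear-in-lambda planes", {
  g <- sampled_grid(32, pixel_pitch = 1)
  chs <- test_channels(150)
  base <- spectralTIE:::with_seed(5, matrix(runif(32 * 32, 1, 2), 32))
  slope <- spectralTIE:::with_seed(6, matrix(rnorm(32 * 32, sd = 2e-4), 32))
  planes <- lapply(chs, function(ch) base + slope * ch$center_wavelength)
  names(planes) <- names(chs)
  cap <- spectral_capture(g, planes, chs)
  for (mode in c("two_channel_RG", "two_channel_GB", "three_channel")) {
    est <- estimate_dI(cap, qpi_params(derivative_mode = mode))
    expect_equal(est$d_intensity_d_lambda, slope, tolerance = 1e-12)
  }
  # identical planes: zero derivative
  cap0 <- spectral_capture(g, list(R = base, G = base, B = base), chs)
  expect_equal(estimate_dI(cap0)$d_intensity_d_lambda, matrix(0, 32, 32))
  # wavelength spacing of the RG pair
  est <- estimate_dI(cap, qpi_params(derivative_mode = "two_channel_RG"))
  expect_equal(abs(est$equivalent_dz), 150)
  expect_equal(est$central_wavelength, 530)
  expect_identical(est$central_intensity, planes$G)
})

test_that("poisson_solve matches the regularized Fourier eigenvalue exactly", {
  n <- 64
  g <- sampled_grid(n, pixel_pitch = 1)
  co <- grid_coords(g)
  q <- 2 * pi * 3 / n
  eps <- 0.01
  expect_equal(poisson_solve(matrix(0, n, n), eps), matrix(0, n, n))
  src <- -(q^2 + eps) * cos(q * co$x)
  expect_equal(poisson_solve(src, eps), cos(q * co$x), tolerance = 1e-10)
  # round trip: discrete Laplacian attenuates by k^2/(k^2+eps) per mode
  u <- poisson_solve(-q^2 * cos(q * co$x), eps)
  expect_equal(u, cos(q * co$x) * q^2 / (q^2 + eps), tolerance = 1e-10)
})

test_that("tie_invert recovers single modes up to the two-stage attenuation", {
  n <- 64
  g <- sampled_grid(n, pixel_pitch = 1)
  co <- grid_coords(g)
  q <- 2 * pi * 5 / n
  a <- 0.17
  eps <- 0.02
  pars <- qpi_params(epsilon = eps, epsilon_prime = eps)
  dIdz <- (0.53 / (2 * pi)) * a * q^2 * cos(q * co$x)
  phi <- tie_invert(dIdz, pars, grid = g, wavelength = 530)
  expected <- a * cos(q * co$x) * (q^2 / (q^2 + eps))^2
  expect_equal(phi, expected, tolerance = 1e-9)
  # uniform capture: zero phase with a notice
  expect_message(z <- tie_invert(matrix(0, n, n), pars, grid = g, wavelength = 530),
                 "all-zero")
  expect_equal(z, matrix(0, n, n))
})

test_that("a consistent initial phase is a fixed point of the refinement", {
  g <- sampled_grid(64, pixel_pitch = 2)
  star <- siemens_star(g, 8, 0.1, 0.52)
  cap <- simulate_capture(star, reference_train())
  truth <- phantom_phase(star, 530)
  fit <- qpi_retrieve(cap, qpi_params(max_iterations = 3), phase_init = truth)
  expect_lt(fit$residual_history[1], 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  # the returned phase equals the seed in the mean-zero gauge
  expect_equal(fit$phase, truth - mean(truth), tolerance = 1e-8)
})

test_that("refinement contracts the residual on a weak-phase star", {
  g <- sampled_grid(128, pixel_pitch = 2)
  star <- siemens_star(g, 8, 0.05, 0.52)
  cap <- simulate_capture(star, reference_train())
  fit <- qpi_retrieve(cap, qpi_params(max_iterations = 3, projection_iterations = 0))
  h <- fit$residual_history
  expect_gt(length(h), 2)
  expect_lt(h[3], h[1])
  expect_true(all(diff(h[1:3]) < 0))
})

test_that("weak-phase retrieval is linear within 2%", {
  g <- sampled_grid(128, pixel_pitch = 2)
  pars <- qpi_params(max_iterations = 6, projection_iterations = 10)
  rec <- function(h) {
    star <- siemens_star(g, 8, h, 0.52)
    qpi_retrieve(simulate_capture(star, reference_train()), pars)$phase
  }
  p1 <- rec(0.01)
  p2 <- rec(0.02)
  expect_lt(rel_rms(p2, 2 * p1), 0.02)
})

test_that("negating the channel defocus negates the recovered phase", {
  g <- sampled_grid(96, pixel_pitch = 1)
  scr <- smooth_phase_screen(96, corr_px = 8, amplitude = 0.3, seed = 12)
  ph <- phase_phantom(g, (scr - min(scr)) * 0.53 / (2 * pi * 0.52), 0.52)
  pars <- qpi_params(max_iterations = 5, projection_iterations = 10)
  cap_p <- simulate_capture(ph, NULL, channels = test_channels(20))
  # same recorded planes, defocus metadata sign-flipped
  cap_m <- spectral_capture(g, cap_p$planes, test_channels(-20, 0, 16))
  fit_p <- qpi_retrieve(cap_p, pars)
  fit_m <- qpi_retrieve(cap_m, pars)
  expect_lt(rel_rms(fit_m$phase, -fit_p$phase), 0.05)
})

test_that("phase_to_height inverts the phantom phase formula", {
  expect_equal(phase_to_height(0, 530, 0.52), 0)
  expect_equal(phase_to_height(0.2 * pi, 530, 0.52) * 1000, 101.923076923,
               tolerance = 1e-9)
  expect_equal(phase_to_height(1.54115866025, 530, 0.52), 0.25, tolerance = 1e-9)
  expect_error(phase_to_height(1, 530, 0), "index_contrast")
})

test_that("calibration matches a plane inserted verbatim into the stack", {
  g <- sampled_grid(96, pixel_pitch = 1)
  d <- precision_diffuser(diffuser_spec(seed = 21), g)
  f <- phantom_field(d, 530)
  zs <- seq(20, 120, by = 10)
  stack <- lapply(zs, function(z) list(z = z, intensity = intensity(fresnel_propagate(f, z))))
  cap <- spectral_capture(g, list(R = stack[[5]]$intensity,
                                  G = intensity(f),
                                  B = stack[[2]]$intensity),
                          list(R = channel_spec("R", 530.1, 60),
                               G = channel_spec("G", 530, 0),
                               B = channel_spec("B", 529.9, 30)))
  zR <- calibrate_channel_defocus(cap, stack, "R", wavelength_correct = FALSE)
  expect_equal(as.numeric(zR), zs[5], tolerance = 1)
  # boundary peak errors out
  cap_out <- spectral_capture(g, list(R = stack[[1]]$intensity, G = intensity(f),
                                      B = stack[[2]]$intensity), cap$channels)
  expect_error(calibrate_channel_defocus(cap_out, stack, "R"), "boundary")
})

test_that("calibration recovers the generation defocus of a simulated capture", {
  g <- sampled_grid(160, pixel_pitch = 1)
  d <- precision_diffuser(diffuser_spec(seed = 6), g)
  cap <- simulate_capture(d, reference_train())
  f <- phantom_field(d, 530)
  zs <- seq(-220, 220, by = 10)
  stack <- lapply(zs, function(z) list(z = z, intensity = intensity(fresnel_propagate(f, z))))
  for (ch in c("R", "B")) {
    cal <- calibrate_channel_defocus(cap, stack, ch)
    expect_lt(abs(as.numeric(cal) - cap$channels[[ch]]$equivalent_defocus), 10)
  }
  # the featureless in-focus green plane calibrates to z = 0
  calG <- calibrate_channel_defocus(cap, stack, "G")
  expect_lt(abs(as.numeric(calG)), 10)
})
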