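test_that("effective wavelengths locate the source x filter product peak", {
  # monochromatic-like source: a delta-narrow line dominates every channel
  wl <- seq(380, 720, by = 1)
  wts <- rep(1e-9, length(wl)); wts[wl == 530] <- 1
  mono <- spectrum_curve(wl, wts)
  expect_equal(unname(effective_wavelengths(mono, default_bayer_spectra())),
               rep(530, 3), tolerance = 1e-6)
  # equal-width Gaussians at 520/540 nm: product peaks at the mean
  gs <- function(c0) spectrum_curve(wl, exp(-(wl - c0)^2 / (2 * 30^2)))
  expect_equal(unname(effective_wavelengths(gs(520), list(G = gs(540)))), 530,
               tolerance = 1e-6)
  # packaged defaults give exactly the nominal RGB channels
  expect_equal(unname(effective_wavelengths()), c(625, 530, 455), tolerance = 1e-9)
  # degenerate (non-overlapping) channel errors out
  lo <- spectrum_curve(seq(380, 420), rep(1, 41))
  expect_error(effective_wavelengths(lo, list(R = gs(700))), "degenerate")
})

test_that("train-derived channel defocus follows the exact chromatic law", {
  chs <- channel_specs_from_train(reference_train())
  expect_equal(chs$R$equivalent_defocus, 152, tolerance = 1e-9)
  expect_equal(chs$G$equivalent_defocus, 0)
  expect_equal(chs$B$equivalent_defocus, -164.835164835, tolerance = 1e-6)
  # the green-stack (zeta) positions are the linearized focal shifts
  expect_equal(chs$R$equivalent_defocus * 625 / 530, 179.245283019, tolerance = 1e-6)
  expect_error(channel_specs_from_train(reference_train(), c(625, 625, 455)), "distinct")
})

test_that("a flat phantom captures as three unit planes; star flips contrast", {
  g <- sampled_grid(64, pixel_pitch = 2)
  flat <- phase_phantom(g, matrix(0, 64, 64), 0.52)
  cap <- simulate_capture(flat, reference_train())
  for (p in cap$planes) expect_equal(p, matrix(1, 64, 64), tolerance = 1e-9)

  # red and blue sit on opposite sides of focus: opposite-contrast spokes
  g2 <- sampled_grid(256, pixel_pitch = 1)
  star <- siemens_star(g2, 16, 0.25, 0.52)
  cap2 <- simulate_capture(star, reference_train())
  m <- siemens_star_masks(star, r_min = 40, r_max = 90)
  dR <- mean(cap2$planes$R[m$spoke]) - mean(cap2$planes$R[m$gap])
  dB <- mean(cap2$planes$B[m$spoke]) - mean(cap2$planes$B[m$gap])
  expect_lt(dR * dB, 0)
  # green at focus is featureless for a pure-phase target
  expect_lt(stats::sd(cap2$planes$G), 1e-6)
})

test_that("diffuser capture shows complementary defocus contrast with the stated signs", {
  g <- sampled_grid(192, pixel_pitch = 1)
  # moderate screen: in the transport-linear regime defocus contrast flips
  # sign across focus, so red and blue planes anticorrelate
  d <- precision_diffuser(diffuser_spec(divergence_angle = 1, seed = 4), g)
  cap <- simulate_capture(d, reference_train())
  f <- phantom_field(d, 530)
  zR <- cap$channels$R$equivalent_defocus * 625 / 530  # zeta-equivalent position
  plus <- intensity(fresnel_propagate(f, zR))
  minus <- intensity(fresnel_propagate(f, -zR))
  cR <- as.vector(cap$planes$R - mean(cap$planes$R))
  expect_gt(cor(cR, as.vector(plus - mean(plus))),
            cor(cR, as.vector(minus - mean(minus))))
  # red and blue caustics are complementary (anti-correlated)
  expect_lt(cor(as.vector(cap$planes$R), as.vector(cap$planes$B)), 0)
})

test_that("Bayer mosaic/demosaic round-trips smooth captures within 1%", {
  g <- sampled_grid(64, pixel_pitch = 1)
  co <- grid_coords(g)
  mk <- function(a) 1 + a * cos(2 * pi * co$x / 64) * sin(2 * pi * co$y / 64)
  planes <- list(R = mk(0.3), G = mk(0.2), B = mk(0.25))
  cap <- spectral_capture(g, planes, test_channels(150))
  raw <- bayer_mosaic(cap)
  expect_identical(attr(raw, "pattern"), "RGGB")
  demo <- bayer_demosaic(raw)
  for (nm in names(planes))
    expect_lt(rel_rms(demo[[nm]], planes[[nm]]), 0.01)
  expect_error(bayer_demosaic(matrix(1, 8, 8)), "RGGB")
})

test_that("fiber bundle acts as intensity-only hexagonal pixels", {
  expect_equal(hex_pitch_from_density(18000), 8.00937138045, tolerance = 1e-6)
  g <- sampled_grid(128, pixel_pitch = 1)
  spec <- fiber_bundle_spec(core_diameter = 3, lattice_pitch = 8, extent = 128)
  uni <- spectral_capture(g, list(R = matrix(1, 128, 128), G = matrix(1, 128, 128),
                                  B = matrix(1, 128, 128)), test_channels(150))
  tu <- fiber_bundle_transmit(uni, spec)
  vals <- unique(round(as.vector(tu$planes$R), 9))
  expect_setequal(vals, c(0, 1))   # cores carry the input, cladding dark
  # idempotent up to cladding rendering
  tu2 <- fiber_bundle_transmit(tu, spec)
  expect_equal(tu2$planes$G, tu$planes$G, tolerance = 1e-9)
  # per-core flux preserved for a structured scene
  co <- grid_coords(g)
  sc <- spectral_capture(g, list(R = 1 + 0.5 * cos(co$x / 6), G = matrix(1, 128, 128),
                                 B = matrix(1, 128, 128)), test_channels(150))
  ts <- fiber_bundle_transmit(sc, spec)
  idx <- spectralTIE:::fiber_core_index(g, spec)
  for (px in idx[c(1, 10, 50)])
    expect_equal(sum(ts$planes$R[px]), sum(sc$planes$R[px]), tolerance = 1e-9)
  # all three channels share identical honeycomb peak locations
  hR <- honeycomb_power(ts$planes$R, 8, 1)
  hG <- honeycomb_power(ts$planes$G, 8, 1)
  expect_gt(hR, 0.01)
  expect_gt(hG, 0.01)
  expect_error(fiber_bundle_transmit(
    spectral_capture(sampled_grid(32, pixel_pitch = 2),
                     list(R = matrix(1, 32, 32), G = matrix(1, 32, 32), B = matrix(1, 32, 32)),
                     test_channels(150)), spec), "coarse")
  expect_error(fiber_bundle_spec(5, 3), "lattice_pitch")
})

test_that("noise model is Poisson-scaled, seeded, and vanishes at high flux", {
  g <- sampled_grid(64, pixel_pitch = 1)
  uni <- spectral_capture(g, list(R = matrix(1, 64, 64), G = matrix(1, 64, 64),
                                  B = matrix(1, 64, 64)), test_channels(150))
  n1 <- add_noise(uni, noise_model(1e4, 0, seed = 42))
  n2 <- add_noise(uni, noise_model(1e4, 0, seed = 42))
  expect_identical(n1$planes$R, n2$planes$R)     # determinism under seed
  expect_equal(stats::sd(n1$planes$R), 0.01, tolerance = 0.1)
  hi <- add_noise(uni, noise_model(1e12, 0, seed = 1))
  expect_lt(max(abs(hi$planes$G - 1)), 1e-4)     # noiseless limit
  rn <- add_noise(uni, noise_model(1e12, 0.05, seed = 7))
  expect_equal(stats::sd(rn$planes$B), 0.05, tolerance = 0.1)
})
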