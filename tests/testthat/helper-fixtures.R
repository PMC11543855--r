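# Shared fixtures: all synthetic, generated in code at test time.

reference_train <- function() optical_train(250, 1000, design_wavelength = 530)

# Channel triple with custom physical defocus (um), nominal RGB wavelengths.
test_channels <- function(zR, zG = 0, zB = -0.8 * zR) {
  list(R = channel_spec("R", 625, zR),
       G = channel_spec("G", 530, zG),
       B = channel_spec("B", 455, zB))
}

# Smooth band-limited random phase screen (rad) on an n x n grid:
# Gaussian-filtered white noise, peak-normalized to `amplitude`.
smooth_phase_screen <- function(n, corr_px = 10, amplitude = 0.2, seed = 1) {
  g <- sampled_grid(n, pixel_pitch = 1)
  fr <- grid_freqs(g)
  scr <- spectralTIE:::with_seed(seed, {
    noise <- matrix(stats::rnorm(n * n), n)
    Re(spectralTIE:::ifft2(spectralTIE:::fft2(noise) * exp(-fr$k2 * corr_px^2)))
  })
  amplitude * scr / max(abs(scr))
}

# Direct (brute-force) Fresnel quadrature on the same sampling: the kernel
# exp(ik((x-x')^2+(y-y')^2)/2z) is separable, so the double sum is
# Kx %*% E %*% t(Ky). Independent oracle for the FFT propagator.
fresnel_quadrature <- function(field, distance) {
  g <- field$grid
  lam <- field$wavelength_um
  k <- 2 * pi / lam
  xs <- (seq_len(g$n_cols) - (g$n_cols + 1) / 2) * g$pixel_pitch
  ys <- (seq_len(g$n_rows) - (g$n_rows + 1) / 2) * g$pixel_pitch
  cx <- exp(1i * k * outer(xs, xs, function(a, b) (a - b)^2) / (2 * distance))
  cy <- exp(1i * k * outer(ys, ys, function(a, b) (a - b)^2) / (2 * distance))
  pref <- g$pixel_pitch^2 * exp(1i * k * distance) / (1i * lam * distance)
  out <- pref * (cy %*% field$amplitude %*% t(cx))
  complex_field(g, out, lam * 1000)
}

rel_rms <- function(a, b) spectralTIE:::rms(a - b) / spectralTIE:::rms(b)
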