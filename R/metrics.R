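# Quantitative validation: phase/height error, the Siemens-star contrast
# transfer curve, plateau-height measurement, honeycomb spectral power, and
# the closed-form optical budget.

#' Relative RMS phase error
#'
#' RMS of (recovered - truth) after mean removal over the mask, reported
#' relative to the RMS of the (equally processed) truth. Comparisons are
#' gauge-invariant: an additive constant contributes nothing. An optional
#' spatial-frequency band restricts both maps to modes with |k| inside
#' `band_limit` before masking.
#'
#' @param recovered,truth Co-registered matrices.
#' @param mask Logical matrix; default all pixels.
#' @param band_limit Optional `c(kmin, kmax)` in rad/um.
#' @param pixel_pitch Grid pitch, um.
#' @return Dimensionless relative RMSE.
#' @export
phase_rmse <- function(recovered, truth, mask = NULL, band_limit = NULL,
                       pixel_pitch = 1) {
  if (!identical(dim(recovered), dim(truth))) stop("maps must be co-registered")
  mask <- mask %||% matrix(TRUE, nrow(truth), ncol(truth))
  if (!any(mask)) stop("empty mask")
  if (!is.null(band_limit)) {
    recovered <- band_filter(recovered, band_limit, pixel_pitch)
    truth <- band_filter(truth, band_limit, pixel_pitch)
  }
  err <- recovered[mask] - truth[mask]
  err <- err - mean(err)
  tr <- truth[mask] - mean(truth[mask])
  rms(err) / rms(tr)
}

band_filter <- function(m, band, pitch) {
  kx <- fft_freq(ncol(m), pitch)
  ky <- fft_freq(nrow(m), pitch)
  K <- sqrt(matrix(kx^2, nrow(m), ncol(m), byrow = TRUE) + matrix(ky^2, nrow(m), ncol(m)))
  keep <- K >= band[1] & K <= band[2]
  Re(ifft2(fft2(m - mean(m)) * keep))
}

#' Siemens-star contrast transfer curve
#'
#' Samples the phase map along circles of the given radii, forms the robust
#' contrast (q95 - q5) / (q95 + q5) per circle after a single global
#' baseline shift anchoring the map's low quantile at zero (so the exact
#' binary target scores 1 at every resolvable radius), and reports the
#' resolution estimate: the largest radius below which the contrast stays
#' under the threshold.
#'
#' @param phase Phase (or height) map.
#' @param center Star center `c(x, y)` in um (grid-centered coordinates).
#' @param n_spokes Spoke count.
#' @param radii Radii to sample, um (strictly increasing).
#' @param pixel_pitch Grid pitch, um.
#' @param probs Quantiles for the robust extrema (default 0.05/0.95).
#' @param threshold Contrast threshold for the resolution estimate
#'   (default just below unity, mirroring a below-unity dip criterion).
#' @return Object of class `contrast_curve`: data frame with `radius`,
#'   `spatial_frequency` (cycles/um), `contrast`, `resolvable`; plus
#'   `resolution_radius` and `resolution_frequency` attributes (NA when the
#'   contrast never drops).
#' @export
contrast_curve <- function(phase, center = c(0, 0), n_spokes, radii,
                           pixel_pitch = 1, probs = c(0.05, 0.95),
                           threshold = 1 - 1e-3) {
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be strictly increasing")
  base <- stats::quantile(phase, 0.01, names = FALSE)
  ph <- phase - base
  nr <- nrow(ph); nc <- ncol(ph)
  res <- lapply(radii, function(r) {
    n_samp <- max(64L, ceiling(4 * pi * r / pixel_pitch))
    th <- seq(0, 2 * pi, length.out = n_samp + 1L)[-1L]
    x <- center[1] + r * cos(th)
    y <- center[2] + r * sin(th)
    ci <- x / pixel_pitch + (nc + 1) / 2
    ri <- y / pixel_pitch + (nr + 1) / 2
    ok <- ci >= 1 & ci <= nc & ri >= 1 & ri <= nr
    if (!all(ok)) stop("radius ", r, " falls outside the map")
    vals <- bilinear_sample(ph, ri, ci)
    period_px <- 2 * pi * r / (n_spokes * pixel_pitch)
    resolvable <- period_px >= 2
    qs <- stats::quantile(vals, probs, names = FALSE)
    contr <- if (qs[1] + qs[2] <= .Machine$double.eps) 0 else (qs[2] - qs[1]) / (qs[2] + qs[1])
    c(contrast = max(contr, 0), resolvable = resolvable)
  })
  out <- data.frame(radius = radii,
                    spatial_frequency = n_spokes / (2 * pi * radii),
                    contrast = vapply(res, `[[`, numeric(1), "contrast"),
                    resolvable = as.logical(vapply(res, `[[`, numeric(1), "resolvable")))
  below <- out$contrast < threshold
  r_est <- NA_real_
  # largest radius r* such that all radii <= r* are below threshold
  run <- cumprod(below) == 1
  if (any(run & out$resolvable)) r_est <- max(out$radius[run])
  else if (any(run)) r_est <- max(out$radius[run])
  attr(out, "resolution_radius") <- r_est
  attr(out, "resolution_frequency") <- if (is.na(r_est)) NA_real_ else n_spokes / (2 * pi * r_est)
  class(out) <- c("contrast_curve", class(out))
  out
}

bilinear_sample <- function(m, ri, ci) {
  r0 <- pmax(pmin(floor(ri), nrow(m) - 1L), 1L)
  c0 <- pmax(pmin(floor(ci), ncol(m) - 1L), 1L)
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Write a contrast curve to CSV
#' @param curve A [contrast_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contrast_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Step (plateau) height of a recovered star target
#'
#' Median over eroded spoke interiors minus median over eroded gaps — the
#' gauge-free measurement of a binary step height.
#'
#' @param map Recovered height (or phase) map.
#' @param star The ground-truth [siemens_star()] phantom (provides the
#'   measurement masks; its heights are not used for the estimate).
#' @param ... Passed to [siemens_star_masks()].
#' @return Scalar step estimate in the units of `map`.
#' @export
star_step_height <- function(map, star, ...) {
  masks <- siemens_star_masks(star, ...)
  if (!any(masks$spoke) || !any(masks$gap)) stop("empty measurement masks")
  stats::median(map[masks$spoke]) - stats::median(map[masks$gap])
}

#' Normalized spectral power at the honeycomb lattice frequency
#'
#' Fraction of a map's AC power lying in an annulus around the hexagonal
#' lattice's fundamental spatial frequency — the quantitative handle on
#' fiber-bundle honeycomb artifacts.
#'
#' @param map Real matrix.
#' @param lattice_pitch Fiber lattice pitch, um.
#' @param pixel_pitch Grid pitch, um.
#' @param rel_width Annulus half-width relative to the peak frequency.
#' @return Dimensionless power fraction.
#' @export
honeycomb_power <- function(map, lattice_pitch, pixel_pitch = 1, rel_width = 0.15) {
  k_h <- 4 * pi / (sqrt(3) * lattice_pitch)   # hex reciprocal-lattice magnitude
  kx <- fft_freq(ncol(map), pixel_pitch)
  ky <- fft_freq(nrow(map), pixel_pitch)
  K <- sqrt(matrix(kx^2, nrow(map), ncol(map), byrow = TRUE) + matrix(ky^2, nrow(map), ncol(map)))
  P <- Mod(fft2(map - mean(map)))^2
  total <- sum(P)
  if (total == 0) return(0)
  ring <- K >= k_h * (1 - rel_width) & K <= k_h * (1 + rel_width)
  sum(P[ring]) / total
}

#' Closed-form optical budget of the imaging train
#'
#' The scalar figures of merit of the single-lens chromatic QPI system:
#' numerical aperture, diffraction-limited lateral resolution, phase-noise
#' limited height sensitivity, sensor oversampling and effective pixel.
#'
#' @param train An [optical_train()].
#' @param wavelength Wavelength, nm.
#' @param min_phase Smallest resolvable phase, radians (default 0.2 pi).
#' @param index_contrast Index contrast used for the height sensitivity.
#' @param spot Diffraction-limited spot size at the object, um.
#' @param magnification Relay magnification onto the sensor.
#' @param pixel Sensor pixel size, um.
#' @return Named list: `numerical_aperture`, `lateral_resolution` (um),
#'   `height_sensitivity` (um), `height_sensitivity_waves` (multiples of
#'   lambda), `oversampling_factor`, `effective_pixel` (um).
#' @examples
#' optical_budget(optical_train(250, 1000), 530, index_contrast = 0.52)
#' @export
optical_budget <- function(train, wavelength = 530, min_phase = 0.2 * pi,
                           index_contrast = 0.52, spot = NULL,
                           magnification = 20, pixel = 3.2) {
  stopifnot(inherits(train, "optical_train"))
  stopifnot_scalar_pos(wavelength, "wavelength")
  lam <- nm_to_um(wavelength)
  na <- train$numerical_aperture
  lateral <- lam / (2 * na)
  spot <- spot %||% lateral
  list(numerical_aperture = na,
       lateral_resolution = lateral,
       height_sensitivity = min_phase * lam / (2 * pi * index_contrast),
       height_sensitivity_waves = min_phase / (2 * pi * index_contrast),
       oversampling_factor = spot * magnification / pixel,
       effective_pixel = pixel / magnification)
}
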