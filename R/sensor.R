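# Everything between the optical field and the recorded planes: spectral
# channel definition (source x Bayer), the single-shot three-channel capture
# through the chromatic train, optional Bayer mosaic/demosaic, fiber-bundle
# intensity-only transmission, and photon/read noise.

#' Spectral curve
#'
#' A sampled non-negative spectrum (source emission or Bayer filter
#' response).
#'
#' @param wavelengths Strictly increasing wavelengths, nm (>= 3 points).
#' @param weights Non-negative weights, same length, not all zero.
#' @return Object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(wavelengths, weights) {
  if (length(wavelengths) < 3 || length(weights) != length(wavelengths))
    stop("need at least 3 matched (wavelength, weight) points")
  if (is.unsorted(wavelengths, strictly = TRUE)) stop("wavelengths must be strictly increasing")
  if (any(weights < 0) || all(weights == 0)) stop("weights must be non-negative and not all zero")
  structure(list(wavelengths = wavelengths, weights = weights), class = "spectrum_curve")
}

#' Default source spectrum
#'
#' Idealized flat white-light emission over 380-720 nm. Real LED spectra can
#' be supplied as [spectrum_curve()]s; with the flat default the effective
#' channel wavelengths coincide exactly with the Bayer filter centers.
#' @return A [spectrum_curve()].
#' @export
default_source_spectrum <- function() {
  wl <- seq(380, 720, by = 1)
  spectrum_curve(wl, rep(1, length(wl)))
}

#' Default Bayer filter responses
#'
#' Gaussian approximations to RGB Bayer filter curves centered at 625, 530
#' and 455 nm; a documented stand-in for untabulated camera curves, chosen
#' so that with the default source the effective wavelengths are exactly
#' 625/530/455 nm.
#' @return Named list of three [spectrum_curve()]s (`R`, `G`, `B`).
#' @export
default_bayer_spectra <- function() {
  wl <- seq(380, 720, by = 1)
  gauss <- function(c0, s) spectrum_curve(wl, exp(-(wl - c0)^2 / (2 * s^2)))
  list(R = gauss(625, 28), G = gauss(530, 35), B = gauss(455, 28))
}

#' Effective channel wavelengths from source and filter curves
#'
#' Per channel, the argmax of the pointwise product of the source emission
#' and the filter response, located by quadratic interpolation around the
#' discrete peak.
#'
#' @param source A [spectrum_curve()].
#' @param bayer Named list of three [spectrum_curve()]s.
#' @return Named numeric vector of effective wavelengths, nm.
#' @examples
#' effective_wavelengths(default_source_spectrum(), default_bayer_spectra())
#' @export
effective_wavelengths <- function(source = default_source_spectrum(),
                                  bayer = default_bayer_spectra()) {
  stopifnot(inherits(source, "spectrum_curve"))
  vapply(bayer, function(filt) {
    stopifnot(inherits(filt, "spectrum_curve"))
    src <- stats::approx(source$wavelengths, source$weights, xout = filt$wavelengths,
                         rule = 1)$y
    prod <- src * filt$weights
    prod[is.na(prod)] <- 0
    if (max(prod) <= 1e-10 * max(filt$weights) * max(source$weights))
      stop("source and filter curves do not overlap (degenerate channel)")
    i <- which.max(prod)
    if (i == 1L || i == length(prod)) return(filt$wavelengths[i])
    # quadratic (parabolic) sub-sample interpolation around the peak
    y1 <- prod[i - 1]; y2 <- prod[i]; y3 <- prod[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
    filt$wavelengths[i] + delta * (filt$wavelengths[i + 1] - filt$wavelengths[i])
  }, numeric(1))
}

#' Spectral channel specification
#'
#' @param name One of "R", "G", "B".
#' @param center_wavelength Effective wavelength, nm.
#' @param equivalent_defocus Signed equivalent defocus relative to the green
#'   image plane, um (positive: the sensor lies beyond this channel's
#'   focus).
#' @return Object of class `channel_spec`.
#' @export
channel_spec <- function(name, center_wavelength, equivalent_defocus) {
  if (!name %in% c("R", "G", "B")) stop("channel name must be R, G or B")
  stopifnot_scalar_pos(center_wavelength, "center_wavelength")
  structure(list(name = name, center_wavelength = center_wavelength,
                 equivalent_defocus = equivalent_defocus),
            class = "channel_spec")
}

#' Channel specifications from the chromatic train
#'
#' Derives the per-channel physical defocus from the exact chromatic focal
#' law (lambda * f conserved): dz_c = f(lambda_ref) - f(lambda_c), with the
#' reference (green) channel defining z = 0 at the image plane. Longer
#' wavelengths focus shorter, so the fixed sensor sits beyond the red focus
#' and its defocus is positive. By the zeta = lambda z equivalence, the
#' matching position of channel c in a green through-focus stack is
#' dz_c * lambda_c / lambda_ref = f (lambda_c - lambda_ref) / lambda_ref,
#' the linearized focal shift (~180 um for red at f = 1 mm).
#'
#' @param train An [optical_train()].
#' @param wavelengths Channel wavelengths, nm, in R/G/B order.
#' @param reference_wavelength Reference (in-focus) wavelength, nm; default
#'   the train's design wavelength.
#' @return Named list of three [channel_spec()]s.
#' @examples
#' channel_specs_from_train(optical_train(250, 1000))
#' @export
channel_specs_from_train <- function(train, wavelengths = c(R = 625, G = 530, B = 455),
                                     reference_wavelength = train$design_wavelength) {
  stopifnot(inherits(train, "optical_train"))
  if (length(wavelengths) != 3 || anyDuplicated(wavelengths))
    stop("need three distinct channel wavelengths")
  nms <- names(wavelengths) %||% c("R", "G", "B")
  out <- Map(function(nm, wl) {
    dz <- train$focal_length - focal_at_wavelength(train$focal_length,
                                                   reference_wavelength, wl)
    channel_spec(nm, wl, dz)
  }, nms, wavelengths)
  names(out) <- nms
  out
}

#' Single-shot spectral capture
#'
#' Three co-registered intensity planes with per-channel effective
#' wavelength and equivalent defocus; the single-shot measurement.
#'
#' @param grid A [sampled_grid()].
#' @param planes Named list of three non-negative intensity matrices
#'   (R, G, B).
#' @param channels Named list of three [channel_spec()]s.
#' @param exposure_scale Photons per unit intensity (metadata).
#' @return Object of class `spectral_capture`.
#' @export
spectral_capture <- function(grid, planes, channels, exposure_scale = 1) {
  stopifnot(inherits(grid, "sampled_grid"))
  if (length(planes) != 3 || length(channels) != 3)
    stop("a spectral capture has exactly three planes and channels")
  for (p in planes) {
    if (!is.matrix(p) || nrow(p) != grid$n_rows || ncol(p) != grid$n_cols)
      stop("planes must be matrices co-registered on the capture grid")
    if (any(!is.finite(p)) || any(p < 0)) stop("intensities must be finite and non-negative")
  }
  wl <- vapply(channels, function(ch) ch$center_wavelength, numeric(1))
  if (anyDuplicated(wl)) stop("channel wavelengths must be distinct")
  names(planes) <- names(channels) <- vapply(channels, function(ch) ch$name, character(1))
  structure(list(grid = grid, planes = planes, channels = channels,
                 exposure_scale = exposure_scale),
            class = "spectral_capture")
}

#' @export
print.spectral_capture <- function(x, ...) {
  cat(sprintf("spectral_capture: %d x %d px, pitch %g um\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_pitch))
  for (ch in x$channels)
    cat(sprintf("  %s: %g nm, equivalent defocus %+.1f um, mean intensity %.4g\n",
                ch$name, ch$center_wavelength, ch$equivalent_defocus,
                mean(x$planes[[ch$name]])))
  invisible(x)
}

#' Noise model for the color sensor
#'
#' @param photon_scale Expected photons at unit intensity (>= 0; larger
#'   means less shot noise).
#' @param read_noise_sd Additive Gaussian read noise, counts relative to
#'   unit intensity.
#' @param seed Integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 1e4, read_noise_sd = 0, seed = 1) {
  if (photon_scale < 0 || read_noise_sd < 0) stop("noise parameters must be >= 0")
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a single-shot three-channel capture
#'
#' For each channel the phantom's focal-plane field is built at the channel
#' wavelength and propagated by the channel's equivalent defocus (the
#' reduced model of imaging through the chromatic train); the recorded
#' plane is its intensity. Optionally the three planes are Bayer-mosaicked
#' (RGGB) and bilinearly demosaicked, and photon + read noise applied.
#'
#' @param phantom A [phase_phantom()].
#' @param train An [optical_train()]; used to derive channel defocus when
#'   `channels` is NULL.
#' @param channels Optional named list of three [channel_spec()]s
#'   (overrides the train-derived defocus).
#' @param wavelengths Channel wavelengths, nm, when deriving from the train.
#' @param noise Optional [noise_model()].
#' @param mosaic Apply Bayer RGGB sampling then bilinear demosaic.
#' @param pad Passed to [fresnel_propagate()].
#' @return A [spectral_capture()].
#' @export
simulate_capture <- function(phantom, train, channels = NULL,
                             wavelengths = c(R = 625, G = 530, B = 455),
                             noise = NULL, mosaic = FALSE, pad = TRUE) {
  stopifnot(inherits(phantom, "phase_phantom"))
  if (is.null(channels)) channels <- channel_specs_from_train(train, wavelengths)
  g <- phantom$grid
  n_eff <- min(g$n_rows, g$n_cols) * (if (pad) 2L else 1L)
  planes <- lapply(channels, function(ch) {
    if (!tf_alias_ok(nm_to_um(ch$center_wavelength), ch$equivalent_defocus,
                     n_eff, g$pixel_pitch))
      warning(sprintf("channel %s defocus %g um exceeds the alias-safe range for this grid",
                      ch$name, ch$equivalent_defocus))
    f <- phantom_field(phantom, ch$center_wavelength)
    intensity(fresnel_propagate(f, ch$equivalent_defocus, pad = pad))
  })
  cap <- spectral_capture(g, planes, channels)
  if (mosaic) cap <- bayer_cycle(cap)
  if (!is.null(noise)) cap <- add_noise(cap, noise)
  cap
}

#' Bayer RGGB mosaic of a capture
#'
#' Samples the three planes onto a single RGGB raw frame (R at odd/odd, B at
#' even/even, G elsewhere, in 2x2 tiles).
#'
#' @param capture A [spectral_capture()].
#' @return Single raw matrix with attribute `pattern = "RGGB"`.
#' @export
bayer_mosaic <- function(capture) {
  stopifnot(inherits(capture, "spectral_capture"))
  nr <- capture$grid$n_rows; nc <- capture$grid$n_cols
  odd_r <- (seq_len(nr) %% 2) == 1
  odd_c <- (seq_len(nc) %% 2) == 1
  raw <- matrix(0, nr, nc)
  raw[odd_r, odd_c] <- capture$planes$R[odd_r, odd_c]
  raw[!odd_r, !odd_c] <- capture$planes$B[!odd_r, !odd_c]
  raw[odd_r, !odd_c] <- capture$planes$G[odd_r, !odd_c]
  raw[!odd_r, odd_c] <- capture$planes$G[!odd_r, odd_c]
  attr(raw, "pattern") <- "RGGB"
  raw
}

#' Bilinear demosaic of an RGGB raw frame
#'
#' @param raw Matrix from [bayer_mosaic()].
#' @return Named list of three interpolated planes (R, G, B).
#' @export
bayer_demosaic <- function(raw) {
  if (!identical(attr(raw, "pattern"), "RGGB")) stop("raw frame must carry the RGGB pattern tag")
  nr <- nrow(raw); nc <- ncol(raw)
  odd_r <- (seq_len(nr) %% 2) == 1
  odd_c <- (seq_len(nc) %% 2) == 1
  interp_plane <- function(mask) {
    vals <- ifelse(mask, raw, 0)
    w <- matrix(as.numeric(mask), nr, nc)
    k <- matrix(c(0.25, 0.5, 0.25, 0.5, 1, 0.5, 0.25, 0.5, 0.25), 3, 3)
    num <- conv3x3(vals, k)
    den <- conv3x3(w, k)
    num / pmax(den, .Machine$double.eps)
  }
  maskR <- outer(odd_r, odd_c, `&`)
  maskB <- outer(!odd_r, !odd_c, `&`)
  maskG <- !(maskR | maskB)
  list(R = interp_plane(maskR), G = interp_plane(maskG), B = interp_plane(maskB))
}

bayer_cycle <- function(capture) {
  planes <- bayer_demosaic(bayer_mosaic(capture))
  spectral_capture(capture$grid, planes, capture$channels, capture$exposure_scale)
}

#' Coherent fiber-bundle specification
#'
#' Hexagonally packed intensity-only fiber cores. The default pitch 8.0 um
#' reconciles 3 um cores with a hexagonal packing density of 18,000 cores
#' per mm^2 (density = 2 / (sqrt(3) pitch^2)).
#'
#' @param core_diameter Core diameter, um.
#' @param lattice_pitch Center-to-center pitch, um (>= core diameter).
#' @param extent Bundle extent (side of the square region covered), um.
#' @return Object of class `fiber_bundle_spec`.
#' @export
fiber_bundle_spec <- function(core_diameter = 3, lattice_pitch = 8, extent = 1000) {
  stopifnot_scalar_pos(core_diameter, "core_diameter")
  stopifnot_scalar_pos(lattice_pitch, "lattice_pitch")
  if (lattice_pitch < core_diameter) stop("lattice_pitch must be >= core_diameter")
  structure(list(core_diameter = core_diameter, lattice_pitch = lattice_pitch,
                 extent = extent),
            class = "fiber_bundle_spec")
}

#' Hexagonal lattice pitch from a core density
#'
#' Inverts the hexagonal packing density d = 2 / (sqrt(3) pitch^2).
#' @param cores_per_mm2 Core density per mm^2.
#' @return Pitch in um.
#' @examples
#' hex_pitch_from_density(18000)  # ~8.0 um
#' @export
hex_pitch_from_density <- function(cores_per_mm2) {
  stopifnot_scalar_pos(cores_per_mm2, "cores_per_mm2")
  sqrt(2 / (sqrt(3) * cores_per_mm2)) * 1000
}

#' Intensity-only transmission through a coherent fiber bundle
#'
#' Each core averages the incident intensity over its disk and re-emits it
#' as a constant over the disk; cladding between cores is set to a fixed
#' dark level. Total per-core flux is preserved and the output carries the
#' hexagonal (honeycomb) spatial-frequency signature at the lattice pitch,
#' identical across the three channels.
#'
#' @param capture A [spectral_capture()] whose grid covers the bundle
#'   extent.
#' @param spec A [fiber_bundle_spec()].
#' @param cladding_level Intensity assigned between cores (default 0).
#' @return A [spectral_capture()] of the proximal (transmitted) image.
#' @export
fiber_bundle_transmit <- function(capture, spec, cladding_level = 0) {
  stopifnot(inherits(capture, "spectral_capture"), inherits(spec, "fiber_bundle_spec"))
  g <- capture$grid
  if (g$pixel_pitch > spec$core_diameter / 2)
    stop("grid is too coarse to resolve the fiber cores (need pitch <= core_diameter / 2)")
  idx <- fiber_core_index(g, spec)
  planes <- lapply(capture$planes, function(p) {
    out <- matrix(cladding_level, g$n_rows, g$n_cols)
    means <- vapply(idx, function(px) mean(p[px]), numeric(1))
    for (i in seq_along(idx)) out[idx[[i]]] <- means[i]
    out
  })
  spectral_capture(g, planes, capture$channels, capture$exposure_scale)
}

# Pixel index sets of the hexagonal core disks covering the grid.
fiber_core_index <- function(grid, spec) {
  co <- grid_coords(grid)
  half <- min(spec$extent, max(grid$n_rows, grid$n_cols) * grid$pixel_pitch) / 2
  p <- spec$lattice_pitch
  rowstep <- p * sqrt(3) / 2
  rows <- seq(-ceiling(half / rowstep), ceiling(half / rowstep))
  R <- spec$core_diameter / 2
  idx <- list()
  xs <- co$x[1, ]; ys <- co$y[, 1]
  for (j in rows) {
    cy <- j * rowstep
    if (abs(cy) > half + R) next
    xoff <- if (j %% 2 == 0) 0 else p / 2
    cols <- seq(-ceiling((half + p) / p), ceiling((half + p) / p))
    for (i in cols) {
      cx <- i * p + xoff
      if (abs(cx) > half + R) next
      ci <- which(abs(xs - cx) <= R)
      ri <- which(abs(ys - cy) <= R)
      if (!length(ci) || !length(ri)) next
      sub <- expand.grid(r = ri, c = ci)
      keep <- (xs[sub$c] - cx)^2 + (ys[sub$r] - cy)^2 <= R^2
      sub <- sub[keep, , drop = FALSE]
      if (nrow(sub)) idx[[length(idx) + 1L]] <- (sub$c - 1L) * grid$n_rows + sub$r
    }
  }
  idx
}

#' Apply photon and read noise to a capture
#'
#' Independent per-pixel Poisson photon noise at `photon_scale` expected
#' photons per unit intensity, rescaled back to intensity units, plus
#' additive Gaussian read noise. Reproducible under the model's seed.
#'
#' @param capture A [spectral_capture()].
#' @param noise A [noise_model()] with `photon_scale > 0`.
#' @return A noisy [spectral_capture()].
#' @export
add_noise <- function(capture, noise) {
  stopifnot(inherits(capture, "spectral_capture"), inherits(noise, "noise_model"))
  if (noise$photon_scale <= 0) stop("photon_scale must be > 0 to apply noise")
  planes <- with_seed(noise$seed, lapply(capture$planes, function(p) {
    counts <- stats::rpois(length(p), lambda = noise$photon_scale * p)
    out <- matrix(counts / noise$photon_scale, nrow(p), ncol(p))
    if (noise$read_noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(p), sd = noise$read_noise_sd), nrow(p))
    pmax(out, 0)
  }))
  spectral_capture(capture$grid, planes, capture$channels, capture$exposure_scale)
}
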