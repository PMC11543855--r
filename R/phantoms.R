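# Synthetic ground-truth phase targets: Siemens star, precision diffuser
# screen, filament (alga-like) phantom, and the Talbot onset estimate.

#' Pure-phase phantom
#'
#' Ground truth for simulation: a physical height map h(x, y) with refractive
#' index contrast delta-n against the surround. Its phase at wavelength
#' lambda is phi = 2 pi h dn / lambda, so phase scales exactly as 1/lambda.
#' With no absorption the target is perfectly transparent at focus
#' (I = 1 everywhere).
#'
#' @param grid A [sampled_grid()].
#' @param height Height map in um, non-negative.
#' @param index_contrast Refractive index contrast (> 0), e.g. 0.52 for glass
#'   in air.
#' @param absorption Optional absorption map in `[0, 1]` (fraction of
#'   intensity removed); default fully transparent.
#' @return Object of class `phase_phantom`.
#' @export
phase_phantom <- function(grid, height, index_contrast, absorption = NULL) {
  stopifnot(inherits(grid, "sampled_grid"))
  if (!is.matrix(height) || nrow(height) != grid$n_rows || ncol(height) != grid$n_cols)
    stop("height must be a matrix matching the grid")
  if (any(height < 0) || any(!is.finite(height))) stop("height must be finite and >= 0")
  stopifnot_scalar_pos(index_contrast, "index_contrast")
  if (!is.null(absorption)) {
    if (!identical(dim(absorption), dim(height)) || any(absorption < 0) || any(absorption > 1))
      stop("absorption must be a matching map in [0, 1]")
  }
  structure(list(grid = grid, height = height, index_contrast = index_contrast,
                 absorption = absorption),
            class = "phase_phantom")
}

#' @export
print.phase_phantom <- function(x, ...) {
  cat(sprintf("phase_phantom: %d x %d px, height range [%.4g, %.4g] um, dn = %g%s\n",
              x$grid$n_rows, x$grid$n_cols, min(x$height), max(x$height),
              x$index_contrast,
              if (is.null(x$absorption)) ", transparent" else ", absorbing"))
  invisible(x)
}

#' Phase of a phantom at a given wavelength
#'
#' @param phantom A [phase_phantom()].
#' @param wavelength Wavelength, nm.
#' @return Phase map in radians: 2 pi h dn / lambda.
#' @export
phantom_phase <- function(phantom, wavelength) {
  stopifnot(inherits(phantom, "phase_phantom"))
  stopifnot_scalar_pos(wavelength, "wavelength")
  (2 * pi / nm_to_um(wavelength)) * phantom$height * phantom$index_contrast
}

#' Complex field of a phantom at its focal plane
#'
#' @param phantom A [phase_phantom()].
#' @param wavelength Wavelength, nm.
#' @return A [complex_field()] with amplitude sqrt(1 - absorption) *
#'   exp(i phi(lambda)).
#' @export
phantom_field <- function(phantom, wavelength) {
  amp <- if (is.null(phantom$absorption)) 1 else sqrt(pmax(1 - phantom$absorption, 0))
  complex_field(phantom$grid, amp * exp(1i * phantom_phase(phantom, wavelength)),
                wavelength)
}

#' Siemens star phase target
#'
#' Binary radial spoke target: `n_spokes` spokes of the given height
#' alternating with gaps over equal angular sectors, so the local spatial
#' period at radius rho is 2 pi rho / n_spokes. Spokes are hard-edged by
#' default so the ground truth is exactly known; an optional 1-pixel cosine
#' taper softens the edges.
#'
#' @param grid A [sampled_grid()].
#' @param n_spokes Even spoke count, at least 4.
#' @param height Spoke height, um (0 allowed: blank target).
#' @param index_contrast Index contrast, default 0.52 (glass in air).
#' @param radius Outer star radius, um; default 78% of the half field.
#' @param edge_taper Apply a 1-pixel cosine edge taper (default off).
#' @return A [phase_phantom()].
#' @examples
#' st <- siemens_star(sampled_grid(64), n_spokes = 8, height = 0.25)
#' @export
siemens_star <- function(grid, n_spokes, height, index_contrast = 0.52,
                         radius = NULL, edge_taper = FALSE) {
  stopifnot(inherits(grid, "sampled_grid"))
  if (n_spokes %% 2 != 0 || n_spokes < 4)
    stop("n_spokes must be even and at least 4")
  if (height < 0) stop("height must be >= 0")
  co <- grid_coords(grid)
  radius <- radius %||% (0.39 * min(grid$n_rows, grid$n_cols) * grid$pixel_pitch)
  theta <- atan2(co$y, co$x)
  sector <- floor(theta / (2 * pi / n_spokes))
  h <- ifelse(sector %% 2 == 0 & co$r <= radius, height, 0)
  if (edge_taper && height > 0) {
    k <- matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0) / 8, 3, 3)
    h <- conv3x3(h, k)
  }
  ph <- phase_phantom(grid, h, index_contrast)
  ph$n_spokes <- n_spokes
  ph$radius <- radius
  ph
}

conv3x3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in -1:1) for (j in -1:1) {
    w <- k[i + 2, j + 2]
    if (w == 0) next
    ri <- pmin(pmax(seq_len(nr) + i, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + j, 1L), nc)
    out <- out + w * m[ri, ci]
  }
  out
}

#' Siemens star measurement masks
#'
#' Logical masks over spoke interiors and gaps, eroded away from edges and
#' restricted to a radial band, for unbiased plateau-height measurements.
#'
#' @param star A phantom from [siemens_star()].
#' @param r_min,r_max Radial band in um (defaults: where the local spoke
#'   period is at least 6 pixels, out to 95% of the star radius).
#' @param erode_px Square erosion repetitions applied to both masks.
#' @return List of logical matrices `spoke` and `gap`.
#' @export
siemens_star_masks <- function(star, r_min = NULL, r_max = NULL, erode_px = 2) {
  stopifnot(inherits(star, "phase_phantom"), !is.null(star$n_spokes))
  g <- star$grid
  co <- grid_coords(g)
  r_min <- r_min %||% (6 * g$pixel_pitch * star$n_spokes / (2 * pi))
  r_max <- r_max %||% (0.95 * star$radius)
  band <- co$r >= r_min & co$r <= r_max
  spoke <- star$height > 0 & band
  gap <- star$height == 0 & band
  for (i in seq_len(erode_px)) {
    spoke <- erode1(spoke)
    gap <- erode1(gap)
  }
  list(spoke = spoke, gap = gap)
}

erode1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in -1:1) for (j in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + i, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + j, 1L), nc)
    out <- out & mask[ri, ci]
  }
  out
}

#' Precision-diffuser specification
#'
#' @param feature_size Correlation length of the surface, um (default 7).
#' @param divergence_angle Scattered-beam divergence, degrees, in (0, 20);
#'   interpreted as the 1-sigma half-width of the far-field angular
#'   intensity (default 5).
#' @param seed Integer seed for reproducible screens.
#' @param index_contrast Index contrast of the surface relief (default 0.52).
#' @param nominal_wavelength Wavelength (nm) at which the divergence is
#'   calibrated (default 530).
#' @return Object of class `diffuser_spec`.
#' @export
diffuser_spec <- function(feature_size = 7, divergence_angle = 5, seed = 1,
                          index_contrast = 0.52, nominal_wavelength = 530) {
  stopifnot_scalar_pos(feature_size, "feature_size")
  if (divergence_angle <= 0 || divergence_angle >= 20)
    stop("divergence_angle must lie in (0, 20) degrees")
  structure(list(feature_size = feature_size, divergence_angle = divergence_angle,
                 seed = as.integer(seed), index_contrast = index_contrast,
                 nominal_wavelength = nominal_wavelength),
            class = "diffuser_spec")
}

#' Gaussian random phase screen emulating a precision diffuser
#'
#' A smooth Gaussian random field with Gaussian autocorrelation
#' exp(-r^2 / l^2) (1/e width = `feature_size`), rescaled so the per-axis RMS
#' phase gradient at the nominal wavelength equals tan(divergence) * 2 pi /
#' lambda — the calibration contract tying the screen to the far-field beam
#' width. Bitwise reproducible under a fixed seed.
#'
#' @param spec A [diffuser_spec()].
#' @param grid A [sampled_grid()]; pitch must resolve the feature size
#'   (feature_size >= 2 * pitch).
#' @return A [phase_phantom()] whose height encodes the screen.
#' @export
precision_diffuser <- function(spec, grid) {
  stopifnot(inherits(spec, "diffuser_spec"), inherits(grid, "sampled_grid"))
  if (spec$feature_size < 2 * grid$pixel_pitch)
    stop("feature_size is under-resolved by the grid (need >= 2 * pixel_pitch)")
  l <- spec$feature_size
  noise <- with_seed(spec$seed,
                     matrix(stats::rnorm(grid$n_rows * grid$n_cols), grid$n_rows))
  fr <- grid_freqs(grid)
  # amplitude filter exp(-k^2 l^2 / 8) gives field ACF exp(-r^2 / l^2)
  screen <- Re(ifft2(fft2(noise) * exp(-fr$k2 * l^2 / 8)))
  screen <- screen - mean(screen)
  gx <- diff_central(screen, grid$pixel_pitch, 2L)
  gy <- diff_central(screen, grid$pixel_pitch, 1L)
  slope_rms <- sqrt((mean(gx^2) + mean(gy^2)) / 2)
  lam <- nm_to_um(spec$nominal_wavelength)
  target <- tan(spec$divergence_angle * pi / 180) * 2 * pi / lam
  screen <- screen * (target / slope_rms)
  height <- screen * lam / (2 * pi * spec$index_contrast)
  height <- height - min(height)
  ph <- phase_phantom(grid, height, spec$index_contrast)
  ph$spec <- spec
  ph
}

#' Filament (alga-like) phase phantom
#'
#' Overlapping cylindrical-profile ribbons with a helical height modulation,
#' idealizing filamentous algae. Crossings add heights; the map is rescaled
#' so the peak-to-peak phase at the nominal wavelength equals
#' `max_phase_range`.
#'
#' @param grid A [sampled_grid()].
#' @param n_filaments Number of ribbons (0 gives a flat phantom).
#' @param diameter Ribbon width, um (>= 3 pixels).
#' @param max_phase_range Target peak-to-peak phase, radians, at
#'   `nominal_wavelength`.
#' @param seed Integer seed.
#' @param index_contrast Index contrast (default 0.14, tissue-like).
#' @param nominal_wavelength nm, default 530.
#' @param edge_window Apply a cosine-taper (Tukey, 12% width) window so the
#'   height map falls to zero at the field edge; keeps the phantom
#'   compatible with Fourier-periodic solvers (default TRUE).
#' @param smoothing Gaussian smoothing (pixels) applied to the height map;
#'   rounds the chord profile's edge cusp so the phase slope stays
#'   resolvable on the grid (default 1; 0 disables).
#' @return A [phase_phantom()].
#' @export
filament_phantom <- function(grid, n_filaments, diameter, max_phase_range,
                             seed = 1, index_contrast = 0.14,
                             nominal_wavelength = 530, edge_window = TRUE,
                             smoothing = 1) {
  stopifnot(inherits(grid, "sampled_grid"))
  if (n_filaments == 0)
    return(phase_phantom(grid, matrix(0, grid$n_rows, grid$n_cols), index_contrast))
  if (diameter < 3 * grid$pixel_pitch)
    stop("diameter must be at least 3 pixels wide")
  co <- grid_coords(grid)
  extent <- max(co$r)
  h <- matrix(0, grid$n_rows, grid$n_cols)
  pars <- with_seed(seed, list(
    theta = stats::runif(n_filaments, 0, pi),
    offset = stats::runif(n_filaments, -0.5, 0.5) * extent,
    twist = stats::runif(n_filaments, 0.5, 1.5),
    phase0 = stats::runif(n_filaments, 0, 2 * pi)))
  R <- diameter / 2
  for (i in seq_len(n_filaments)) {
    nx <- -sin(pars$theta[i]); ny <- cos(pars$theta[i])
    d <- co$x * nx + co$y * ny - pars$offset[i]        # signed distance to axis
    s <- co$x * cos(pars$theta[i]) + co$y * sin(pars$theta[i])  # along-axis coord
    inside <- abs(d) <= R
    prof <- sqrt(pmax(1 - (d / R)^2, 0))
    helix <- 0.75 + 0.25 * cos(2 * pi * s / (pars$twist[i] * 4 * diameter) + pars$phase0[i])
    h <- h + ifelse(inside, prof * helix, 0)
  }
  if (smoothing > 0) {
    kx <- fft_freq(grid$n_cols, 1)
    ky <- fft_freq(grid$n_rows, 1)
    K2 <- matrix(kx^2, grid$n_rows, grid$n_cols, byrow = TRUE) +
      matrix(ky^2, grid$n_rows, grid$n_cols)
    h <- Re(ifft2(fft2(h) * exp(-K2 * smoothing^2 / 2)))
    h <- pmax(h, 0)
  }
  if (edge_window) {
    tuk <- function(n) {
      w <- rep(1, n)
      m <- max(2L, round(0.12 * n))
      ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
      w[seq_len(m)] <- ramp
      w[n + 1 - seq_len(m)] <- ramp
      w
    }
    h <- h * outer(tuk(grid$n_rows), tuk(grid$n_cols))
  }
  lam <- nm_to_um(nominal_wavelength)
  peak_phase <- (2 * pi / lam) * index_contrast * (max(h) - min(h))
  if (peak_phase > 0) h <- h * (max_phase_range / peak_phase)
  phase_phantom(grid, h, index_contrast)
}

#' Talbot-type onset distance for caustics
#'
#' Distance scale 2 p^2 / lambda beyond which a screen with feature size p
#' develops fully modulated intensity structure.
#'
#' @param feature_size Feature size p, um.
#' @param wavelength Wavelength, nm.
#' @return Distance in um.
#' @examples
#' talbot_onset(7, 530)  # ~184.9 um
#' @export
talbot_onset <- function(feature_size, wavelength) {
  stopifnot_scalar_pos(feature_size, "feature_size")
  stopifnot_scalar_pos(wavelength, "wavelength")
  2 * feature_size^2 / nm_to_um(wavelength)
}

#' Write a phantom to disk
#'
#' Height map as single-plane float TIFF (normalized, with scale recorded)
#' plus a JSON sidecar holding the index contrast, pitch and generator
#' parameters.
#'
#' @param phantom A [phase_phantom()].
#' @param path Path to the TIFF; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phase_phantom"))
  hmax <- max(phantom$height)
  scale <- if (hmax > 0) hmax else 1
  tiff::writeTIFF(phantom$height / scale, path, bits.per.sample = 32L,
                  compression = "none")
  meta <- list(height_scale_um = scale,
               index_contrast = phantom$index_contrast,
               pixel_pitch_um = phantom$grid$pixel_pitch,
               n_rows = phantom$grid$n_rows, n_cols = phantom$grid$n_cols)
  if (!is.null(phantom$spec)) meta$generator <- unclass(phantom$spec)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#' @param path Path to the TIFF.
#' @return A [phase_phantom()].
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  h <- tiff::readTIFF(path) * meta$height_scale_um
  phase_phantom(sampled_grid(meta$n_rows, meta$n_cols, meta$pixel_pitch_um),
                h, meta$index_contrast)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".json")
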