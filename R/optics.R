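# Scalar paraxial wave optics: metalens phase, chromatic focal law, Fresnel
# propagation, transport-equation rate evaluators and digital refocusing.

#' Thin-lens optical train
#'
#' Geometry of the single-lens imaging train: aperture, focal length at the
#' design wavelength, and the object/image conjugates. The default is the
#' 2f-2f configuration (object and image each two focal lengths from the
#' lens, unit magnification) used for quantitative phase microscopy.
#'
#' @param aperture_radius Aperture radius in um.
#' @param focal_length Focal length at the design wavelength, um.
#' @param design_wavelength Design wavelength in nm (green by default).
#' @param object_distance,image_distance Conjugate distances in um; must
#'   satisfy the thin-lens equation. Default 2f-2f.
#' @return An object of class `optical_train` with derived `magnification`
#'   and paraxial `numerical_aperture`.
#' @examples
#' tr <- optical_train(250, 1000)
#' tr$numerical_aperture   # 0.25
#' @export
optical_train <- function(aperture_radius, focal_length, design_wavelength = 530,
                          object_distance = 2 * focal_length,
                          image_distance = 2 * focal_length) {
  for (nm in c("aperture_radius", "focal_length", "design_wavelength",
               "object_distance", "image_distance"))
    stopifnot_scalar_pos(get(nm), nm)
  conj <- 1 / object_distance + 1 / image_distance
  if (abs(conj - 1 / focal_length) > 1e-9 / focal_length)
    stop("object/image distances do not satisfy the thin-lens equation")
  na <- aperture_radius / focal_length
  if (na <= 0 || na >= 1) stop("paraxial NA must lie in (0, 1)")
  structure(list(aperture_radius = aperture_radius, focal_length = focal_length,
                 design_wavelength = design_wavelength,
                 object_distance = object_distance, image_distance = image_distance,
                 magnification = image_distance / object_distance,
                 numerical_aperture = na),
            class = "optical_train")
}

#' @export
print.optical_train <- function(x, ...) {
  cat(sprintf("optical_train: f = %g um @ %g nm, aperture radius %g um (NA %.3f), conjugates %g/%g um (M = %.2f)\n",
              x$focal_length, x$design_wavelength, x$aperture_radius,
              x$numerical_aperture, x$object_distance, x$image_distance,
              x$magnification))
  invisible(x)
}

#' Hyperboloid metalens phase profile
#'
#' Exact (non-paraxial) phase of a hyperboloid lens,
#' phi(r) = (2 pi / lambda) (sqrt(r^2 + f^2) - f), evaluated pointwise on the
#' grid. Under this package's sign conventions (forward propagation
#' exp(+ikz)) a converging lens multiplies the field by exp(-i phi(r)).
#'
#' @param grid A [sampled_grid()].
#' @param focal_length Focal length in um.
#' @param wavelength Wavelength in nm.
#' @return Matrix of phase in radians; zero on axis, increasing with radius.
#' @examples
#' g <- sampled_grid(8, pixel_pitch = 1)
#' ph <- hyperboloid_phase(g, focal_length = 1000, wavelength = 530)
#' @export
hyperboloid_phase <- function(grid, focal_length, wavelength) {
  stopifnot(inherits(grid, "sampled_grid"))
  stopifnot_scalar_pos(focal_length, "focal_length")
  stopifnot_scalar_pos(wavelength, "wavelength")
  lam <- nm_to_um(wavelength)
  r <- grid_coords(grid)$r
  (2 * pi / lam) * (sqrt(r^2 + focal_length^2) - focal_length)
}

#' Chromatic focal law of a diffractive lens
#'
#' The hyperboloid metalens carries linear longitudinal chromatic aberration
#' with the product lambda * f conserved: f(lambda) = lambda_ref * f_ref /
#' lambda.
#'
#' @param f_ref Focal length (um) at the reference wavelength.
#' @param lambda_ref,lambda Reference and query wavelengths, nm.
#' @return Focal length at `lambda`, um.
#' @examples
#' focal_at_wavelength(1150, 530, 625)  # 975.2 um
#' @export
focal_at_wavelength <- function(f_ref, lambda_ref, lambda) {
  stopifnot_scalar_pos(f_ref, "f_ref")
  stopifnot_scalar_pos(lambda_ref, "lambda_ref")
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be positive")
  lambda_ref * f_ref / lambda
}

#' Linearized chromatic focal shift
#'
#' First-order form of the chromatic focal law, delta f = f * delta lambda /
#' lambda, the scale on which the red and green channels separate axially.
#'
#' @param f_ref Focal length (um) at `lambda_ref`.
#' @param lambda_ref Reference wavelength, nm.
#' @param delta_lambda Wavelength offset, nm (signed).
#' @return Focal shift magnitude scale f * dl / l, um (signed with
#'   `delta_lambda`).
#' @examples
#' chromatic_focal_shift(1000, 530, 95)  # ~179 um red-green shift
#' @export
chromatic_focal_shift <- function(f_ref, lambda_ref, delta_lambda) {
  stopifnot_scalar_pos(f_ref, "f_ref")
  stopifnot_scalar_pos(lambda_ref, "lambda_ref")
  f_ref * delta_lambda / lambda_ref
}

# Alias-safety bound for the transfer-function Fresnel kernel on an n-point
# axis: the chirp is adequately sampled while lambda |z| <= n * pitch^2.
tf_alias_ok <- function(lambda_um, z, n, pitch) abs(lambda_um * z) <= n * pitch^2

#' Fresnel propagation of a complex field
#'
#' Propagates the field a signed axial distance using scalar paraxial
#' (Fresnel) diffraction with the exp(+ikz) forward convention. The kernel is
#' chosen automatically: the frequency-domain transfer function when the
#' sampling criterion lambda*|z| <= N*pitch^2 holds (unitary, energy
#' conserving), otherwise the impulse-response (convolutional chirp) kernel.
#' Mirror padding (factor 2, on by default) suppresses periodic wrap-around.
#'
#' @param field A [complex_field()].
#' @param distance Propagation distance in um; may be negative
#'   (back-propagation) or zero (identity).
#' @param pad Mirror-pad by a factor 2 before the FFT (transfer-function
#'   path). The impulse-response path always zero-pads.
#' @param method `"auto"`, `"tf"` or `"ir"` to force a kernel.
#' @return The propagated [complex_field()].
#' @examples
#' g <- sampled_grid(64, pixel_pitch = 2)
#' f <- complex_field(g, matrix(1 + 0i, 64, 64), 530)
#' p <- fresnel_propagate(f, 200)
#' @export
fresnel_propagate <- function(field, distance, pad = TRUE, method = c("auto", "tf", "ir")) {
  stopifnot(inherits(field, "complex_field"))
  method <- match.arg(method)
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance))
    stop("'distance' must be a finite scalar")
  if (distance == 0) return(field)
  g <- field$grid
  lam <- field$wavelength_um
  k <- 2 * pi / lam
  n_eff <- min(g$n_rows, g$n_cols) * (if (pad) 2L else 1L)
  tf_ok <- tf_alias_ok(lam, distance, n_eff, g$pixel_pitch)
  if (method == "auto") method <- if (tf_ok) "tf" else "ir"
  if (method == "tf" && !tf_ok)
    warning(sprintf(
      "transfer-function kernel is under-sampled: lambda*|z| = %.3g um^2 exceeds N*pitch^2 = %.3g um^2",
      lam * abs(distance), n_eff * g$pixel_pitch^2))
  if (method == "ir" && tf_ok && abs(lam * distance) < 0.25 * n_eff * g$pixel_pitch^2)
    warning(sprintf(
      "impulse-response kernel is under-sampled at short range: lambda*|z| = %.3g um^2 below N*pitch^2 = %.3g um^2",
      lam * abs(distance), n_eff * g$pixel_pitch^2))
  amp <- field$amplitude
  if (method == "tf") {
    a <- if (pad) pad_mirror(amp) else amp
    kx <- fft_freq(ncol(a), g$pixel_pitch)
    ky <- fft_freq(nrow(a), g$pixel_pitch)
    K2 <- matrix(kx^2, nrow(a), ncol(a), byrow = TRUE) + matrix(ky^2, nrow(a), ncol(a))
    H <- exp(1i * k * distance) * exp(-1i * distance * K2 / (2 * k))
    out <- ifft2(fft2(a) * H)
    out <- crop_topleft(out, g$n_rows, g$n_cols)
  } else {
    a <- pad_zero(amp)
    nr <- nrow(a); nc <- ncol(a)
    xs <- fft_freq(nc, 1) / (2 * pi) * nc * g$pixel_pitch  # wrap-ordered coords
    ys <- fft_freq(nr, 1) / (2 * pi) * nr * g$pixel_pitch
    R2 <- matrix(xs^2, nr, nc, byrow = TRUE) + matrix(ys^2, nr, nc)
    h <- g$pixel_pitch^2 * exp(1i * k * distance) / (1i * lam * distance) *
      exp(1i * k * R2 / (2 * distance))
    out <- ifft2(fft2(a) * fft2(h))
    out <- crop_topleft(out, g$n_rows, g$n_cols)
  }
  complex_field(g, out, field$wavelength_um * 1000)
}

#' Transport-of-intensity rate dI/dz
#'
#' Evaluates the right-hand side of the transport of intensity equation,
#' dI/dz = -(lambda / 2 pi) div(I grad phi), with second-order central
#' differences (one-sided at the edges).
#'
#' @param intensity_map Non-negative intensity matrix.
#' @param phase_map Phase matrix (radians), same dimensions.
#' @param wavelength Wavelength, nm.
#' @param pixel_pitch Grid pitch, um.
#' @return Matrix of dI/dz in intensity units per um.
#' @export
tie_rhs <- function(intensity_map, phase_map, wavelength, pixel_pitch = 1) {
  if (!identical(dim(intensity_map), dim(phase_map)))
    stop("intensity and phase maps must share one grid")
  if (any(intensity_map < 0)) stop("intensity must be non-negative")
  stopifnot_scalar_pos(wavelength, "wavelength")
  lam <- nm_to_um(wavelength)
  gx <- diff_central(phase_map, pixel_pitch, 2L)
  gy <- diff_central(phase_map, pixel_pitch, 1L)
  div <- diff_central(intensity_map * gx, pixel_pitch, 2L) +
    diff_central(intensity_map * gy, pixel_pitch, 1L)
  -(lam / (2 * pi)) * div
}

#' Transport-of-phase rate dphi/dz
#'
#' Evaluates the transport-of-phase right-hand side
#' dphi/dz = (1 / 2k) (-|grad phi|^2 + lap(I)/(2I) - |grad I|^2 / (4 I^2)),
#' with k = 2 pi / lambda, using central differences. The 1/(2k)
#' normalization makes the rate equal the actual phase evolution of
#' paraxial (Fresnel) propagation, verified against finite differences of
#' the propagator. Intensities at or below `intensity_floor` are clamped
#' and the clamped-pixel count reported via a message.
#'
#' @inheritParams tie_rhs
#' @param intensity_floor Lower clamp applied to the intensity before
#'   division.
#' @return Matrix of dphi/dz in rad/um.
#' @export
tpe_rhs <- function(intensity_map, phase_map, wavelength, pixel_pitch = 1,
                    intensity_floor = 1e-6) {
  if (!identical(dim(intensity_map), dim(phase_map)))
    stop("intensity and phase maps must share one grid")
  stopifnot_scalar_pos(wavelength, "wavelength")
  lam <- nm_to_um(wavelength)
  n_clamped <- sum(intensity_map <= intensity_floor)
  if (n_clamped > 0)
    message(sprintf("tpe_rhs: clamped %d pixels at the intensity floor %g", n_clamped, intensity_floor))
  I <- pmax(intensity_map, intensity_floor)
  px <- diff_central(phase_map, pixel_pitch, 2L)
  py <- diff_central(phase_map, pixel_pitch, 1L)
  Ix <- diff_central(intensity_map, pixel_pitch, 2L)
  Iy <- diff_central(intensity_map, pixel_pitch, 1L)
  lapI <- diff2_central(intensity_map, pixel_pitch, 2L) +
    diff2_central(intensity_map, pixel_pitch, 1L)
  (lam / (4 * pi)) * (-(px^2 + py^2) + lapI / (2 * I) - (Ix^2 + Iy^2) / (4 * I^2))
}

#' Digital refocusing to a set of (wavelength, distance) targets
#'
#' Propagates one complex field to each requested plane and returns the
#' intensities. Because the Fresnel pattern of a fixed field depends on the
#' product zeta = lambda * z only, targets with equal products give identical
#' normalized patterns; this is the spectral-focal equivalence used to turn
#' color channels into a through-focus stack.
#'
#' @param field A [complex_field()]; its amplitude is reused at every target
#'   wavelength.
#' @param targets Data frame or list with per-target `wavelength` (nm) and
#'   `distance` (um).
#' @param pad Passed to [fresnel_propagate()].
#' @return List of intensity matrices, one per target.
#' @export
refocus_stack <- function(field, targets, pad = TRUE) {
  stopifnot(inherits(field, "complex_field"))
  if (is.data.frame(targets)) targets <- split(targets, seq_len(nrow(targets)))
  lapply(targets, function(t) {
    t <- as.list(t)
    stopifnot_scalar_pos(t$wavelength, "wavelength")
    f <- complex_field(field$grid, field$amplitude, t$wavelength)
    intensity(fresnel_propagate(f, t$distance, pad = pad))
  })
}

#' Coherent aperture (NA) low-pass filter
#'
#' Truncates the field's angular spectrum at the pupil cutoff k = 2 pi NA /
#' lambda, emulating a diffraction-limited system of the given numerical
#' aperture.
#'
#' @param field A [complex_field()].
#' @param numerical_aperture Paraxial NA in (0, 1).
#' @return The filtered [complex_field()].
#' @export
aperture_filter <- function(field, numerical_aperture) {
  stopifnot(inherits(field, "complex_field"))
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    stop("numerical_aperture must lie in (0, 1)")
  kc <- 2 * pi * numerical_aperture / field$wavelength_um
  fr <- grid_freqs(field$grid)
  mask <- sqrt(fr$k2) <= kc
  complex_field(field$grid, ifft2(fft2(field$amplitude) * mask),
                field$wavelength_um * 1000)
}

#' Incoherent diffraction-limited blur of an intensity map
#'
#' Applies the incoherent optical transfer function of an ideal circular
#' pupil (cutoff 2 NA / lambda) to an intensity image.
#'
#' @param intensity_map Real matrix.
#' @param numerical_aperture Paraxial NA.
#' @param wavelength Wavelength, nm.
#' @param pixel_pitch Grid pitch, um.
#' @return Blurred matrix.
#' @export
incoherent_blur <- function(intensity_map, numerical_aperture, wavelength,
                            pixel_pitch = 1) {
  lam <- nm_to_um(wavelength)
  fc <- 2 * numerical_aperture / lam  # cycles/um
  kx <- fft_freq(ncol(intensity_map), pixel_pitch) / (2 * pi)
  ky <- fft_freq(nrow(intensity_map), pixel_pitch) / (2 * pi)
  FR <- sqrt(matrix(kx^2, nrow(intensity_map), ncol(intensity_map), byrow = TRUE) +
               matrix(ky^2, nrow(intensity_map), ncol(intensity_map)))
  nu <- pmin(FR / fc, 1)
  otf <- (2 / pi) * (acos(nu) - nu * sqrt(1 - nu^2))
  Re(ifft2(fft2(intensity_map) * otf))
}
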