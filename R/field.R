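#' Sampled scalar complex field
#'
#' The monochromatic scalar electric field E = sqrt(I) exp(i phi) sampled on a
#' [sampled_grid()], with its wavelength carried as metadata. All propagation
#' operates on this object. Lengths are micrometres internally; wavelengths
#' are supplied in nanometres at the interface.
#'
#' @param grid A [sampled_grid()].
#' @param amplitude Complex matrix of dimension `n_rows x n_cols`.
#' @param wavelength Wavelength in nm.
#' @return An object of class `complex_field`.
#' @examples
#' g <- sampled_grid(32)
#' f <- complex_field(g, matrix(1 + 0i, 32, 32), wavelength = 530)
#' range(intensity(f))
#' @export
complex_field <- function(grid, amplitude, wavelength) {
  stopifnot(inherits(grid, "sampled_grid"))
  if (is.numeric(amplitude)) amplitude <- amplitude + 0i
  if (!is.matrix(amplitude) || nrow(amplitude) != grid$n_rows ||
      ncol(amplitude) != grid$n_cols)
    stop("amplitude must be a matrix matching the grid dimensions")
  if (!all(is.finite(Re(amplitude))) || !all(is.finite(Im(amplitude))))
    stop("amplitude values must all be finite")
  stopifnot_scalar_pos(wavelength, "wavelength")
  structure(list(grid = grid, amplitude = amplitude,
                 wavelength_um = nm_to_um(wavelength)),
            class = "complex_field")
}

#' Intensity of a complex field
#' @param field A [complex_field()].
#' @return Real matrix |E|^2.
#' @export
intensity <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  Re(field$amplitude * Conj(field$amplitude))
}

#' Phase of a complex field
#' @param field A [complex_field()].
#' @return Real matrix Arg(E) in radians (wrapped to (-pi, pi]).
#' @export
field_phase <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  Arg(field$amplitude)
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d px, pitch %g um, wavelength %g nm, total intensity %.4g\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_pitch,
              x$wavelength_um * 1000, sum(intensity(x))))
  invisible(x)
}
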