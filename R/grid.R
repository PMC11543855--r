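#' Sampled pixel grid
#'
#' A regular, pixel-centered sampling lattice shared by fields, phantoms and
#' captures. Coordinates are centered on the array: x increases with column
#' index, y with row index, and the origin sits at the array center.
#'
#' @param n_rows,n_cols Number of rows/columns (at least 8).
#' @param pixel_pitch Pixel pitch in micrometres.
#' @return An object of class `sampled_grid`.
#' @examples
#' g <- sampled_grid(64, 64, pixel_pitch = 1)
#' range(grid_coords(g)$x)
#' @export
sampled_grid <- function(n_rows, n_cols = n_rows, pixel_pitch = 1) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 8 || n_cols < 8)
    stop("grid dimensions must be at least 8 x 8")
  stopifnot_scalar_pos(pixel_pitch, "pixel_pitch")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_pitch = pixel_pitch),
            class = "sampled_grid")
}

#' @export
print.sampled_grid <- function(x, ...) {
  cat(sprintf("sampled_grid: %d x %d px, pitch %g um (%.1f x %.1f um)\n",
              x$n_rows, x$n_cols, x$pixel_pitch,
              x$n_rows * x$pixel_pitch, x$n_cols * x$pixel_pitch))
  invisible(x)
}

#' Pixel-centered coordinate maps for a grid
#'
#' @param grid A [sampled_grid()].
#' @return List with matrices `x`, `y` (um) and radial distance `r`.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "sampled_grid"))
  xs <- (seq_len(grid$n_cols) - (grid$n_cols + 1) / 2) * grid$pixel_pitch
  ys <- (seq_len(grid$n_rows) - (grid$n_rows + 1) / 2) * grid$pixel_pitch
  x <- matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE)
  y <- matrix(ys, grid$n_rows, grid$n_cols)
  list(x = x, y = y, r = sqrt(x^2 + y^2))
}

#' Angular spatial-frequency lattice of a grid
#'
#' Frequencies in rad/um in FFT (wrap-around) ordering, as used by the
#' Fourier-domain Poisson solver and the Fresnel transfer function.
#'
#' @param grid A [sampled_grid()].
#' @return List with matrices `kx`, `ky` and `k2 = kx^2 + ky^2`.
#' @export
grid_freqs <- function(grid) {
  stopifnot(inherits(grid, "sampled_grid"))
  kx <- fft_freq(grid$n_cols, grid$pixel_pitch)
  ky <- fft_freq(grid$n_rows, grid$pixel_pitch)
  KX <- matrix(kx, grid$n_rows, grid$n_cols, byrow = TRUE)
  KY <- matrix(ky, grid$n_rows, grid$n_cols)
  list(kx = KX, ky = KY, k2 = KX^2 + KY^2)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$pixel_pitch, b$pixel_pitch))
}
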