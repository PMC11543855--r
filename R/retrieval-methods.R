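# S3 methods for the fitted retrieval object.

#' @export
print.qpi_retrieval <- function(x, ...) {
  cat("Spectral TIE phase retrieval\n")
  cat(sprintf("  grid: %d x %d px, pitch %g um\n",
              x$capture$grid$n_rows, x$capture$grid$n_cols,
              x$capture$grid$pixel_pitch))
  cat(sprintf("  central wavelength: %g nm; derivative mode: %s\n",
              x$central_wavelength, x$params$derivative_mode))
  cat(sprintf("  iterations: %d; final relative residual: %.3g%s%s\n",
              x$iterations,
              if (length(x$residual_history)) utils::tail(x$residual_history, 1) else NA,
              if (x$converged) " (converged)" else "",
              if (x$diverged) " (divergence flagged; best iterate kept)" else ""))
  cat(sprintf("  phase range: [%.3f, %.3f] rad (mean-zero gauge)\n",
              min(x$phase), max(x$phase)))
  if (!is.null(x$height))
    cat(sprintf("  height range: [%.4f, %.4f] um (dn = %g)\n",
                min(x$height), max(x$height), x$index_contrast))
  invisible(x)
}

#' @export
summary.qpi_retrieval <- function(object, ...) {
  s <- list(
    grid = object$capture$grid,
    central_wavelength = object$central_wavelength,
    derivative_mode = object$params$derivative_mode,
    epsilon = object$params$epsilon,
    epsilon_prime = object$params$epsilon_prime,
    iterations = object$iterations,
    residual_history = object$residual_history,
    converged = object$converged,
    diverged = object$diverged,
    floored_pixels = object$floored_pixels,
    phase_rms = rms(object$phase),
    phase_range = range(object$phase),
    height_range = if (!is.null(object$height)) range(object$height))
  class(s) <- "summary.qpi_retrieval"
  s
}

#' @export
print.summary.qpi_retrieval <- function(x, ...) {
  cat("Spectral TIE phase retrieval — summary\n")
  cat(sprintf("  grid %d x %d px (pitch %g um), lambda0 %g nm, mode %s\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_pitch,
              x$central_wavelength, x$derivative_mode))
  cat(sprintf("  regularizers: epsilon %.3g, epsilon' %.3g um^-2\n",
              x$epsilon, x$epsilon_prime))
  cat(sprintf("  iterations %d, converged %s, diverged %s, floored px %d\n",
              x$iterations, x$converged, x$diverged, x$floored_pixels))
  cat("  residual history:", paste(sprintf("%.3g", x$residual_history), collapse = " "), "\n")
  cat(sprintf("  phase RMS %.4g rad, range [%.3f, %.3f] rad\n",
              x$phase_rms, x$phase_range[1], x$phase_range[2]))
  if (!is.null(x$height_range))
    cat(sprintf("  height range [%.4f, %.4f] um\n", x$height_range[1], x$height_range[2]))
  invisible(x)
}

#' Extract the estimated phase (and height) maps
#'
#' The "coefficients" of the retrieval are the recovered mean-zero phase
#' map and, when an index contrast was supplied, the derived height map.
#'
#' @param object A `qpi_retrieval`.
#' @param ... Unused.
#' @return Named list with `phase` (radians) and possibly `height` (um).
#' @export
coef.qpi_retrieval <- function(object, ...) {
  out <- list(phase = object$phase)
  if (!is.null(object$height)) out$height <- object$height
  out
}

#' @export
fitted.qpi_retrieval <- function(object, ...) object$fitted_planes

#' Per-channel intensity residuals of a retrieval
#'
#' Measured minus fitted intensity planes for the channels used by the
#' derivative mode.
#'
#' @param object A `qpi_retrieval`.
#' @param ... Unused.
#' @return Named list of residual matrices.
#' @export
residuals.qpi_retrieval <- function(object, ...) {
  used <- used_channels(object$params$derivative_mode)
  out <- lapply(used, function(nm) object$capture$planes[[nm]] - object$fitted_planes[[nm]])
  names(out) <- used
  out
}

#' Digital refocusing from a retrieval
#'
#' Predicts intensity at new (wavelength, distance) planes by propagating
#' the recovered complex field — the holographic reconstruction that turns
#' one capture into a hyperspectral/through-focus stack.
#'
#' @param object A `qpi_retrieval`.
#' @param wavelength Wavelengths, nm (recycled against `distance`).
#' @param distance Propagation distances, um.
#' @param pad Passed to [fresnel_propagate()].
#' @param ... Unused.
#' @return List of intensity matrices, one per requested plane.
#' @export
predict.qpi_retrieval <- function(object, wavelength = object$central_wavelength,
                                  distance = 0, pad = TRUE, ...) {
  n <- max(length(wavelength), length(distance))
  wavelength <- rep_len(wavelength, n)
  distance <- rep_len(distance, n)
  amp <- sqrt(pmax(object$capture$planes[[central_plane_name(object)]],
                   object$params$intensity_floor))
  lam0 <- object$central_wavelength
  targets <- lapply(seq_len(n), function(i) list(wavelength = wavelength[i],
                                                 distance = distance[i]))
  lapply(targets, function(t) {
    scale <- lam0 / t$wavelength
    f <- complex_field(object$capture$grid, amp * exp(1i * object$phase * scale),
                       t$wavelength)
    intensity(fresnel_propagate(f, t$distance, pad = pad))
  })
}

central_plane_name <- function(object) {
  switch(object$params$derivative_mode,
         two_channel_RG = "G", two_channel_GB = "B", three_channel = "G")
}

#' Plot a retrieval
#'
#' Base-graphics panels: recovered phase, height (if available) or the
#' central measured plane, and the residual history.
#'
#' @param x A `qpi_retrieval`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.qpi_retrieval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x$phase, main = "recovered phase (rad)", axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (!is.null(x$height)) {
    graphics::image(x$height, main = "height (um)", axes = FALSE,
                    col = grDevices::hcl.colors(64, "cividis"), ...)
  } else {
    graphics::image(x$capture$planes[[central_plane_name(x)]],
                    main = "central plane", axes = FALSE,
                    col = grDevices::gray.colors(64), ...)
  }
  graphics::plot(seq_along(x$residual_history), x$residual_history, type = "b",
                 log = "y", xlab = "iteration", ylab = "relative residual",
                 main = "convergence")
  invisible(x)
}
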