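# File formats and configuration: float TIFF planes with JSON sidecars for
# captures and retrievals, YAML run configuration.

#' Write a spectral capture to disk
#'
#' Three-plane 32-bit float TIFF plus a JSON sidecar carrying the
#' physics-critical metadata (channel wavelengths, equivalent defocus,
#' pixel pitch, normalization scale). Planes are stored normalized to
#' `[0, 1]` by a common scale recorded in the sidecar.
#'
#' @param capture A [spectral_capture()].
#' @param path Path to the TIFF; sidecar written next to it as `.json`.
#' @return `path`, invisibly.
#' @export
write_capture <- function(capture, path) {
  stopifnot(inherits(capture, "spectral_capture"))
  mx <- max(vapply(capture$planes, max, numeric(1)))
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(lapply(capture$planes, function(p) p / scale), path,
                  bits.per.sample = 32L, compression = "none")
  meta <- list(
    intensity_scale = scale,
    pixel_pitch_um = capture$grid$pixel_pitch,
    n_rows = capture$grid$n_rows, n_cols = capture$grid$n_cols,
    exposure_scale = capture$exposure_scale,
    channels = lapply(capture$channels, function(ch)
      list(name = ch$name, center_wavelength_nm = ch$center_wavelength,
           equivalent_defocus_um = ch$equivalent_defocus)))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral capture written by [write_capture()]
#'
#' Also accepts 16-bit integer TIFF planes, rescaled by the sidecar's stated
#' scale. A sidecar without channel wavelengths is a hard error: there are
#' no silent defaults for physics-critical metadata.
#'
#' @param path Path to the TIFF.
#' @param sidecar Optional explicit sidecar path.
#' @return A [spectral_capture()].
#' @export
read_capture <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(sidecar)) stop("capture sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  chs <- meta$channels
  if (is.null(chs) || any(vapply(chs, function(ch)
    is.null(ch$center_wavelength_nm) || is.null(ch$equivalent_defocus_um), logical(1))))
    stop("capture sidecar lacks channel wavelength/defocus metadata")
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 3) stop("expected a 3-plane capture TIFF")
  scale <- meta$intensity_scale %||% 1
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  })
  channels <- lapply(chs, function(ch)
    channel_spec(ch$name, ch$center_wavelength_nm, ch$equivalent_defocus_um))
  names(channels) <- vapply(channels, function(ch) ch$name, character(1))
  spectral_capture(sampled_grid(meta$n_rows, meta$n_cols, meta$pixel_pitch_um),
                   planes, channels, meta$exposure_scale %||% 1)
}

#' Write retrieval results to disk
#'
#' Phase (radians) and, when present, height (um) as float TIFFs with a JSON
#' diagnostics sidecar (residual history, iterations, solver parameters).
#'
#' @param fit A `qpi_retrieval`.
#' @param prefix Output path prefix; files `<prefix>_phase.tif`,
#'   `<prefix>_height.tif`, `<prefix>_diagnostics.json`.
#' @return The diagnostics path, invisibly.
#' @export
write_retrieval <- function(fit, prefix) {
  stopifnot(inherits(fit, "qpi_retrieval"))
  write_scaled_tiff(fit$phase, paste0(prefix, "_phase.tif"))
  if (!is.null(fit$height)) write_scaled_tiff(fit$height, paste0(prefix, "_height.tif"))
  diag_path <- paste0(prefix, "_diagnostics.json")
  jsonlite::write_json(list(
    central_wavelength_nm = fit$central_wavelength,
    iterations = fit$iterations,
    converged = fit$converged, diverged = fit$diverged,
    residual_history = fit$residual_history,
    epsilon = fit$params$epsilon, epsilon_prime = fit$params$epsilon_prime,
    derivative_mode = fit$params$derivative_mode,
    intensity_floor = fit$params$intensity_floor,
    phase_range_rad = range(fit$phase)),
    diag_path, auto_unbox = TRUE, digits = NA)
  invisible(diag_path)
}

write_scaled_tiff <- function(m, path) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(offset = lo, scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_scaled_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  tiff::readTIFF(path) * meta$scale + meta$offset
}

#' Run configuration
#'
#' Flat key-value (YAML) description of a simulation/retrieval run. Keys
#' carry their units in the name to prevent unit bugs. Round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param focal_length_um,aperture_radius_um,design_wavelength_nm Train.
#' @param wavelengths_nm Channel wavelengths (R, G, B).
#' @param grid_n,pixel_pitch_um Grid.
#' @param phantom Phantom type: "siemens_star", "diffuser" or "filament".
#' @param phantom_height_um,index_contrast,n_spokes Star parameters.
#' @param seed Integer seed for stochastic generators/noise.
#' @param max_iterations,derivative_mode Solver.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(focal_length_um = 1000, aperture_radius_um = 250,
                       design_wavelength_nm = 530,
                       wavelengths_nm = c(625, 530, 455),
                       grid_n = 256, pixel_pitch_um = 1,
                       phantom = "siemens_star", phantom_height_um = 0.25,
                       index_contrast = 0.52, n_spokes = 16,
                       seed = 1, max_iterations = 10,
                       derivative_mode = "two_channel_RG") {
  structure(list(focal_length_um = focal_length_um,
                 aperture_radius_um = aperture_radius_um,
                 design_wavelength_nm = design_wavelength_nm,
                 wavelengths_nm = wavelengths_nm,
                 grid_n = grid_n, pixel_pitch_um = pixel_pitch_um,
                 phantom = phantom, phantom_height_um = phantom_height_um,
                 index_contrast = index_contrast, n_spokes = n_spokes,
                 seed = seed, max_iterations = max_iterations,
                 derivative_mode = derivative_mode),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(x)) cfg[[nm]] <- x[[nm]]
  cfg
}

#' Build the objects described by a run configuration
#'
#' @param config A [run_config()].
#' @return List with `grid`, `train`, `phantom`, `params`.
#' @export
materialize_config <- function(config) {
  g <- sampled_grid(config$grid_n, config$grid_n, config$pixel_pitch_um)
  tr <- optical_train(config$aperture_radius_um, config$focal_length_um,
                      config$design_wavelength_nm)
  ph <- switch(config$phantom,
               siemens_star = siemens_star(g, config$n_spokes,
                                           config$phantom_height_um,
                                           config$index_contrast),
               diffuser = precision_diffuser(diffuser_spec(seed = config$seed), g),
               filament = filament_phantom(g, 3, 10, 10 * pi, seed = config$seed),
               stop("unknown phantom type: ", config$phantom))
  pars <- qpi_params(max_iterations = config$max_iterations,
                     derivative_mode = config$derivative_mode)
  list(grid = g, train = tr, phantom = ph, params = pars)
}
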