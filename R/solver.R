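# The inverse problem: spectral intensity derivative, regularized
# double-Poisson TIE inversion, iterative refinement by forward propagation,
# and phase-to-height conversion.

#' Solver parameters for the spectral TIE retrieval
#'
#' @param epsilon,epsilon_prime Tikhonov regularizers (um^-2) for the first
#'   and second Fourier-domain Poisson inversions. `NULL` (default) resolves
#'   at solve time to four times the grid's fundamental mode,
#'   (2 pi / (N pitch))^2 * 4, then stays fixed between calibration and
#'   measurement.
#' @param max_iterations Maximum refinement iterations (>= 1).
#' @param relative_tolerance Stop when the relative residual norm of the
#'   intensity derivative falls below this.
#' @param derivative_mode `"two_channel_RG"` (default; the blue channel has
#'   the poorest signal-to-noise ratio in practice), `"two_channel_GB"`, or
#'   `"three_channel"` (per-pixel weighted least-squares slope over the
#'   three wavelengths).
#' @param intensity_floor Lower clamp (relative to unit background) applied
#'   to the central intensity before the grad(psi)/I division.
#' @param central `"plane"` uses the mode's central plane as the TIE
#'   intensity; `"mean"` uses the channel mean.
#' @param band_limit Spatial-frequency cutoff (rad/um) applied to every
#'   phase update. `NULL` (default) resolves at solve time to the first
#'   zero of the defocus contrast transfer function of the capture
#'   geometry, k = 2 pi / sqrt(lambda z_max); beyond it the defocus
#'   measurement carries no invertible phase contrast. `Inf` disables the
#'   filter.
#' @param ctf_delta Wiener constant for the contrast-transfer
#'   preconditioner applied to each update: inside the band the update is
#'   divided per mode by the exact sinc-type transfer of the finite-defocus
#'   difference, regularized as s / (s^2 + delta). Zero disables the
#'   correction (pure TIE small-defocus limit).
#' @param projection_iterations Amplitude-projection refinement cycles run
#'   after the TIE residual iterations (default 60; 0 disables). Each cycle
#'   enforces the measured modulus at every defocused channel plane by
#'   propagate/replace-modulus/back-propagate, accumulating wrap-safe,
#'   band-limited phase increments. This stage resolves the slow twin-image
#'   stagnation of derivative-only iterations for strong-phase objects; it
#'   is skipped when the TIE stage already converged.
#' @return Object of class `qpi_params`.
#' @export
qpi_params <- function(epsilon = NULL, epsilon_prime = NULL, max_iterations = 10,
                       relative_tolerance = 1e-3,
                       derivative_mode = c("two_channel_RG", "two_channel_GB", "three_channel"),
                       intensity_floor = 0.05, central = c("plane", "mean"),
                       band_limit = NULL, ctf_delta = 0.05,
                       projection_iterations = 60) {
  derivative_mode <- match.arg(derivative_mode)
  central <- match.arg(central)
  if (!is.null(epsilon)) stopifnot_scalar_pos(epsilon, "epsilon")
  if (!is.null(epsilon_prime)) stopifnot_scalar_pos(epsilon_prime, "epsilon_prime")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (intensity_floor <= 0 || intensity_floor >= 0.5)
    stop("intensity_floor must lie in (0, 0.5)")
  stopifnot_scalar_pos(relative_tolerance, "relative_tolerance")
  if (!is.null(band_limit) && (!is.numeric(band_limit) || band_limit <= 0))
    stop("band_limit must be a positive frequency (rad/um) or NULL")
  structure(list(epsilon = epsilon, epsilon_prime = epsilon_prime,
                 max_iterations = as.integer(max_iterations),
                 relative_tolerance = relative_tolerance,
                 derivative_mode = derivative_mode,
                 intensity_floor = intensity_floor, central = central,
                 band_limit = band_limit, ctf_delta = ctf_delta,
                 projection_iterations = as.integer(projection_iterations)),
            class = "qpi_params")
}

default_epsilon <- function(grid) {
  (2 * pi / (max(grid$n_rows, grid$n_cols) * grid$pixel_pitch))^2 * 4
}

resolve_params <- function(params, grid) {
  params$epsilon <- params$epsilon %||% default_epsilon(grid)
  params$epsilon_prime <- params$epsilon_prime %||% default_epsilon(grid)
  params
}

#' Equivalent defocus of spectral channels
#'
#' The chromatic focal law lambda * z = constant gives lambda dz = -z
#' dlambda: a wavelength offset at a fixed observation plane is equivalent
#' to refocusing by dz_i = -z (lambda_i - lambda_0) / lambda_0. The sign is
#' the refocus distance back to the reference plane; the forward-model
#' (capture) defocus carries the opposite sign (see
#' [channel_specs_from_train()]).
#'
#' @param channels Named list of three [channel_spec()]s.
#' @param nominal_z Nominal propagation distance z, um (> 0).
#' @param nominal_lambda Reference wavelength, nm (> 0).
#' @return Named numeric vector of per-channel equivalent dz, um.
#' @examples
#' chs <- channel_specs_from_train(optical_train(250, 1000))
#' spectral_to_defocus(chs, nominal_z = 1150, nominal_lambda = 530)
#' @export
spectral_to_defocus <- function(channels, nominal_z, nominal_lambda) {
  stopifnot_scalar_pos(nominal_z, "nominal_z")
  stopifnot_scalar_pos(nominal_lambda, "nominal_lambda")
  vapply(channels, function(ch)
    -nominal_z * (ch$center_wavelength - nominal_lambda) / nominal_lambda,
    numeric(1))
}

#' Estimate the spectral intensity derivative of a capture
#'
#' Two-channel modes take the plane difference over the wavelength spacing;
#' the three-channel mode combines the RG and GB pairwise slopes with
#' inverse-spacing weights (exact for data linear in wavelength). The axial
#' derivative dI/dz follows from the channels' stored equivalent defocus.
#'
#' @param capture A [spectral_capture()].
#' @param params A [qpi_params()].
#' @return Object of class `derivative_estimate` with fields
#'   `d_intensity_d_lambda` (per nm), `d_intensity_d_z` (per um),
#'   `equivalent_dz` (um, the dz spacing backing the estimate),
#'   `central_intensity` and `central_wavelength` (nm).
#' @export
estimate_dI <- function(capture, params = qpi_params()) {
  stopifnot(inherits(capture, "spectral_capture"))
  ch <- capture$channels
  wl <- vapply(ch, function(c) c$center_wavelength, numeric(1))
  dz <- vapply(ch, function(c) c$equivalent_defocus, numeric(1))
  if (anyDuplicated(wl)) stop("channel wavelengths must be distinct (degenerate derivative)")
  pl <- capture$planes
  mode <- params$derivative_mode
  pair_slope <- function(a, b) {
    dl <- wl[[a]] - wl[[b]]
    list(dIdl = (pl[[a]] - pl[[b]]) / dl, dl = dl, dzs = dz[[a]] - dz[[b]])
  }
  if (mode == "two_channel_RG") {
    s <- pair_slope("R", "G")
    central_name <- "G"
  } else if (mode == "two_channel_GB") {
    s <- pair_slope("G", "B")
    central_name <- "B"
  } else {
    rg <- pair_slope("R", "G"); gb <- pair_slope("G", "B")
    w_rg <- 1 / abs(rg$dl); w_gb <- 1 / abs(gb$dl)
    dIdl <- (w_rg * rg$dIdl + w_gb * gb$dIdl) / (w_rg + w_gb)
    dzs <- (w_rg * rg$dzs + w_gb * gb$dzs) / (w_rg + w_gb)
    dls <- (w_rg * rg$dl + w_gb * gb$dl) / (w_rg + w_gb)
    s <- list(dIdl = dIdl, dl = dls, dzs = dzs)
    central_name <- "G"
  }
  if (s$dzs == 0) stop("channel equivalent defocus spacing is zero; cannot form dI/dz")
  central <- if (params$central == "mean") Reduce(`+`, pl) / 3 else pl[[central_name]]
  structure(list(d_intensity_d_lambda = s$dIdl,
                 d_intensity_d_z = s$dIdl * (s$dl / s$dzs),
                 equivalent_dz = s$dzs,
                 central_intensity = central,
                 central_wavelength = wl[[central_name]],
                 mode = mode),
            class = "derivative_estimate")
}

#' Regularized FFT Poisson solve
#'
#' Solves the Poisson equation lap(u) = source in the Fourier domain by
#' dividing by -(kx^2 + ky^2 + epsilon); the Tikhonov constant epsilon
#' prevents division by zero at the origin of the parabola. The source mean
#' (unobservable zero frequency) is subtracted; the output is mean-zero.
#'
#' @param source Real matrix.
#' @param regularizer Tikhonov epsilon, um^-2 (> 0).
#' @param pixel_pitch Grid pitch, um.
#' @return Mean-zero potential matrix; per Fourier mode the round trip
#'   attenuates by k^2 / (k^2 + epsilon).
#' @export
poisson_solve <- function(source, regularizer, pixel_pitch = 1) {
  stopifnot_scalar_pos(regularizer, "regularizer")
  src <- source - mean(source)
  kx <- fft_freq(ncol(src), pixel_pitch)
  ky <- fft_freq(nrow(src), pixel_pitch)
  K2 <- matrix(kx^2, nrow(src), ncol(src), byrow = TRUE) + matrix(ky^2, nrow(src), ncol(src))
  out <- Re(ifft2(fft2(src) / -(K2 + regularizer)))
  out - mean(out)
}

#' Single-pass TIE inversion (double Poisson solve)
#'
#' Helmholtz substitution I grad(phi) = grad(psi) turns the TIE into two
#' nested Poisson problems: lap(psi) = -k dI/dz solved with regularizer
#' epsilon, then lap(phi) = div(grad(psi) / I) with epsilon-prime. Gradients
#' and divergence are spectral, consistent with the Fourier Laplacian
#' inversion. The returned phase is mean-zero and unwrapped by construction
#' (the integrations never wrap).
#'
#' @param deriv A `derivative_estimate` from [estimate_dI()], or a plain
#'   dI/dz matrix together with `wavelength` and `central_intensity`.
#' @param params A [qpi_params()].
#' @param grid A [sampled_grid()] (needed when `deriv` is a plain matrix).
#' @param wavelength,central_intensity Used when `deriv` is a plain matrix.
#' @return Mean-zero phase matrix, radians.
#' @export
tie_invert <- function(deriv, params = qpi_params(), grid = NULL,
                       wavelength = NULL, central_intensity = NULL) {
  if (inherits(deriv, "derivative_estimate")) {
    dIdz <- deriv$d_intensity_d_z
    wavelength <- deriv$central_wavelength
    central_intensity <- central_intensity %||% deriv$central_intensity
  } else {
    dIdz <- deriv
    if (is.null(wavelength)) stop("wavelength required for a plain derivative map")
    central_intensity <- central_intensity %||% matrix(1, nrow(dIdz), ncol(dIdz))
  }
  pitch <- if (!is.null(grid)) grid$pixel_pitch else 1
  params <- resolve_params(params, grid %||% sampled_grid(nrow(dIdz), ncol(dIdz), pitch))
  if (all(dIdz == 0)) {
    message("tie_invert: all-zero derivative; returning zero phase")
    return(matrix(0, nrow(dIdz), ncol(dIdz)))
  }
  k <- 2 * pi / nm_to_um(wavelength)
  I <- pmax(central_intensity, params$intensity_floor)
  psi <- poisson_solve(-k * dIdz, params$epsilon, pitch)
  gp <- fourier_gradient(psi, pitch)
  src2 <- fourier_divergence(gp$x / I, gp$y / I, pitch)
  phi <- poisson_solve(src2, params$epsilon_prime, pitch)
  phi - mean(phi)
}

#' Convert phase to physical height
#'
#' h = phi * lambda / (2 pi dn), pointwise.
#'
#' @param phase Phase map, radians.
#' @param wavelength Wavelength, nm.
#' @param index_contrast Refractive index contrast (> 0).
#' @return Height map, um.
#' @examples
#' phase_to_height(1.541, 530, 0.52)  # ~0.25 um
#' @export
phase_to_height <- function(phase, wavelength, index_contrast) {
  stopifnot_scalar_pos(wavelength, "wavelength")
  stopifnot_scalar_pos(index_contrast, "index_contrast")
  phase * nm_to_um(wavelength) / (2 * pi * index_contrast)
}

#' Spectral TIE phase retrieval with iterative refinement
#'
#' The fitting function of the package: estimates the quantitative phase
#' from a single three-channel capture. The first pass inverts the measured
#' spectral intensity derivative through the regularized double-Poisson TIE
#' solver; each refinement iteration then forward-propagates the current
#' field estimate to every channel's equivalent defocus (full Fresnel
#' propagation, with the pure-phase 1/lambda dispersion of the object),
#' recomputes the predicted derivative, and feeds the residual back through
#' the TIE inverse. Iteration stops at the relative tolerance, the iteration
#' cap, or on divergence (two consecutive residual increases; the best
#' iterate is kept and flagged).
#'
#' @param capture A [spectral_capture()].
#' @param params A [qpi_params()].
#' @param phase_init Optional starting phase map (radians, at the central
#'   wavelength); default zero.
#' @param index_contrast Optional index contrast; when given, the result
#'   carries a height map via [phase_to_height()].
#' @param dispersive Model the object as pure phase with phi proportional to
#'   1/lambda when predicting the other channels (default TRUE).
#' @param pad Passed to [fresnel_propagate()].
#' @return Object of class `qpi_retrieval`: mean-zero unwrapped `phase`,
#'   optional `height`, `residual_history`, `iterations`, `converged`,
#'   `diverged`, the fitted per-channel planes and the inputs.
#' @examples
#' g <- sampled_grid(64, pixel_pitch = 2)
#' star <- siemens_star(g, 8, height = 0.1)
#' cap <- simulate_capture(star, optical_train(250, 1000))
#' fit <- qpi_retrieve(cap, qpi_params(max_iterations = 3), index_contrast = 0.52)
#' @export
qpi_retrieve <- function(capture, params = qpi_params(), phase_init = NULL,
                         index_contrast = NULL, dispersive = TRUE, pad = TRUE) {
  stopifnot(inherits(capture, "spectral_capture"))
  g <- capture$grid
  params <- resolve_params(params, g)
  meas <- estimate_dI(capture, params)
  lam0 <- meas$central_wavelength
  k_cut <- params$band_limit %||% transport_passband(capture, params)
  band_w <- build_band_window(g, k_cut)
  update_filter <- build_update_filter(capture, params, band_w)
  I0 <- pmax(meas$central_intensity, params$intensity_floor)
  floored <- sum(meas$central_intensity < params$intensity_floor)
  amp0 <- sqrt(I0)
  used <- used_channels(params$derivative_mode)
  meas_norm <- rms(meas$d_intensity_d_z)
  zero_meas <- meas_norm == 0
  phi <- phase_init %||% matrix(0, g$n_rows, g$n_cols)
  best_phi <- phi
  best_res <- Inf
  history <- numeric(0)
  n_bad <- 0L
  diverged <- FALSE
  iterations <- 0L
  fitted_planes <- capture$planes
  if (!zero_meas) {
    for (it in seq_len(params$max_iterations)) {
      pred <- predict_planes(phi, amp0, capture, used, lam0, dispersive, pad)
      pred_cap <- spectral_capture(g, pred, capture$channels)
      pred_deriv <- estimate_dI(pred_cap, params)
      resid <- meas$d_intensity_d_z - pred_deriv$d_intensity_d_z
      rel <- rms(resid) / meas_norm
      history <- c(history, rel)
      if (rel < best_res) {
        best_res <- rel
        best_phi <- phi
        fitted_planes <- pred
        n_bad <- 0L
      } else {
        n_bad <- n_bad + 1L
        if (n_bad >= 2L) {
          diverged <- TRUE
          break
        }
      }
      iterations <- it
      if (rel < params$relative_tolerance) break
      dphi <- tie_invert(resid, params, grid = g, wavelength = lam0,
                         central_intensity = I0)
      phi <- phi + apply_k_filter(dphi, update_filter)
    }
    # score the final iterate (its residual was never measured in the loop)
    pred <- predict_planes(phi, amp0, capture, used, lam0, dispersive, pad)
    pred_deriv <- estimate_dI(spectral_capture(g, pred, capture$channels), params)
    rel <- rms(meas$d_intensity_d_z - pred_deriv$d_intensity_d_z) / meas_norm
    if (rel <= best_res) {
      best_res <- rel
      best_phi <- phi
      fitted_planes <- pred
      if (length(history) == 0 || rel < history[length(history)])
        history <- c(history, rel)
    }
    if (params$projection_iterations > 0 &&
        best_res >= params$relative_tolerance) {
      best_phi <- project_refine(best_phi, amp0, capture, lam0,
                                 params$projection_iterations, dispersive,
                                 band_w, pad)
      pred <- predict_planes(best_phi, amp0, capture, used, lam0, dispersive, pad)
      pred_deriv <- estimate_dI(spectral_capture(g, pred, capture$channels), params)
      best_res <- rms(meas$d_intensity_d_z - pred_deriv$d_intensity_d_z) / meas_norm
      fitted_planes <- pred
      history <- c(history, best_res)
    }
  } else {
    message("qpi_retrieve: all-zero measured derivative; returning zero phase")
    best_res <- 0
    history <- 0
  }
  phase <- best_phi - mean(best_phi)
  out <- list(phase = phase,
              height = if (!is.null(index_contrast))
                phase_to_height(phase, lam0, index_contrast),
              index_contrast = index_contrast,
              central_wavelength = lam0,
              residual_history = history,
              iterations = iterations,
              converged = is.finite(best_res) && best_res < params$relative_tolerance,
              diverged = diverged,
              floored_pixels = floored,
              fitted_planes = fitted_planes,
              capture = capture, params = params)
  class(out) <- "qpi_retrieval"
  out
}

# Transport passband of a capture: the defocus contrast transfer
# sin(lambda z k^2 / 4 pi) has its first zero at k = 2 pi / sqrt(lambda z);
# beyond it the finite-defocus measurement carries no invertible phase
# contrast. Cutoff from the largest channel defocus in use.
transport_passband <- function(capture, params) {
  used <- used_channels(params$derivative_mode)
  z_max <- max(abs(vapply(capture$channels[used],
                          function(ch) ch$equivalent_defocus, numeric(1))))
  if (z_max == 0) return(Inf)
  lam0 <- nm_to_um(estimate_central_wavelength(capture, params))
  2 * pi / sqrt(lam0 * z_max)
}

estimate_central_wavelength <- function(capture, params) {
  nm <- switch(params$derivative_mode,
               two_channel_RG = "G", two_channel_GB = "B", three_channel = "G")
  capture$channels[[nm]]$center_wavelength
}

# Per-mode linear response of (forward defocus difference -> derivative
# estimate -> small-defocus TIE interpretation), excluding the regularizer:
# s(k) -> 1 as k -> 0, and rolls off as a sinc-type contrast transfer at
# finite defocus. Exact linearization of this package's own forward model
# for a unit-background pure-phase object.
ctf_response <- function(capture, params, k2) {
  ch <- capture$channels
  lam <- vapply(ch, function(c) nm_to_um(c$center_wavelength), numeric(1))
  dz <- vapply(ch, function(c) c$equivalent_defocus, numeric(1))
  lam0 <- nm_to_um(estimate_central_wavelength(capture, params))
  pair_resp <- function(a, b) {
    dzs <- dz[[a]] - dz[[b]]
    theta_a <- lam[[a]] * dz[[a]] * k2 / (4 * pi)
    theta_b <- lam[[b]] * dz[[b]] * k2 / (4 * pi)
    num <- (lam0 / lam[[a]]) * sin(theta_a) - (lam0 / lam[[b]]) * sin(theta_b)
    out <- (4 * pi / (lam0 * dzs)) * num / pmax(k2, .Machine$double.eps)
    out[k2 < 1e-12] <- 1
    out
  }
  switch(params$derivative_mode,
         two_channel_RG = pair_resp("R", "G"),
         two_channel_GB = pair_resp("G", "B"),
         three_channel = {
           w_rg <- 1 / abs(lam[["R"]] - lam[["G"]])
           w_gb <- 1 / abs(lam[["G"]] - lam[["B"]])
           (w_rg * pair_resp("R", "G") + w_gb * pair_resp("G", "B")) / (w_rg + w_gb)
         })
}

# Raised-cosine low-pass window at the transport passband (NULL = no-op).
build_band_window <- function(grid, k_cut) {
  if (!is.finite(k_cut)) return(NULL)
  kx <- fft_freq(grid$n_cols, grid$pixel_pitch)
  ky <- fft_freq(grid$n_rows, grid$pixel_pitch)
  K <- sqrt(matrix(kx^2, grid$n_rows, grid$n_cols, byrow = TRUE) +
              matrix(ky^2, grid$n_rows, grid$n_cols))
  lo <- 0.9 * k_cut
  ifelse(K <= lo, 1,
         ifelse(K >= k_cut, 0, 0.5 * (1 + cos(pi * (K - lo) / (k_cut - lo)))))
}

# k-space filter for TIE updates: Wiener-regularized inverse of the
# contrast-transfer response, windowed at the transport passband.
build_update_filter <- function(capture, params, band_w) {
  if (params$ctf_delta <= 0) return(band_w)
  g <- capture$grid
  kx <- fft_freq(g$n_cols, g$pixel_pitch)
  ky <- fft_freq(g$n_rows, g$pixel_pitch)
  K2 <- matrix(kx^2, g$n_rows, g$n_cols, byrow = TRUE) + matrix(ky^2, g$n_rows, g$n_cols)
  s <- ctf_response(capture, params, K2)
  w <- s / (s^2 + params$ctf_delta)
  if (!is.null(band_w)) w <- w * band_w
  w
}

apply_k_filter <- function(m, filt) {
  if (is.null(filt)) return(m)
  Re(ifft2(fft2(m) * filt))
}

used_channels <- function(mode) {
  switch(mode,
         two_channel_RG = c("R", "G"),
         two_channel_GB = c("G", "B"),
         three_channel = c("R", "G", "B"))
}

# Amplitude-projection refinement: cycle over the defocused channel planes,
# enforce each measured modulus after forward propagation, back-propagate,
# and accumulate the wrap-safe phase increment (band-limited to the
# transport passband). The central-plane modulus constraint is re-imposed
# every cycle by rebuilding the field from amp0.
project_refine <- function(phi, amp0, capture, lam0, n_cycles, dispersive,
                           band_w, pad) {
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  g <- capture$grid
  chans <- Filter(function(ch) ch$equivalent_defocus != 0, capture$channels)
  if (!length(chans)) return(phi)
  for (i in seq_len(n_cycles)) {
    for (ch in chans) {
      scale <- if (dispersive) lam0 / ch$center_wavelength else 1
      f <- complex_field(g, amp0 * exp(1i * phi * scale), ch$center_wavelength)
      e <- fresnel_propagate(f, ch$equivalent_defocus, pad = pad)$amplitude
      e <- sqrt(capture$planes[[ch$name]]) * exp(1i * Arg(e))
      back <- fresnel_propagate(complex_field(g, e, ch$center_wavelength),
                                -ch$equivalent_defocus, pad = pad)$amplitude
      dphi <- wrap(Arg(back) - phi * scale) / scale
      phi <- phi + apply_k_filter(dphi, band_w)
    }
  }
  phi
}

# Forward model: per channel, field sqrt(I0) exp(i phi * lam0/lam_c)
# propagated by the channel's stored equivalent defocus.
predict_planes <- function(phi, amp0, capture, used, lam0, dispersive, pad) {
  planes <- capture$planes
  for (nm in used) {
    ch <- capture$channels[[nm]]
    scale <- if (dispersive) lam0 / ch$center_wavelength else 1
    f <- complex_field(capture$grid, amp0 * exp(1i * phi * scale),
                       ch$center_wavelength)
    planes[[nm]] <- intensity(fresnel_propagate(f, ch$equivalent_defocus, pad = pad))
  }
  planes
}

#' Calibrate a channel's equivalent defocus against a through-focus stack
#'
#' Finds the axial position maximizing the normalized cross-correlation
#' between the channel plane and a measured (or simulated) through-focus
#' intensity stack of the same scene, with parabolic sub-grid interpolation
#' around the peak. A featureless (in-focus, pure-phase) channel plane is
#' matched by minimum stack contrast instead.
#'
#' Because the Fresnel pattern of a field depends on the product
#' zeta = lambda z, a channel at wavelength lambda_c and physical defocus
#' z_c matches the stack (recorded at `stack_wavelength`) at
#' z* = z_c lambda_c / lambda_stack. With `wavelength_correct = TRUE`
#' (default) the returned value is rescaled back to the channel's physical
#' defocus z_c; the raw matched stack position is attached as attribute
#' `"stack_z"` (for red against a green stack this is the ~180 um
#' linearized focal-shift scale).
#'
#' @param capture A [spectral_capture()].
#' @param through_focus List of `list(z = , intensity = )` entries (or a
#'   data-frame-like pair of `z` and matrices), spanning the expected
#'   defocus.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param stack_wavelength Wavelength (nm) at which the through-focus stack
#'   was recorded (default 530).
#' @param wavelength_correct Rescale the matched position by
#'   lambda_stack / lambda_c to report the channel's physical defocus.
#' @return Calibrated defocus, um, with attribute `stack_z`.
#' @export
calibrate_channel_defocus <- function(capture, through_focus, channel,
                                      stack_wavelength = 530,
                                      wavelength_correct = TRUE) {
  stopifnot(inherits(capture, "spectral_capture"))
  plane <- capture$planes[[channel]]
  if (is.null(plane)) stop("unknown channel: ", channel)
  zs <- vapply(through_focus, function(t) t$z, numeric(1))
  if (is.unsorted(zs)) {
    o <- order(zs)
    through_focus <- through_focus[o]
    zs <- zs[o]
  }
  pv <- as.vector(plane - mean(plane))
  p_sd <- stats::sd(pv)
  score <- vapply(through_focus, function(t) {
    sv <- as.vector(t$intensity - mean(t$intensity))
    s_sd <- stats::sd(sv)
    if (p_sd < 1e-12) return(-s_sd)            # featureless plane: least contrast wins
    if (s_sd < 1e-12) return(0)
    sum(pv * sv) / (length(pv) * p_sd * s_sd)
  }, numeric(1))
  i <- which.max(score)
  if (i == 1L || i == length(score))
    stop("correlation peak at the boundary of the through-focus stack (out of range)")
  y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  z_star <- zs[i] + delta * (zs[i + 1] - zs[i])
  lam_c <- capture$channels[[channel]]$center_wavelength
  out <- if (wavelength_correct) z_star * stack_wavelength / lam_c else z_star
  attr(out, "stack_z") <- z_star
  out
}
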