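# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are reproducible without clobbering the
#' session stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Angular spatial frequencies (rad/um) for an n-point axis with given pitch,
# in FFT (wrap-around) order.
fft_freq <- function(n, pitch) {
  idx <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  2 * pi * idx / (n * pitch)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Mirror (even) padding to twice the size in each dimension; suppresses FFT
# wrap-around for compact fields while keeping the extended field continuous.
pad_mirror <- function(m) {
  rbind(cbind(m, m[, ncol(m):1, drop = FALSE]),
        cbind(m[nrow(m):1, , drop = FALSE], m[nrow(m):1, ncol(m):1, drop = FALSE]))
}

pad_zero <- function(m) {
  out <- matrix(if (is.complex(m)) 0 + 0i else 0, 2L * nrow(m), 2L * ncol(m))
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

crop_topleft <- function(m, nr, nc) m[seq_len(nr), seq_len(nc), drop = FALSE]

# Second-order central differences with one-sided second-order stencils at the
# edges. dim = 1 differentiates down rows (y), dim = 2 across columns (x).
diff_central <- function(m, pitch, dim = 2L) {
  n <- dim(m)[dim]
  if (n < 3L) stop("need at least 3 samples to differentiate")
  if (dim == 1L) m <- t(m)
  d <- m
  d[, 2:(n - 1L)] <- (m[, 3:n] - m[, 1:(n - 2L)]) / (2 * pitch)
  d[, 1L] <- (-3 * m[, 1L] + 4 * m[, 2L] - m[, 3L]) / (2 * pitch)
  d[, n] <- (3 * m[, n] - 4 * m[, n - 1L] + m[, n - 2L]) / (2 * pitch)
  if (dim == 1L) t(d) else d
}

# Second derivative, central with one-sided ends.
diff2_central <- function(m, pitch, dim = 2L) {
  n <- dim(m)[dim]
  if (dim == 1L) m <- t(m)
  d <- m
  d[, 2:(n - 1L)] <- (m[, 3:n] - 2 * m[, 2:(n - 1L)] + m[, 1:(n - 2L)]) / pitch^2
  d[, 1L] <- (m[, 1L] - 2 * m[, 2L] + m[, 3L]) / pitch^2
  d[, n] <- (m[, n] - 2 * m[, n - 1L] + m[, n - 2L]) / pitch^2
  if (dim == 1L) t(d) else d
}

# Spectral (FFT) first derivative of a real map; exact for band-limited
# periodic data, used inside the Fourier-domain solver.
fourier_gradient <- function(m, pitch) {
  kx <- fft_freq(ncol(m), pitch)
  ky <- fft_freq(nrow(m), pitch)
  Fm <- fft2(m)
  gx <- Re(ifft2(Fm * matrix(1i * kx, nrow(m), ncol(m), byrow = TRUE)))
  gy <- Re(ifft2(Fm * matrix(1i * ky, nrow(m), ncol(m))))
  list(x = gx, y = gy)
}

fourier_divergence <- function(vx, vy, pitch) {
  kx <- fft_freq(ncol(vx), pitch)
  ky <- fft_freq(nrow(vx), pitch)
  Re(ifft2(fft2(vx) * matrix(1i * kx, nrow(vx), ncol(vx), byrow = TRUE) +
             fft2(vy) * matrix(1i * ky, nrow(vy), ncol(vy))))
}

rms <- function(x) sqrt(mean(x^2))

nm_to_um <- function(wavelength_nm) wavelength_nm / 1000

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
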