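#' Temporal high-pass filtering of pixel-value time series
#'
#' Removes the slow (respiratory and drift) component of a pixel-value time
#' series so that only the cardiac-band oscillation remains. The filter is a
#' 4th-order Butterworth high-pass applied forward and backward (zero phase):
#' zero-phase filtering is essential here because the downstream
#' cross-correlation compares the *timing* of the lung and ventricle
#' waveforms, and a causal filter would shift both by a frequency-dependent
#' lag. The effective magnitude response is the squared Butterworth response;
#' the half-power point of a single pass sits at `cutoff_hz`.
#'
#' Edge effects are handled by odd-reflection padding of `2 * filter order`
#' samples at each end with step-response initial conditions, so a constant
#' series maps to (numerically) zero everywhere.
#'
#' @param series numeric vector, one sample per frame.
#' @param frame_rate_hz sampling rate in frames per second.
#' @param cutoff_hz high-pass cutoff frequency in Hz; must lie strictly
#'   between 0 and the Nyquist frequency. Default 0.85 Hz, separating the
#'   respiratory band (< ~0.5 Hz) from the cardiac band (> ~0.85 Hz).
#' @return numeric vector of the same length, zero-phase high-pass filtered.
#' @examples
#' t <- seq(0, 10, by = 1 / 15)
#' x <- sin(2 * pi * 1.2 * t) + 5 * sin(2 * pi * 0.25 * t)
#' y <- highpass_filter(x, frame_rate_hz = 15)
#' @export
highpass_filter <- function(series, frame_rate_hz, cutoff_hz = 0.85) {
  if (!is.numeric(series)) stopf("`series` must be numeric")
  co <- hp_coefficients(frame_rate_hz, cutoff_hz)
  drop(zero_phase_filter(matrix(series, ncol = 1L), co$b, co$a))
}

# Butterworth high-pass coefficients (order 4), shared by all filtering paths.
hp_coefficients <- function(frame_rate_hz, cutoff_hz, order = 4L) {
  if (!is_num1(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("`frame_rate_hz` must be a positive number")
  if (!is_num1(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= frame_rate_hz / 2)
    stopf("`cutoff_hz` must lie in (0, frame_rate_hz/2) = (0, %g)",
          frame_rate_hz / 2)
  bf <- signal::butter(order, cutoff_hz / (frame_rate_hz / 2), type = "high")
  list(b = bf$b, a = bf$a)
}

# Steady-state initial filter state for a unit step (direct form II
# transposed), so that filtering a constant produces no start-up transient.
lfilter_zi <- function(b, a) {
  b <- b / a[1L]
  a <- a / a[1L]
  n <- length(a)
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[2L:n]
  if (n > 2L) comp[cbind(2L:(n - 1L), 1L:(n - 2L))] <- 1
  solve(diag(n - 1L) - t(comp), b[2L:n] - a[2L:n] * b[1L])
}

# IIR filter along the rows (time) of a T x P matrix, direct form II
# transposed, vectorised over the P series. `zi` is an (order x P) state
# matrix or NULL for zero initial conditions.
filter_mat <- function(b, a, x, zi = NULL) {
  b <- b / a[1L]
  a <- a / a[1L]
  n <- length(a)
  nt <- nrow(x)
  np <- ncol(x)
  y <- matrix(0, nt, np)
  z <- vector("list", n - 1L)
  for (k in seq_len(n - 1L))
    z[[k]] <- if (is.null(zi)) numeric(np) else zi[k, ]
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[[1L]]
    if (n > 2L)
      for (k in seq_len(n - 2L))
        z[[k]] <- b[k + 1L] * xt + z[[k + 1L]] - a[k + 1L] * yt
    z[[n - 1L]] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# Zero-phase (forward-backward) filtering of every column of a T x P matrix,
# with odd-reflection edge padding of 2*(filter order) samples.
zero_phase_filter <- function(x, b, a) {
  pad <- 2L * (length(a) - 1L)
  nt <- nrow(x)
  if (nt < pad + 1L)
    stopf("series too short for zero-phase filtering: need at least %d frames, got %d",
          pad + 1L, nt)
  zi <- lfilter_zi(b, a)
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(nt, pad), , drop = FALSE] -
    x[(nt - 1L):(nt - pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  y <- filter_mat(b, a, ext, zi = zi %o% ext[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- filter_mat(b, a, y, zi = zi %o% y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(pad + 1L):(pad + nt), , drop = FALSE]
}
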