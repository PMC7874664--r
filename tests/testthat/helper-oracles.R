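# Small parameter sets and independent brute-force oracles shared by the
# test files. The oracles deliberately use direct textbook formulas (or
# double loops), not the package's vectorised paths.

tiny_params <- function(...) {
  defaults <- list(image_height_px = 16L, image_width_px = 16L,
                   n_frames = 60L, noise_sd = 20, resp_amplitude = 0,
                   rng_seed = 1L)
  do.call(synth_imaging_params, modifyList(defaults, list(...)))
}

# Per-pixel, per-window Pearson correlation by explicit double loop.
# Filtering reuses highpass_filter (the oracle targets the windowed
# correlation machinery); correlations come from stats::cor.
naive_ccv <- function(sim, cardiac, window_frames) {
  px <- sim$sequence$pixels
  d <- dim(px)
  lung <- sim$masks$right_lung | sim$masks$left_lung
  r <- -cardiac$pc_lv
  half <- (window_frames - 1L) %/% 2L
  centers <- (half + 1L):(d[3L] - (window_frames - 1L - half))
  ccv <- array(NA_real_, c(d[1L], d[2L], length(centers)))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    if (!lung[i, j]) next
    ser <- highpass_filter(px[i, j, ], sim$sequence$frame_rate_hz)
    for (k in seq_along(centers)) {
      wi <- (centers[k] - half):(centers[k] + window_frames - 1L - half)
      ccv[i, j, k] <- suppressWarnings(stats::cor(ser[wi], r[wi]))
    }
  }
  list(ccv = ccv, centers = centers)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = r^2, p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

bland_altman_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  m <- (a + b) / 2
  sl <- sum((m - mean(m)) * (d - md)) / sum((m - mean(m))^2)
  list(mean_difference = md, sd_difference = sdd,
       loa_low = md - 2 * sdd, loa_high = md + 2 * sdd,
       pct_within_2sd = 100 * sum(abs(d - md) <= 2 * sdd) / n,
       prop_error_slope = sl, prop_error_intercept = md - sl * mean(m))
}

t_test_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, p_value = 2 * stats::pt(-abs(tval), n1 + n2 - 2))
}

# Zero-phase magnitude response of the package's filter design at `f_hz`
# (squared single-pass Butterworth response, evaluated on the unit circle).
zero_phase_gain <- function(f_hz, fs_hz, cutoff_hz = 0.85, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "high")
  z <- exp(1i * 2 * pi * f_hz / fs_hz)
  Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
      sum(bf$a * z^-(seq_along(bf$a) - 1)))^2
}
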