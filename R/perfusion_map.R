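#' Extract the cardiac reference signal from the ventricle ROI
#'
#' Averages pixel values over the ventricle ROI frame by frame, high-pass
#' filters the resulting series to isolate the cardiac component
#' (`pc_lv(t)`), and estimates the cardiac period from the dominant spectral
#' peak in the 0.85–3.0 Hz band (51–180 beats/min). The spectral peak must
#' concentrate a minimum fraction of the band power: a flat (noise-only or
#' constant) spectrum raises a "no cardiac component detected" error rather
#' than returning a spurious period.
#'
#' @param seq a [frame_sequence()].
#' @param masks an [anatomy_masks()] with a nonempty ventricle ROI.
#' @param cutoff_hz high-pass cutoff (Hz) passed to [highpass_filter()].
#' @param min_peak_snr minimum ratio of the peak periodogram ordinate to the
#'   median ordinate in the cardiac band (at native frequency resolution)
#'   for the peak to count as a detected cardiac component; a noise-only
#'   spectrum stays an order of magnitude below the default.
#' @return an object of class `cardiac_signal`: list with `pc_lv` (zero-mean
#'   filtered ROI mean series), `estimated_period_frames`,
#'   `estimated_freq_hz`, and `frame_rate_hz`.
#' @export
extract_ventricle_signal <- function(seq, masks, cutoff_hz = 0.85,
                                     min_peak_snr = 20) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(masks, "anatomy_masks"))
  if (!any(masks$ventricle_roi)) stopf("ventricle ROI is empty")
  d <- dim(seq$pixels)
  if (!identical(dim(masks$ventricle_roi), d[1:2]))
    stopf("mask geometry does not match sequence geometry")
  nt <- d[3L]
  fs <- seq$frame_rate_hz
  px <- matrix(seq$pixels, d[1L] * d[2L], nt)
  roi_mean <- colMeans(px[as.vector(masks$ventricle_roi), , drop = FALSE])
  if (sd(roi_mean) < 1e-12 * max(1, mean(abs(roi_mean))))
    stopf("no cardiac component detected: ventricle ROI signal is constant")
  pc_lv <- highpass_filter(roi_mean, fs, cutoff_hz)
  pc_lv <- pc_lv - mean(pc_lv)  # edge transients leave a small residual mean

  # Detection on the native-resolution periodogram (independent bins): the
  # peak must stand clear of the band's median ordinate (the noise floor).
  pw_nat <- Mod(fft(pc_lv))^2
  f_nat <- (seq_len(nt) - 1L) * fs / nt
  band_nat <- which(f_nat >= 0.85 & f_nat <= min(3.0, fs / 2))
  if (length(band_nat) < 3L) stopf("no usable cardiac band below Nyquist")
  snr <- max(pw_nat[band_nat]) / median(pw_nat[band_nat])
  if (!is.finite(snr) || snr < min_peak_snr)
    stopf("no cardiac component detected: peak-to-median periodogram ratio %.1f in the 0.85-3 Hz band (need >= %g)",
          snr, min_peak_snr)

  # Frequency refinement from a zero-padded periodogram.
  nfft <- 2^ceiling(log2(8L * nt))
  pw <- Mod(fft(c(pc_lv, numeric(nfft - nt))))^2
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  band <- which(freqs >= 0.85 & freqs <= min(3.0, fs / 2))
  f_card <- freqs[band[which.max(pw[band])]]
  period <- as.integer(round(fs / f_card))
  structure(list(pc_lv = pc_lv,
                 estimated_period_frames = period,
                 estimated_freq_hz = f_card,
                 frame_rate_hz = fs),
            class = "cardiac_signal")
}

#' @export
print.cardiac_signal <- function(x, ...) {
  cat(sprintf("cardiac_signal: %d frames @ %g fps, estimated %.2f Hz (period %d frames)\n",
              length(x$pc_lv), x$frame_rate_hz, x$estimated_freq_hz,
              x$estimated_period_frames))
  invisible(x)
}

#' Per-pixel cross-correlation perfusion map (CCv / MaxCCv)
#'
#' For every lung-field pixel, high-pass filters its time series
#' (`pc_lf(x, y, t)`) and computes, frame by frame, the Pearson correlation
#' between `-1 * pc_lv` and the pixel series over a sliding window centred
#' on each frame. Because lung-field attenuation moves opposite to the
#' ventricle signal, a well-perfused pixel correlates strongly with the
#' *negated* reference: CCv near +1 means blood flow, CCv near -1 means an
#' in-phase (non-perfusion) signal. `max_ccv` is the per-pixel maximum of
#' CCv over all valid frames.
#'
#' Window centres where the full window does not fit inside the sequence
#' are excluded (`valid_frames`). Windows with zero temporal variance yield
#' CCv 0 and are flagged undefined, as are pixels saturated in more than
#' `saturation_frac` of frames; undefined pixels have `max_ccv = NA`.
#'
#' @param seq a [frame_sequence()].
#' @param cardiac a `cardiac_signal` from [extract_ventricle_signal()].
#' @param masks an [anatomy_masks()]; only lung-field pixels are mapped.
#' @param window_frames sliding-window length in frames; default one
#'   estimated cardiac period, rounded to the nearest odd count, minimum 5.
#' @param cutoff_hz high-pass cutoff (Hz) for the per-pixel filtering; use
#'   the same value as for the reference signal.
#' @param spatial_bin optional k for k x k spatial binning before
#'   correlation (block-mean time series assigned back to member pixels);
#'   default 1 (per-pixel, no binning).
#' @param saturation_frac pixels at `saturation_level` in more than this
#'   fraction of frames are flagged undefined.
#' @param store_ccv keep the full `height x width x n_windows` CCv array
#'   (set `FALSE` to save memory; `max_ccv` is always computed).
#' @return an object of class `perfusion_map`: list with `max_ccv`
#'   (`height x width`, `NA` outside lung fields and for undefined pixels),
#'   `ccv` (array `height x width x length(valid_frames)` or `NULL`),
#'   `undefined` (logical matrix: lung pixels with no defined CCv),
#'   `valid_frames` (window-centre frame indices), `window_frames`, and
#'   `cardiac_freq_hz_est`.
#' @export
compute_ccv <- function(seq, cardiac, masks, window_frames = NULL,
                        cutoff_hz = 0.85, spatial_bin = 1L,
                        saturation_frac = 0.10, store_ccv = TRUE) {
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(cardiac, "cardiac_signal"),
            inherits(masks, "anatomy_masks"))
  d <- dim(seq$pixels)
  h <- d[1L]; w <- d[2L]; nt <- d[3L]
  if (!identical(dim(masks$right_lung), c(h, w)))
    stopf("mask geometry does not match sequence geometry")
  lung <- masks$right_lung | masks$left_lung
  if (!any(masks$right_lung) || !any(masks$left_lung))
    stopf("both lung masks must be nonempty")
  if (length(cardiac$pc_lv) != nt)
    stopf("cardiac signal length (%d) does not match sequence (%d frames)",
          length(cardiac$pc_lv), nt)

  if (is.null(window_frames)) {
    window_frames <- max(5L, cardiac$estimated_period_frames)
    if (window_frames %% 2L == 0L) window_frames <- window_frames + 1L
  }
  window_frames <- as.integer(window_frames)
  if (window_frames < 3L) stopf("window_frames must be at least 3")
  if (window_frames > nt)
    stopf("window of %d frames does not fit in a %d-frame sequence",
          window_frames, nt)

  idx <- which(as.vector(lung))
  px <- t(matrix(seq$pixels, h * w, nt)[idx, , drop = FALSE])  # T x P

  # saturated pixels are excluded from analysis entirely
  sat_frac <- colMeans(px >= seq$saturation_level)
  saturated <- sat_frac > saturation_frac

  # optional k x k block binning: replace each pixel series by its block mean
  if (spatial_bin > 1L) {
    k <- as.integer(spatial_bin)
    rr <- ((idx - 1L) %% h) %/% k
    cc <- ((idx - 1L) %/% h) %/% k
    block <- rr + cc * ((h %/% k) + 1L)
    keep <- !saturated
    bsum <- rowsum(t(px[, keep, drop = FALSE]), block[keep])
    bn <- as.vector(table(block[keep]))
    bmean <- bsum / bn
    px[, keep] <- t(bmean[match(block[keep], sort(unique(block[keep]))), ,
                          drop = FALSE])
  }

  co <- hp_coefficients(seq$frame_rate_hz, cutoff_hz)
  xf <- zero_phase_filter(px, co$b, co$a)  # T x P, filtered

  r <- -cardiac$pc_lv
  wlen <- window_frames
  half <- (wlen - 1L) %/% 2L
  nwin <- nt - wlen + 1L
  centers <- seq_len(nwin) + half

  # moving window sums along time, from one global cumulative sum per matrix
  # (column offsets cancel in the window differences)
  movsum <- function(m) {
    np <- ncol(m)
    cs <- matrix(cumsum(m), nt, np)
    base <- rbind(c(0, cs[nt, -np, drop = TRUE]), cs)  # (T+1) x P
    base[(wlen + 1L):(nt + 1L), , drop = FALSE] -
      base[1L:(nt - wlen + 1L), , drop = FALSE]
  }
  sx <- movsum(xf)
  sxx <- movsum(xf * xf)
  sxr <- movsum(xf * r)          # column-major recycling: each column * r
  sr <- as.vector(movsum(matrix(r, ncol = 1L)))
  srr <- as.vector(movsum(matrix(r * r, ncol = 1L)))

  # nwin x P matrices; length-nwin vectors recycle down columns
  varx <- sxx - sx * sx / wlen
  varr <- srr - sr * sr / wlen
  cov <- sxr - sx * (sr / wlen)

  tol <- (1e-6 * seq$saturation_level)^2  # zero-variance threshold
  den <- sqrt(pmax(varx, 0)) * sqrt(pmax(varr, 0))
  zero_var <- (varx <= tol) | (varr <= tol)
  den[zero_var] <- 1
  ccv <- cov / den
  ccv[zero_var] <- 0
  ccv <- clamp(ccv, -1, 1)
  if (any(saturated)) ccv[, saturated] <- 0

  defined <- !zero_var
  if (any(saturated)) defined[, saturated] <- FALSE
  tmp <- ccv
  tmp[!defined] <- -Inf
  mx <- tmp[1L, ]
  if (nwin > 1L) for (t in 2L:nwin) mx <- pmax(mx, tmp[t, ])
  undef_px <- !is.finite(mx)
  mx[undef_px] <- NA_real_

  max_ccv <- matrix(NA_real_, h, w)
  max_ccv[idx] <- mx
  undefined <- matrix(FALSE, h, w)
  undefined[idx] <- undef_px

  ccv_arr <- NULL
  if (store_ccv) {
    flat <- matrix(NA_real_, h * w, nwin)
    tmp2 <- ccv
    tmp2[!defined] <- NA_real_
    flat[idx, ] <- t(tmp2)
    ccv_arr <- array(flat, c(h, w, nwin))
  }

  structure(list(max_ccv = max_ccv, ccv = ccv_arr, undefined = undefined,
                 valid_frames = centers, window_frames = wlen,
                 cardiac_freq_hz_est = cardiac$estimated_freq_hz),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  n_def <- sum(!is.na(x$max_ccv))
  cat(sprintf("perfusion_map: %d x %d, %d defined lung pixels, window %d frames, %d valid frames\n",
              nrow(x$max_ccv), ncol(x$max_ccv), n_def, x$window_frames,
              length(x$valid_frames)))
  if (n_def > 0)
    cat(sprintf("  MaxCCv: median %.3f, range [%.3f, %.3f]\n",
                median(x$max_ccv, na.rm = TRUE), min(x$max_ccv, na.rm = TRUE),
                max(x$max_ccv, na.rm = TRUE)))
  invisible(x)
}
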