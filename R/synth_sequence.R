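#' Parameters of the synthetic dynamic-radiograph simulator
#'
#' Bundles the acquisition and signal parameters used by
#' [generate_sequence()]. The acquisition defaults mirror a clinical
#' breath-hold protocol on a 1024x1024 flat-panel detector (15 frames/s,
#' 0.417 mm pixels, 16-bit values saturating near 58,000), scaled down to a
#' 128x128 grid for desk-scale runtimes; the full-scale geometry is obtained
#' by setting `image_height_px = image_width_px = 1024` and
#' `pixel_spacing_mm = 0.417`.
#'
#' The simulated signal model is, per pixel and frame,
#' `baseline - A_perf(x, y) * s_card(t) + A_resp * s_resp(t) + noise` inside
#' the lung fields and `baseline + A_vent * s_card(t) + noise` inside the
#' ventricle ROI: lung-field attenuation *decreases* during systole while the
#' ventricle signal *increases*, so the two are in anti-phase, which is the
#' contrast the cross-correlation analysis exploits.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param n_frames number of frames in the sequence.
#' @param frame_rate_hz acquisition frame rate (frames per second).
#' @param pixel_spacing_mm physical size of one pixel (mm); used to size the
#'   25 x 25 mm ventricle ROI.
#' @param cardiac_freq_hz heart rate in Hz (1.25 Hz = 75 beats/min).
#' @param resp_freq_hz residual respiratory frequency in Hz (breath-hold
#'   leaves a small drift; set `resp_amplitude = 0` to remove it).
#' @param resp_amplitude,perfusion_amplitude_left,perfusion_amplitude_right,ventricle_amplitude
#'   oscillation amplitudes in pixel-value units.
#' @param noise_sd per-pixel per-frame additive Gaussian noise SD
#'   (pixel-value units).
#' @param baseline_level mean pixel value (pixel-value units).
#' @param saturation_level detector saturation; generated values are clipped
#'   to `[0, saturation_level]`.
#' @param cardiac_waveform `"sine"` or `"fast_upstroke"` (asymmetric periodic
#'   shape with a steeper systolic upstroke); both have unit peak amplitude.
#' @param rng_seed integer seed for reproducible generation.
#' @param allow_clipping set `TRUE` to permit `baseline + amplitudes` to
#'   exceed the saturation level (for tests that exercise clipping).
#' @return an object of class `synth_imaging_params` (a validated list).
#' @seealso [generate_sequence()], [default_anatomy_masks()]
#' @export
synth_imaging_params <- function(image_height_px = 128L,
                                 image_width_px = 128L,
                                 n_frames = 150L,
                                 frame_rate_hz = 15,
                                 pixel_spacing_mm = 0.417 * 1024 / 128,
                                 cardiac_freq_hz = 1.25,
                                 resp_freq_hz = 0.25,
                                 resp_amplitude = 60,
                                 perfusion_amplitude_left = 200,
                                 perfusion_amplitude_right = 200,
                                 ventricle_amplitude = 600,
                                 noise_sd = 50,
                                 baseline_level = 30000,
                                 saturation_level = 58000,
                                 cardiac_waveform = c("sine", "fast_upstroke"),
                                 rng_seed = 1L,
                                 allow_clipping = FALSE) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_frames = as.integer(n_frames),
    frame_rate_hz = frame_rate_hz,
    pixel_spacing_mm = pixel_spacing_mm,
    cardiac_freq_hz = cardiac_freq_hz,
    resp_freq_hz = resp_freq_hz,
    resp_amplitude = resp_amplitude,
    perfusion_amplitude_left = perfusion_amplitude_left,
    perfusion_amplitude_right = perfusion_amplitude_right,
    ventricle_amplitude = ventricle_amplitude,
    noise_sd = noise_sd,
    baseline_level = baseline_level,
    saturation_level = saturation_level,
    cardiac_waveform = match.arg(cardiac_waveform),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    allow_clipping = isTRUE(allow_clipping)
  )
  class(p) <- "synth_imaging_params"
  validate_imaging_params(p)
  p
}

validate_imaging_params <- function(p) {
  amps <- c(p$resp_amplitude, p$perfusion_amplitude_left,
            p$perfusion_amplitude_right, p$ventricle_amplitude)
  if (p$image_height_px < 8L || p$image_width_px < 8L)
    stopf("image must be at least 8 x 8 pixels")
  if (p$n_frames < 2L) stopf("n_frames must be at least 2")
  if (p$frame_rate_hz <= 2 * p$cardiac_freq_hz)
    stopf("frame_rate_hz (%g) must exceed twice cardiac_freq_hz (%g) for the cardiac signal to be resolvable",
          p$frame_rate_hz, p$cardiac_freq_hz)
  if (!(p$resp_freq_hz < 0.85 && 0.85 < p$cardiac_freq_hz))
    stopf("need resp_freq_hz < 0.85 Hz < cardiac_freq_hz so the high-pass filter separates the two components")
  if (any(amps < 0) || p$noise_sd < 0)
    stopf("amplitudes and noise_sd must be nonnegative")
  if (p$baseline_level < 0 || p$saturation_level <= 0)
    stopf("baseline_level must be >= 0 and saturation_level > 0")
  headroom <- p$baseline_level + max(p$perfusion_amplitude_left,
                                     p$perfusion_amplitude_right,
                                     p$ventricle_amplitude) + p$resp_amplitude
  if (!p$allow_clipping && headroom > p$saturation_level)
    stopf("baseline_level + amplitudes (%g) exceeds saturation_level (%g); set allow_clipping = TRUE if clipping is intended",
          headroom, p$saturation_level)
  invisible(p)
}

# Unit-peak periodic cardiac waveform as a function of phase (radians).
cardiac_waveform_fn <- function(type) {
  switch(type,
    sine = function(theta) sin(theta),
    fast_upstroke = {
      raw <- function(theta) sin(theta) + 0.35 * sin(2 * theta + 0.9)
      peak <- max(abs(raw(seq(0, 2 * pi, length.out = 4096L))))
      function(theta) raw(theta) / peak
    },
    stopf("unknown cardiac waveform '%s'", type)
  )
}

#' Default lung-field and ventricle masks for the synthetic thorax
#'
#' Places two rounded-rectangle lung fields and a square ventricle ROI
#' between them, scaled to the image size. Image row 1 is superior. Side
#' labels are anatomical: the *right* lung of the subject appears on the
#' viewer's left in a posteroanterior radiograph, i.e. in the low-column
#' half of the image.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param pixel_spacing_mm pixel size in mm; the ventricle ROI is 25 x 25 mm.
#' @return an [anatomy_masks()] object.
#' @export
default_anatomy_masks <- function(image_height_px, image_width_px,
                                  pixel_spacing_mm) {
  h <- as.integer(image_height_px)
  w <- as.integer(image_width_px)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  rounded_rect <- function(r0, r1, c0, c1, rad) {
    core <- (rows >= r0 & rows <= r1 & cols >= c0 + rad & cols <= c1 - rad) |
      (rows >= r0 + rad & rows <= r1 - rad & cols >= c0 & cols <= c1)
    corner <- function(rc, cc)
      (rows - rc)^2 + (cols - cc)^2 <= rad^2
    core |
      corner(r0 + rad, c0 + rad) | corner(r0 + rad, c1 - rad) |
      corner(r1 - rad, c0 + rad) | corner(r1 - rad, c1 - rad)
  }

  r0 <- round(0.12 * h); r1 <- round(0.88 * h)
  rad <- round(0.12 * (r1 - r0))
  rc1 <- round(0.38 * w)
  lc0 <- round(0.62 * w)
  right <- rounded_rect(r0, r1, round(0.08 * w), rc1, rad)
  left  <- rounded_rect(r0, r1, lc0, round(0.92 * w), rad)

  # 25 x 25 mm ROI, clamped to fit the mediastinal gap between the lungs
  gap <- lc0 - rc1 - 1L
  side <- max(2L, min(round(25 / pixel_spacing_mm), gap - 2L, round(0.2 * h)))
  vr0 <- round(0.62 * h - side / 2)
  vc0 <- round((rc1 + lc0) / 2 - side / 2)
  vent <- rows >= vr0 & rows < vr0 + side & cols >= vc0 & cols < vc0 + side

  anatomy_masks(right_lung = right, left_lung = left, ventricle_roi = vent)
}

#' Anatomical region masks
#'
#' Container for the three pixel regions the perfusion analysis needs:
#' the two lung fields and the ventricle reference ROI. Regions must be
#' pairwise disjoint logical matrices of identical size, and the ventricle
#' ROI must be nonempty. Side labels refer to subject anatomy, not display
#' side.
#'
#' @param right_lung,left_lung,ventricle_roi logical matrices of identical
#'   dimensions.
#' @return an object of class `anatomy_masks`.
#' @export
anatomy_masks <- function(right_lung, left_lung, ventricle_roi) {
  ms <- list(right_lung = right_lung, left_lung = left_lung,
             ventricle_roi = ventricle_roi)
  for (nm in names(ms)) {
    if (!is.logical(ms[[nm]]) || !is.matrix(ms[[nm]]))
      stopf("mask '%s' must be a logical matrix", nm)
  }
  d <- dim(right_lung)
  if (!identical(d, dim(left_lung)) || !identical(d, dim(ventricle_roi)))
    stopf("masks must share the same dimensions")
  if (any(right_lung & left_lung) || any(right_lung & ventricle_roi) ||
      any(left_lung & ventricle_roi))
    stopf("masks must be pairwise disjoint")
  if (!any(ventricle_roi)) stopf("ventricle ROI is empty")
  structure(ms, class = "anatomy_masks")
}

#' @export
print.anatomy_masks <- function(x, ...) {
  d <- dim(x$right_lung)
  cat(sprintf("anatomy_masks %d x %d: right lung %d px, left lung %d px, ventricle ROI %d px\n",
              d[1L], d[2L], sum(x$right_lung), sum(x$left_lung),
              sum(x$ventricle_roi)))
  invisible(x)
}

#' Dynamic radiograph frame sequence
#'
#' A stack of frames with acquisition metadata. Pixel values must lie in
#' `[0, saturation_level]`, and the sequence must be long enough to contain
#' about two cycles at the 0.85 Hz band edge
#' (`n_frames >= 2 * frame_rate_hz / 0.85`), otherwise the cardiac band is
#' not observable after filtering.
#'
#' @param pixels numeric array `height x width x n_frames`.
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param pixel_spacing_mm pixel size (mm).
#' @param saturation_level detector saturation (pixel-value units).
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(pixels, frame_rate_hz, pixel_spacing_mm,
                           saturation_level) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("`pixels` must be a height x width x frames array")
  nt <- dim(pixels)[3L]
  min_frames <- ceiling(2 * frame_rate_hz / 0.85)
  if (nt < min_frames)
    stopf("sequence too short: %d frames, need >= %d (two cycles at the 0.85 Hz band edge)",
          nt, min_frames)
  rng <- range(pixels)
  if (rng[1L] < 0 || rng[2L] > saturation_level)
    stopf("pixel values outside [0, saturation_level]")
  structure(list(pixels = pixels, frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm,
                 saturation_level = saturation_level),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame_sequence: %d x %d pixels, %d frames @ %g fps (%.1f s), saturation %g\n",
              d[1L], d[2L], d[3L], x$frame_rate_hz, d[3L] / x$frame_rate_hz,
              x$saturation_level))
  invisible(x)
}

#' Generate a synthetic dynamic radiograph sequence
#'
#' Simulates a breath-hold dynamic chest radiograph stack with a known
#' perfusion ground truth. Lung-field pixels oscillate in anti-phase with
#' the ventricle ROI at the cardiac frequency (amplitude proportional to
#' regional perfusion), an optional low-frequency respiratory residual is
#' added over the lung fields, i.i.d. Gaussian noise is added everywhere,
#' and values are clipped to `[0, saturation_level]`.
#'
#' @param params a [synth_imaging_params()] object.
#' @param masks optional [anatomy_masks()]; defaults to
#'   [default_anatomy_masks()] for the configured geometry.
#' @return a list with components `sequence` ([frame_sequence()]),
#'   `masks` ([anatomy_masks()]), and `truth`, a `ground_truth` list with
#'   the per-pixel perfusion amplitude map, `true_left_fraction` (the left
#'   lung's share of total perfusion amplitude), the cardiac frequency, and
#'   the exact component waveforms used (`cardiac`, unit amplitude;
#'   `ventricle` and `respiratory`, in pixel-value units).
#' @examples
#' sim <- generate_sequence(synth_imaging_params(
#'   image_height_px = 32, image_width_px = 32, n_frames = 60, noise_sd = 10))
#' sim$truth$true_left_fraction
#' @export
generate_sequence <- function(params, masks = NULL) {
  stopifnot(inherits(params, "synth_imaging_params"))
  validate_imaging_params(params)
  h <- params$image_height_px
  w <- params$image_width_px
  nt <- params$n_frames
  if (is.null(masks)) {
    masks <- default_anatomy_masks(h, w, params$pixel_spacing_mm)
  }
  if (!inherits(masks, "anatomy_masks")) stopf("`masks` must be an anatomy_masks object")
  if (!identical(dim(masks$right_lung), c(h, w)))
    stopf("mask geometry (%d x %d) does not match image geometry (%d x %d)",
          nrow(masks$right_lung), ncol(masks$right_lung), h, w)

  tt <- (seq_len(nt) - 1L) / params$frame_rate_hz
  wf <- cardiac_waveform_fn(params$cardiac_waveform)
  s_card <- wf(2 * pi * params$cardiac_freq_hz * tt)
  s_resp <- sin(2 * pi * params$resp_freq_hz * tt)

  amp_map <- matrix(0, h, w)
  amp_map[masks$left_lung] <- params$perfusion_amplitude_left
  amp_map[masks$right_lung] <- params$perfusion_amplitude_right

  lung <- masks$left_lung | masks$right_lung
  x <- with_seed(params$rng_seed, {
    x <- matrix(params$baseline_level, h * w, nt)
    x[lung, ] <- x[lung, ] - amp_map[lung] %o% s_card +
      rep(params$resp_amplitude, sum(lung)) %o% s_resp
    x[masks$ventricle_roi, ] <- x[masks$ventricle_roi, ] +
      rep(params$ventricle_amplitude, sum(masks$ventricle_roi)) %o% s_card
    if (params$noise_sd > 0)
      x <- x + matrix(rnorm(h * w * nt, sd = params$noise_sd), h * w, nt)
    x
  })
  x <- clamp(x, 0, params$saturation_level)

  denom <- sum(amp_map[lung])
  truth <- structure(list(
    perfusion_amplitude_map = amp_map,
    true_left_fraction = if (denom > 0) sum(amp_map[masks$left_lung]) / denom else NA_real_,
    cardiac_freq_hz = params$cardiac_freq_hz,
    waveforms = list(
      time_s = tt,
      cardiac = s_card,
      ventricle = params$ventricle_amplitude * s_card,
      respiratory = params$resp_amplitude * s_resp
    )
  ), class = "ground_truth")

  list(
    sequence = frame_sequence(array(x, c(h, w, nt)),
                              frame_rate_hz = params$frame_rate_hz,
                              pixel_spacing_mm = params$pixel_spacing_mm,
                              saturation_level = params$saturation_level),
    masks = masks,
    truth = truth
  )
}
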