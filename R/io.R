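#' Write / read a frame sequence as multi-frame TIFF with a JSON sidecar
#'
#' The stack is stored as a 16-bit multi-frame TIFF (pixel values divided
#' by 65535 for the `[0, 1]` TIFF convention) and the acquisition metadata
#' (frame rate, pixel spacing, saturation level, plus any ground-truth
#' summary) in a JSON sidecar next to it.
#'
#' @param seq a [frame_sequence()].
#' @param path TIFF file path; the sidecar is written at `paste0(path,
#'   ".json")`.
#' @param truth optional `ground_truth` list from [generate_sequence()];
#'   its scalar summary (true left fraction, cardiac frequency) is stored
#'   in the sidecar.
#' @param rng_seed optional seed to record for provenance.
#' @return `write_frame_sequence()` returns `path` invisibly;
#'   `read_frame_sequence()` returns a [frame_sequence()].
#' @export
write_frame_sequence <- function(seq, path, truth = NULL, rng_seed = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$pixels)
  frames <- lapply(seq_len(d[3L]), function(t) seq$pixels[, , t] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(
    frame_rate_hz = seq$frame_rate_hz,
    pixel_spacing_mm = seq$pixel_spacing_mm,
    saturation_level = seq$saturation_level,
    n_frames = d[3L], height_px = d[1L], width_px = d[2L],
    pixel_scale = 65535
  )
  if (!is.null(rng_seed)) meta$rng_seed <- rng_seed
  if (!is.null(truth))
    meta$ground_truth <- list(true_left_fraction = truth$true_left_fraction,
                              cardiac_freq_hz = truth$cardiac_freq_hz)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_sequence
#' @export
read_frame_sequence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  px <- array(0, c(dim(frames[[1L]]), length(frames)))
  for (t in seq_along(frames)) px[, , t] <- frames[[t]] * meta$pixel_scale
  frame_sequence(px, frame_rate_hz = meta$frame_rate_hz,
                 pixel_spacing_mm = meta$pixel_spacing_mm,
                 saturation_level = meta$saturation_level)
}

#' Write / read anatomy masks as an 8-bit label TIFF
#'
#' Label semantics: 0 background, 1 right lung, 2 left lung, 3 ventricle
#' ROI. Labels refer to subject anatomy; in a posteroanterior radiograph
#' the subject's right lung appears on the viewer's left.
#'
#' @param masks an [anatomy_masks()].
#' @param path TIFF file path.
#' @return `write_masks()` returns `path` invisibly; `read_masks()` an
#'   [anatomy_masks()].
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "anatomy_masks"))
  lab <- matrix(0, nrow(masks$right_lung), ncol(masks$right_lung))
  lab[masks$right_lung] <- 1
  lab[masks$left_lung] <- 2
  lab[masks$ventricle_roi] <- 3
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  lab <- round(tiff::readTIFF(path) * 255)
  anatomy_masks(right_lung = lab == 1, left_lung = lab == 2,
                ventricle_roi = lab == 3)
}

#' Write / read a perfusion map
#'
#' `max_ccv` is exported as a two-frame 32-bit TIFF: frame 1 the map under
#' the affine intensity mapping `(value + 1) / 2` (so CCv -1..1 spans
#' 0..1; undefined pixels stored as 0), frame 2 a 0/1 defined-pixel mask.
#' The JSON sidecar records the mapping, the window length, the estimated
#' cardiac frequency, and the undefined-pixel count. Round-trip error is
#' below 1e-9 (32-bit quantisation of the unit interval). The full CCv
#' array, if present and requested, is written the same way as a
#' multi-frame TIFF at `paste0(path, ".ccv.tif")`.
#'
#' @param map a `perfusion_map` from [compute_ccv()].
#' @param path TIFF file path for the MaxCCv map; sidecar at
#'   `paste0(path, ".json")`.
#' @param write_ccv also export the full CCv stack (large).
#' @return `write_perfusion_map()` returns `path` invisibly;
#'   `read_perfusion_map()` a list with `max_ccv` (NA where undefined),
#'   `window_frames`, `valid_frames`, `cardiac_freq_hz_est`.
#' @export
write_perfusion_map <- function(map, path, write_ccv = FALSE) {
  stopifnot(inherits(map, "perfusion_map"))
  defined <- !is.na(map$max_ccv)
  enc <- map$max_ccv
  enc[!defined] <- -1
  tiff::writeTIFF(list((enc + 1) / 2, defined * 1), path,
                  bits.per.sample = 32L)
  meta <- list(value_mapping = "stored = (ccv + 1) / 2; frame 2 = defined mask",
               window_frames = map$window_frames,
               valid_frames = map$valid_frames,
               cardiac_freq_hz_est = map$cardiac_freq_hz_est,
               n_defined = sum(defined),
               n_undefined_lung = sum(map$undefined))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (write_ccv && !is.null(map$ccv)) {
    frames <- lapply(seq_len(dim(map$ccv)[3L]), function(t) {
      fr <- map$ccv[, , t]
      fr[is.na(fr)] <- -1
      (fr + 1) / 2
    })
    tiff::writeTIFF(frames, paste0(path, ".ccv.tif"), bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_perfusion_map
#' @export
read_perfusion_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  mx <- frames[[1L]] * 2 - 1
  mx[frames[[2L]] < 0.5] <- NA_real_
  list(max_ccv = mx, window_frames = meta$window_frames,
       valid_frames = meta$valid_frames,
       cardiac_freq_hz_est = meta$cardiac_freq_hz_est)
}

#' Write a BFR result (with provenance) as JSON
#'
#' @param bfr a `bfr_result` from [blood_flow_ratio()].
#' @param sums the `lung_field_sums` it was computed from.
#' @param path output JSON path.
#' @param provenance optional named list (input hashes, parameters) stored
#'   verbatim.
#' @return `path`, invisibly.
#' @export
write_bfr_json <- function(bfr, sums, path, provenance = NULL) {
  out <- list(affected_side = bfr$affected_side,
              bfr_affected = bfr$bfr_affected,
              bfr_intact = bfr$bfr_intact,
              sum_max_ccv_left = sums$sum_max_ccv_left,
              sum_max_ccv_right = sums$sum_max_ccv_right,
              n_pixels_left = sums$n_pixels_left,
              n_pixels_right = sums$n_pixels_right)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}
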