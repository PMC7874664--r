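#' Per-lung sums of the MaxCCv map
#'
#' Sums the defined MaxCCv values over each lung field. Undefined pixels
#' (saturated or zero-variance) contribute nothing and are excluded from the
#' pixel counts. Negative MaxCCv values (possible in pure-noise pixels) are
#' included as-is by default, preserving the plain summation definition;
#' `clip_negative = TRUE` floors them at zero instead.
#'
#' @param map a `perfusion_map` from [compute_ccv()].
#' @param masks the [anatomy_masks()] used to compute the map.
#' @param clip_negative replace negative MaxCCv values by 0 before summing.
#' @return an object of class `lung_field_sums`: list with
#'   `sum_max_ccv_left`, `sum_max_ccv_right`, `n_pixels_left`,
#'   `n_pixels_right`.
#' @export
sum_max_ccv <- function(map, masks, clip_negative = FALSE) {
  stopifnot(inherits(map, "perfusion_map"), inherits(masks, "anatomy_masks"))
  if (!identical(dim(map$max_ccv), dim(masks$right_lung)))
    stopf("mask geometry does not match map geometry")
  if (!any(masks$left_lung) || !any(masks$right_lung))
    stopf("both lung masks must be nonempty")
  side_sum <- function(mask) {
    v <- map$max_ccv[mask]
    v <- v[!is.na(v)]
    if (clip_negative) v <- pmax(v, 0)
    list(sum = sum(v), n = length(v))
  }
  l <- side_sum(masks$left_lung)
  r <- side_sum(masks$right_lung)
  structure(list(sum_max_ccv_left = l$sum, sum_max_ccv_right = r$sum,
                 n_pixels_left = l$n, n_pixels_right = r$n),
            class = "lung_field_sums")
}

#' @export
print.lung_field_sums <- function(x, ...) {
  cat(sprintf("lung_field_sums: left %.2f (%d px), right %.2f (%d px)\n",
              x$sum_max_ccv_left, x$n_pixels_left,
              x$sum_max_ccv_right, x$n_pixels_right))
  invisible(x)
}

#' Affected-side blood flow ratio (BFR)
#'
#' The BFR of the affected side is that side's share of the summed MaxCCv
#' over both lung fields:
#' `BFR = SumMaxCCv_affected / (SumMaxCCv_left + SumMaxCCv_right)`.
#' The intact-side ratio is its complement, so the two always sum to 1.
#'
#' @param sums a `lung_field_sums` from [sum_max_ccv()].
#' @param affected_side `"left"` or `"right"` — the side carrying the lesion
#'   to be resected.
#' @return an object of class `bfr_result`: list with `affected_side`,
#'   `bfr_affected`, `bfr_intact`.
#' @examples
#' s <- structure(list(sum_max_ccv_left = 30, sum_max_ccv_right = 70,
#'                     n_pixels_left = 100, n_pixels_right = 100),
#'                class = "lung_field_sums")
#' blood_flow_ratio(s, "left")$bfr_affected  # 0.3
#' @export
blood_flow_ratio <- function(sums, affected_side = c("left", "right")) {
  stopifnot(inherits(sums, "lung_field_sums"))
  affected_side <- match.arg(affected_side)
  total <- sums$sum_max_ccv_left + sums$sum_max_ccv_right
  if (!is.finite(total) || total <= 0)
    stopf("no perfusion signal: summed MaxCCv is not positive")
  bfr_left <- sums$sum_max_ccv_left / total
  bfr_aff <- if (affected_side == "left") bfr_left else 1 - bfr_left
  structure(list(affected_side = affected_side,
                 bfr_affected = bfr_aff,
                 bfr_intact = 1 - bfr_aff),
            class = "bfr_result")
}

#' @export
print.bfr_result <- function(x, ...) {
  cat(sprintf("bfr_result: affected side %s, BFR affected %.4f, intact %.4f\n",
              x$affected_side, x$bfr_affected, x$bfr_intact))
  invisible(x)
}
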