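#' Bronchopulmonary segment table
#'
#' The standard 19-segment partition of the lungs used by the
#' segment-counting method: right upper 3, right middle 2, right lower 5
#' (right total 10); left upper division 3, lingula 2, left lower 4 (left
#' total 9). The resection unit `"left_upper"` is accepted as shorthand for
#' the upper division plus lingula (a left upper lobectomy, 5 segments).
#'
#' @return a data frame with columns `unit`, `side`, `segments`.
#' @export
lung_segment_table <- function() {
  data.frame(
    unit = c("right_upper", "right_middle", "right_lower",
             "left_upper_division", "lingula", "left_lower"),
    side = c("right", "right", "right", "left", "left", "left"),
    segments = c(3L, 2L, 5L, 3L, 2L, 4L),
    stringsAsFactors = FALSE
  )
}

TOTAL_SEGMENTS <- 19L

side_total_segments <- function(side, table = lung_segment_table()) {
  s <- sum(table$segments[table$side == side])
  if (s == 0L) stopf("unknown side '%s'", side)
  s
}

# Resolve a resection description to (segment count, side or NA).
# `resected` is either a character vector of unit names (alias "left_upper"
# expands to upper division + lingula) or a single numeric segment count
# (supporting segmentectomies, which remove 1-3 segments of a unit).
resolve_resection <- function(resected, table = lung_segment_table()) {
  if (is.numeric(resected)) {
    if (length(resected) != 1L || !is_count(resected))
      stopf("a numeric resection must be a single nonnegative segment count")
    return(list(segments = as.integer(resected), side = NA_character_))
  }
  if (!is.character(resected)) stopf("`resected` must be unit names or a segment count")
  resected <- unlist(lapply(resected, function(u) {
    if (u == "left_upper") c("left_upper_division", "lingula") else u
  }), use.names = FALSE)
  unknown <- setdiff(resected, table$unit)
  if (length(unknown) > 0L)
    stopf("unknown resection unit(s): %s; valid units are %s (or 'left_upper', or a segment count)",
          paste(unknown, collapse = ", "), paste(table$unit, collapse = ", "))
  if (anyDuplicated(resected))
    stopf("duplicated resection units")
  i <- match(resected, table$unit)
  sides <- unique(table$side[i])
  list(segments = sum(table$segments[i]),
       side = if (length(sides) == 1L) sides else NA_character_,
       sides = table$side[i], units = resected)
}

#' Predicted postoperative value by segment counting
#'
#' Scales the preoperative value by the fraction of the 19 bronchopulmonary
#' segments that remain after resection:
#' `ppo = pre * (19 - resected) / 19`.
#'
#' @param pre_value preoperative value (e.g. FEV1 in litres, or DLco).
#' @param resected resection description: a character vector of unit names
#'   from [lung_segment_table()] (plus the `"left_upper"` alias), or a
#'   single numeric segment count (for segmentectomies).
#' @param table segment table; override only for sensitivity analyses.
#' @param allow_zero permit a zero-segment "resection" (returns `pre_value`
#'   unchanged); off by default because it usually indicates an input error.
#' @return the predicted postoperative value, same units as `pre_value`.
#' @examples
#' ppo_segment_counting(1.9, "right_upper")  # 1.9 * 16/19 = 1.6
#' @export
ppo_segment_counting <- function(pre_value, resected,
                                 table = lung_segment_table(),
                                 allow_zero = FALSE) {
  if (!is.numeric(pre_value) || any(!is.finite(pre_value)) || any(pre_value <= 0))
    stopf("`pre_value` must be positive")
  res <- resolve_resection(resected, table)
  n <- res$segments
  if (n == 0L && !allow_zero)
    stopf("resected segment count is 0; set allow_zero = TRUE if intended")
  if (n >= TOTAL_SEGMENTS)
    stopf("resected segment count (%d) must be below the %d-segment total",
          n, TOTAL_SEGMENTS)
  pre_value * (TOTAL_SEGMENTS - n) / TOTAL_SEGMENTS
}

#' Predicted postoperative value weighted by the blood flow ratio
#'
#' Refines segment counting with the measured perfusion split between the
#' lungs: the intact side keeps its full perfusion share, while the affected
#' side's share is scaled by the fraction of that side's segments that
#' remain:
#' `ppo = pre * (BFR_intact + remaining_affected / total_affected * BFR_affected)`.
#'
#' When `bfr_affected` equals the affected side's segment share of 19
#' (10/19 right, 9/19 left), this reduces algebraically to
#' [ppo_segment_counting()].
#'
#' @param pre_value preoperative value (positive).
#' @param bfr a [blood_flow_ratio()] result, or a numeric `bfr_affected`
#'   in `[0, 1]` (then `affected_side` must be given).
#' @param resected resection description as in [ppo_segment_counting()];
#'   all named units must lie on the affected side.
#' @param affected_side `"left"` or `"right"`; taken from `bfr` when that is
#'   a `bfr_result`.
#' @param table segment table.
#' @return the predicted postoperative value.
#' @examples
#' ppo_perfusion(2.0, bfr = 0.5, resected = "right_lower",
#'               affected_side = "right")  # 2.0 * (0.5 + 0.5 * 0.5) = 1.5
#' @export
ppo_perfusion <- function(pre_value, bfr, resected, affected_side = NULL,
                          table = lung_segment_table()) {
  if (!is.numeric(pre_value) || any(!is.finite(pre_value)) || any(pre_value <= 0))
    stopf("`pre_value` must be positive")
  if (inherits(bfr, "bfr_result")) {
    if (!is.null(affected_side) && !identical(affected_side, bfr$affected_side))
      stopf("`affected_side` ('%s') contradicts the bfr_result ('%s')",
            affected_side, bfr$affected_side)
    affected_side <- bfr$affected_side
    bfr_affected <- bfr$bfr_affected
  } else {
    if (!is.numeric(bfr) || length(bfr) != 1L || bfr < 0 || bfr > 1)
      stopf("numeric `bfr` must be a single value in [0, 1]")
    if (is.null(affected_side))
      stopf("`affected_side` is required when `bfr` is numeric")
    bfr_affected <- bfr
  }
  affected_side <- match.arg(affected_side, c("left", "right"))
  res <- resolve_resection(resected, table)
  total_aff <- side_total_segments(affected_side, table)
  if (!is.na(res$side) && res$side != affected_side ||
      (is.character(resected) && any(res$sides != affected_side)))
    stopf("resected unit(s) on the intact side: resection must lie on the affected ('%s') side",
          affected_side)
  if (res$segments > total_aff)
    stopf("resected segment count (%d) exceeds the affected side's total (%d)",
          res$segments, total_aff)
  remaining <- total_aff - res$segments
  pre_value * ((1 - bfr_affected) + remaining / total_aff * bfr_affected)
}

#' Percent of predicted-normal value
#'
#' Expresses an absolute lung-function value as a percentage of the
#' patient's predicted-normal value (from an age/height/sex reference
#' equation). No specific reference equation is bundled; the predicted
#' normal is a required input, and which equation produced it should be
#' recorded alongside the cohort.
#'
#' @param absolute_value measured or predicted absolute value.
#' @param predicted_normal_value the patient's predicted-normal value
#'   (must be positive).
#' @return `100 * absolute_value / predicted_normal_value` (vectorised).
#' @export
percent_predicted <- function(absolute_value, predicted_normal_value) {
  if (any(!is.finite(predicted_normal_value)) ||
      any(predicted_normal_value <= 0))
    stopf("`predicted_normal_value` must be positive")
  100 * absolute_value / predicted_normal_value
}

#' Perioperative risk bands for ppo%FEV1 and ppo%DLco
#'
#' Classifies predicted postoperative percent values into the risk bands
#' used for complication stratification: ppo%FEV1 into `<40`, `40-70`,
#' `>=70`; ppo%DLco into `<40`, `40-60`, `>=60`. Boundary values belong to
#' the upper band (exactly 70 is `>=70`).
#'
#' @param ppo_pct_fev1,ppo_pct_dlco numeric vectors of percent values
#'   (either may be `NULL` to skip that classification).
#' @return a list with factors `fev1_band` and `dlco_band`.
#' @examples
#' risk_band(70, 60)  # both in the top band
#' @export
risk_band <- function(ppo_pct_fev1 = NULL, ppo_pct_dlco = NULL) {
  band <- function(x, cuts, labs) {
    if (is.null(x)) return(NULL)
    if (any(x < 0, na.rm = TRUE)) stopf("percent values must be >= 0")
    cut(x, breaks = c(-Inf, cuts, Inf), labels = labs, right = FALSE)
  }
  list(
    fev1_band = band(ppo_pct_fev1, c(40, 70), c("<40", "40-70", ">=70")),
    dlco_band = band(ppo_pct_dlco, c(40, 60), c("<40", "40-60", ">=60"))
  )
}

#' Predicted postoperative values for a whole cohort
#'
#' Applies [ppo_segment_counting()] and [ppo_perfusion()] row-wise to a
#' cohort table (see [generate_cohort()] for the column schema), producing
#' predictions for FEV1 and DLco, percent-of-predicted values, and risk
#' bands.
#'
#' @param cohort a cohort data frame with columns `pre_fev1_l`, `pre_dlco`,
#'   `predicted_normal_fev1_l`, `predicted_normal_dlco`, `affected_side`,
#'   `resected_unit`, `resected_segments`, and the BFR column named by
#'   `bfr_column`.
#' @param bfr_column name of the column carrying the affected-side BFR
#'   (default the DPDR-observed one).
#' @return the cohort with added columns `ppo_fev1_segment_l`,
#'   `ppo_fev1_perfusion_l`, `ppo_dlco_perfusion`, `ppo_pct_fev1`,
#'   `ppo_pct_dlco`, `fev1_band`, `dlco_band`.
#' @export
ppo_cohort <- function(cohort, bfr_column = "dpdr_bfr_affected") {
  need <- c("pre_fev1_l", "pre_dlco", "predicted_normal_fev1_l",
            "predicted_normal_dlco", "affected_side", "resected_segments",
            bfr_column)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  n <- nrow(cohort)
  seg <- perf_f <- perf_d <- numeric(n)
  for (i in seq_len(n)) {
    k <- cohort$resected_segments[i]
    side <- cohort$affected_side[i]
    bfr <- cohort[[bfr_column]][i]
    seg[i] <- ppo_segment_counting(cohort$pre_fev1_l[i], k)
    perf_f[i] <- ppo_perfusion(cohort$pre_fev1_l[i], bfr, k, side)
    perf_d[i] <- ppo_perfusion(cohort$pre_dlco[i], bfr, k, side)
  }
  cohort$ppo_fev1_segment_l <- seg
  cohort$ppo_fev1_perfusion_l <- perf_f
  cohort$ppo_dlco_perfusion <- perf_d
  cohort$ppo_pct_fev1 <- percent_predicted(perf_f, cohort$predicted_normal_fev1_l)
  cohort$ppo_pct_dlco <- percent_predicted(perf_d, cohort$predicted_normal_dlco)
  bands <- risk_band(cohort$ppo_pct_fev1, cohort$ppo_pct_dlco)
  cohort$fev1_band <- as.character(bands$fev1_band)
  cohort$dlco_band <- as.character(bands$dlco_band)
  cohort
}
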