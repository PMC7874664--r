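#' Parameters of the synthetic patient-cohort simulator
#'
#' Controls [generate_cohort()]. Defaults emulate a lung-cancer resection
#' cohort of the size and composition typical of a single-centre
#' prospective series: n = 52, elderly (mean age 71.7, SD 7.6), mostly
#' male, with resections distributed over the five lobectomy types
#' (right upper 18 : right middle 4 : right lower 8 : left upper 16 :
#' left lower 6, which also fixes the right/left affected-side split at
#' 30 : 22).
#'
#' Each simulated patient carries a *true* affected-side blood-flow ratio
#' centred on that side's segment share of 19; the DPDR-observed and
#' scintigraphy-comparator BFRs are the truth plus independent Gaussian
#' noise. Measured postoperative values are the perfusion-weighted
#' prediction computed from the true BFR, times `1 + ` Gaussian relative
#' error. Respiratory complications follow a logistic model in ppo%DLco
#' (probability decreasing with better predicted function); cardiovascular
#' complications are an independent Bernoulli draw.
#'
#' @param n_patients number of patients (>= 2).
#' @param mean_age,sd_age age distribution (years), truncated to 53-83.
#' @param prop_male proportion of male patients.
#' @param resection_weights named nonnegative weights over the five
#'   resection types `right_upper`, `right_middle`, `right_lower`,
#'   `left_upper`, `left_lower`.
#' @param predicted_normal_fev1_mean_l,predicted_normal_fev1_sd_l
#'   predicted-normal FEV1 distribution (litres).
#' @param pct_fev1_mean,pct_fev1_sd preoperative percent-of-normal FEV1
#'   distribution (%), truncated to 40-120.
#' @param predicted_normal_dlco_mean,predicted_normal_dlco_sd
#'   predicted-normal DLco distribution (mL/min/mmHg).
#' @param pct_dlco_mean,pct_dlco_sd preoperative %DLco distribution (%),
#'   truncated to 35-130.
#' @param bfr_spread_sd SD of the true BFR around the affected side's
#'   segment share (dimensionless, truncated to 0.15-0.70).
#' @param bfr_noise_sd SD of the DPDR observation noise on the BFR.
#' @param pps_noise_sd SD of the independent scintigraphy-comparator noise.
#' @param measurement_rel_sd_fev1,measurement_rel_sd_dlco relative SD of the
#'   spirometry/diffusion measurement error on postoperative values.
#' @param complication_intercept,complication_slope logistic model for the
#'   respiratory-complication probability:
#'   `logit(p) = intercept + slope * ppo%DLco` (slope < 0, so poorer
#'   predicted function means more complications).
#' @param cardio_rate probability of a cardiovascular complication.
#' @param rng_seed integer seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 52L,
                          mean_age = 71.7, sd_age = 7.6,
                          prop_male = 40 / 52,
                          resection_weights = c(right_upper = 18, right_middle = 4,
                                                right_lower = 8, left_upper = 16,
                                                left_lower = 6),
                          predicted_normal_fev1_mean_l = 2.8,
                          predicted_normal_fev1_sd_l = 0.55,
                          pct_fev1_mean = 80, pct_fev1_sd = 15,
                          predicted_normal_dlco_mean = 17,
                          predicted_normal_dlco_sd = 3,
                          pct_dlco_mean = 75, pct_dlco_sd = 18,
                          bfr_spread_sd = 0.04,
                          bfr_noise_sd = 0.03,
                          pps_noise_sd = 0.03,
                          measurement_rel_sd_fev1 = 0.10,
                          measurement_rel_sd_dlco = 0.10,
                          complication_intercept = 1.75,
                          complication_slope = -0.05,
                          cardio_rate = 0.115,
                          rng_seed = 1L) {
  p <- as.list(environment())
  class(p) <- "cohort_params"
  if (!is_count(p$n_patients) || p$n_patients < 2L)
    stopf("n_patients must be an integer >= 2")
  sds <- c(p$sd_age, p$predicted_normal_fev1_sd_l, p$pct_fev1_sd,
           p$predicted_normal_dlco_sd, p$pct_dlco_sd, p$bfr_spread_sd,
           p$bfr_noise_sd, p$pps_noise_sd, p$measurement_rel_sd_fev1,
           p$measurement_rel_sd_dlco)
  if (any(sds < 0)) stopf("all noise/spread SDs must be >= 0")
  expected <- c("right_upper", "right_middle", "right_lower",
                "left_upper", "left_lower")
  if (!setequal(names(p$resection_weights), expected) ||
      any(p$resection_weights < 0) || sum(p$resection_weights) <= 0)
    stopf("resection_weights must be nonnegative weights named %s",
          paste(expected, collapse = ", "))
  if (p$complication_slope > 0)
    stopf("complication_slope must be <= 0 (risk decreases with better predicted function)")
  if (p$cardio_rate < 0 || p$cardio_rate > 1) stopf("cardio_rate must be in [0, 1]")
  p$n_patients <- as.integer(p$n_patients)
  p
}

# segment counts removed by each resection type (left_upper = division + lingula)
RESECTION_SEGMENTS <- c(right_upper = 3L, right_middle = 2L, right_lower = 5L,
                        left_upper = 5L, left_lower = 4L)
RESECTION_SIDE <- c(right_upper = "right", right_middle = "right",
                    right_lower = "right", left_upper = "left",
                    left_lower = "left")

#' Generate a synthetic patient cohort
#'
#' Draws a cohort of lung-resection patients with known prediction-error
#' structure (see [cohort_params()] for the generative model). Deterministic
#' under a fixed seed: two calls with the same parameters yield identical
#' cohorts, and the CSV serialisation via [write_cohort()] is
#' byte-for-byte reproducible.
#'
#' @param params a [cohort_params()] object.
#' @return a data frame, one row per patient, with columns: `id`, `age`,
#'   `sex`, `height_cm`, `affected_side`, `resected_unit`,
#'   `resected_segments`, `true_bfr_affected`, `dpdr_bfr_affected`,
#'   `pps_bfr_affected`, `predicted_normal_fev1_l`, `pre_fev1_l`,
#'   `predicted_normal_dlco`, `pre_dlco`, `measured_fev1_m1_l`,
#'   `measured_fev1_m3_l`, `measured_dlco_m1`, `measured_dlco_m3`,
#'   `complication_respiratory`, `complication_cardiovascular`,
#'   `complication_any`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  with_seed(params$rng_seed, {
    rtrunc <- function(n, mean, sd, lo, hi) clamp(rnorm(n, mean, sd), lo, hi)

    sex <- ifelse(runif(n) < params$prop_male, "male", "female")
    age <- round(rtrunc(n, params$mean_age, params$sd_age, 53, 83))
    height <- ifelse(sex == "male", rnorm(n, 165, 6), rnorm(n, 152, 6))

    unit <- sample(names(params$resection_weights), n, replace = TRUE,
                   prob = params$resection_weights / sum(params$resection_weights))
    side <- unname(RESECTION_SIDE[unit])
    resected_segments <- unname(RESECTION_SEGMENTS[unit])
    share <- ifelse(side == "right", 10 / 19, 9 / 19)

    true_bfr <- rtrunc(n, share, params$bfr_spread_sd, 0.15, 0.70)
    dpdr_bfr <- clamp(true_bfr + rnorm(n, 0, params$bfr_noise_sd), 0, 1)
    pps_bfr <- clamp(true_bfr + rnorm(n, 0, params$pps_noise_sd), 0, 1)

    pn_fev1 <- rtrunc(n, params$predicted_normal_fev1_mean_l,
                      params$predicted_normal_fev1_sd_l, 1.2, 4.5)
    pre_fev1 <- pn_fev1 * rtrunc(n, params$pct_fev1_mean, params$pct_fev1_sd,
                                 40, 120) / 100
    pn_dlco <- rtrunc(n, params$predicted_normal_dlco_mean,
                      params$predicted_normal_dlco_sd, 8, 28)
    pre_dlco <- pn_dlco * rtrunc(n, params$pct_dlco_mean, params$pct_dlco_sd,
                                 35, 130) / 100

    ppo_fev1_true <- ppo_dlco_true <- numeric(n)
    for (i in seq_len(n)) {
      ppo_fev1_true[i] <- ppo_perfusion(pre_fev1[i], true_bfr[i],
                                        resected_segments[i], side[i])
      ppo_dlco_true[i] <- ppo_perfusion(pre_dlco[i], true_bfr[i],
                                        resected_segments[i], side[i])
    }
    meas <- function(truth, rel_sd)
      pmax(truth * (1 + rnorm(n, 0, rel_sd)), 0.05)
    fev1_m1 <- meas(ppo_fev1_true, params$measurement_rel_sd_fev1)
    fev1_m3 <- meas(ppo_fev1_true, params$measurement_rel_sd_fev1)
    dlco_m1 <- meas(ppo_dlco_true, params$measurement_rel_sd_dlco)
    dlco_m3 <- meas(ppo_dlco_true, params$measurement_rel_sd_dlco)

    ppo_pct_dlco <- percent_predicted(ppo_dlco_true, pn_dlco)
    p_resp <- plogis(params$complication_intercept +
                     params$complication_slope * ppo_pct_dlco)
    resp <- rbinom(n, 1L, p_resp) == 1L
    cardio <- rbinom(n, 1L, params$cardio_rate) == 1L

    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age,
      sex = sex,
      height_cm = round(height, 1),
      affected_side = side,
      resected_unit = unit,
      resected_segments = resected_segments,
      true_bfr_affected = true_bfr,
      dpdr_bfr_affected = dpdr_bfr,
      pps_bfr_affected = pps_bfr,
      predicted_normal_fev1_l = pn_fev1,
      pre_fev1_l = pre_fev1,
      predicted_normal_dlco = pn_dlco,
      pre_dlco = pre_dlco,
      measured_fev1_m1_l = fev1_m1,
      measured_fev1_m3_l = fev1_m3,
      measured_dlco_m1 = dlco_m1,
      measured_dlco_m3 = dlco_m3,
      complication_respiratory = resp,
      complication_cardiovascular = cardio,
      complication_any = resp | cardio,
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal separator; one row per
#' patient. Writing is deterministic: the same data frame always produces
#' byte-identical output.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
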