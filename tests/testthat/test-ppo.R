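test_that("segment counting reproduces the worked arithmetic", {
  expect_equal(ppo_segment_counting(1.9, "right_upper"), 1.9 * 16 / 19)
  expect_equal(ppo_segment_counting(1.9, "right_upper"), 1.6)
  expect_equal(ppo_segment_counting(19, "left_lower"), 15)
  expect_equal(ppo_segment_counting(2.0, 5), 2.0 * 14 / 19)  # numeric count
  # zero-segment identity only via the explicit flag
  expect_error(ppo_segment_counting(2.0, 0), "allow_zero")
  expect_equal(ppo_segment_counting(2.0, 0, allow_zero = TRUE), 2.0)
  expect_error(ppo_segment_counting(2.0, "right_hilum"), "valid units")
  expect_error(ppo_segment_counting(-1, "right_upper"), "positive")
  expect_error(ppo_segment_counting(2.0, 19), "below")
})

test_that("the perfusion formula reduces to segment counting at the segment-share BFR", {
  pre <- 2.37
  lobes <- list(right_upper = "right", right_middle = "right",
                right_lower = "right", left_upper = "left",
                left_lower = "left")
  for (lobe in names(lobes)) {
    side <- lobes[[lobe]]
    share <- if (side == "right") 10 / 19 else 9 / 19
    expect_equal(ppo_perfusion(pre, share, lobe, side),
                 ppo_segment_counting(pre, lobe),
                 tolerance = 1e-15)
  }
  # the identity also holds for the sub-lobar left units
  for (u in c("left_upper_division", "lingula")) {
    expect_equal(ppo_perfusion(pre, 9 / 19, u, "left"),
                 ppo_segment_counting(pre, u), tolerance = 1e-15)
  }
})

test_that("perfusion-weighted prediction handles degenerate and worked cases", {
  # affected lung contributing nothing: prediction is the intact share alone
  expect_equal(ppo_perfusion(2.4, 0, "left_lower", "left"), 2.4)
  # worked example: right lower lobectomy (5 of 10), BFR 0.5
  expect_equal(ppo_perfusion(2.0, 0.5, "right_lower", "right"), 1.5)
  # bfr_result objects carry the affected side
  sums <- structure(list(sum_max_ccv_left = 30, sum_max_ccv_right = 70,
                         n_pixels_left = 5, n_pixels_right = 5),
                    class = "lung_field_sums")
  bfr <- blood_flow_ratio(sums, "left")
  expect_equal(ppo_perfusion(2.0, bfr, "left_lower", table = lung_segment_table()),
               2.0 * (0.7 + 5 / 9 * 0.3))
  expect_error(ppo_perfusion(2.0, 0.5, "right_upper", "left"), "intact side")
  expect_error(ppo_perfusion(2.0, 1.5, "right_upper", "right"), "\\[0, 1\\]")
  expect_error(ppo_perfusion(2.0, 0.5, 11, "right"), "exceeds")
})

test_that("prediction is linear in the preoperative value and bounded by it", {
  for (bfr in c(0.2, 0.5, 0.8)) {
    p1 <- ppo_perfusion(1, bfr, "left_upper", "left")
    expect_equal(ppo_perfusion(3.7, bfr, "left_upper", "left"), 3.7 * p1,
                 tolerance = 1e-12)
    expect_lte(p1, 1)
  }
  # monotone: shifting perfusion toward the intact side raises the prediction
  ladder <- sapply(seq(0, 1, by = 0.1), function(b)
    ppo_perfusion(2.5, b, "right_lower", "right"))
  expect_true(all(diff(ladder) < 0))  # decreasing in bfr_affected
  # equality with pre only when the affected side contributes nothing
  expect_equal(ppo_perfusion(2.5, 0, "right_lower", "right"), 2.5)
  expect_lt(ppo_perfusion(2.5, 0.3, "right_lower", "right"), 2.5)
})

test_that("percent-of-predicted arithmetic and validation", {
  expect_equal(percent_predicted(2.5, 2.5), 100)
  expect_equal(percent_predicted(0, 2.5), 0)
  expect_equal(percent_predicted(1.6, 2.5), 64)
  expect_error(percent_predicted(1.6, 0), "positive")
})

test_that("risk-band boundaries belong to the upper band", {
  b <- risk_band(c(39.9, 40, 55, 69.99, 70, 90),
                 c(39.9, 40, 50, 59.99, 60, 80))
  expect_equal(as.character(b$fev1_band),
               c("<40", "40-70", "40-70", "40-70", ">=70", ">=70"))
  expect_equal(as.character(b$dlco_band),
               c("<40", "40-60", "40-60", "40-60", ">=60", ">=60"))
  expect_error(risk_band(-5, 50), ">= 0")
})

test_that("cohort-level prediction adds the documented columns", {
  co <- ppo_cohort(generate_cohort(cohort_params(n_patients = 12, rng_seed = 2)))
  expect_true(all(c("ppo_fev1_segment_l", "ppo_fev1_perfusion_l",
                    "ppo_dlco_perfusion", "ppo_pct_fev1", "ppo_pct_dlco",
                    "fev1_band", "dlco_band") %in% names(co)))
  expect_true(all(co$ppo_fev1_perfusion_l <= co$pre_fev1_l + 1e-12))
  expect_error(ppo_cohort(data.frame(x = 1)), "missing column")
})
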