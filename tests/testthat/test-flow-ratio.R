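# build a perfusion_map object around an arbitrary max_ccv matrix
fake_map <- function(max_ccv) {
  structure(list(max_ccv = max_ccv, ccv = NULL,
                 undefined = matrix(FALSE, nrow(max_ccv), ncol(max_ccv)),
                 valid_frames = 1:10, window_frames = 11,
                 cardiac_freq_hz_est = 1.25),
            class = "perfusion_map")
}

square_masks <- function(n = 16) {
  right <- left <- vent <- matrix(FALSE, n, n)
  right[3:(n - 2), 2:6] <- TRUE
  left[3:(n - 2), (n - 5):(n - 1)] <- TRUE
  vent[(n - 4):(n - 3), 7:8] <- TRUE
  anatomy_masks(right, left, vent)
}

test_that("per-lung sums match constant maps and a brute-force loop", {
  m <- square_masks()
  n_side <- sum(m$left_lung)
  ones <- fake_map(matrix(1, 16, 16))
  s <- sum_max_ccv(ones, m)
  expect_equal(s$sum_max_ccv_left, n_side)
  expect_equal(s$sum_max_ccv_right, n_side)
  expect_equal(s$n_pixels_left, n_side)

  zeros <- fake_map(matrix(0, 16, 16))
  s0 <- sum_max_ccv(zeros, m)
  expect_equal(s0$sum_max_ccv_left, 0)
  expect_equal(s0$sum_max_ccv_right, 0)

  set.seed(2)
  mv <- matrix(rnorm(256), 16, 16)
  mv[1, 1:4] <- NA  # outside the lungs anyway
  s2 <- sum_max_ccv(fake_map(mv), m)
  brute_l <- 0
  for (i in 1:16) for (j in 1:16)
    if (m$left_lung[i, j] && !is.na(mv[i, j])) brute_l <- brute_l + mv[i, j]
  expect_equal(s2$sum_max_ccv_left, brute_l, tolerance = 1e-12)
})

test_that("undefined pixels are excluded from sums and counts", {
  m <- square_masks()
  mv <- matrix(1, 16, 16)
  holes <- which(m$left_lung)[1:3]
  mv[holes] <- NA
  s <- sum_max_ccv(fake_map(mv), m)
  expect_equal(s$n_pixels_left, sum(m$left_lung) - 3)
  expect_equal(s$sum_max_ccv_left, sum(m$left_lung) - 3)
})

test_that("negative values are kept by default and floored with clip_negative", {
  m <- square_masks()
  mv <- matrix(0, 16, 16)
  mv[m$left_lung] <- -0.2
  mv[m$right_lung] <- 0.8
  s <- sum_max_ccv(fake_map(mv), m)
  expect_equal(s$sum_max_ccv_left, -0.2 * sum(m$left_lung))
  sc <- sum_max_ccv(fake_map(mv), m, clip_negative = TRUE)
  expect_equal(sc$sum_max_ccv_left, 0)
})

test_that("BFR arithmetic, symmetry and scale invariance hold", {
  mk <- function(l, r) structure(list(sum_max_ccv_left = l, sum_max_ccv_right = r,
                                      n_pixels_left = 10, n_pixels_right = 10),
                                 class = "lung_field_sums")
  expect_equal(blood_flow_ratio(mk(30, 70), "left")$bfr_affected, 0.30)
  expect_equal(blood_flow_ratio(mk(30, 70), "right")$bfr_affected, 0.70)
  expect_equal(blood_flow_ratio(mk(55, 55), "left")$bfr_affected, 0.5)
  # affected-left and affected-right views of the same sums sum to 1
  bl <- blood_flow_ratio(mk(33, 77), "left")
  br <- blood_flow_ratio(mk(33, 77), "right")
  expect_equal(bl$bfr_affected + br$bfr_affected, 1, tolerance = 1e-15)
  expect_equal(bl$bfr_affected + bl$bfr_intact, 1, tolerance = 1e-15)
  # uniform scaling of the map leaves BFR unchanged
  expect_equal(blood_flow_ratio(mk(3.3, 7.7), "left")$bfr_affected,
               blood_flow_ratio(mk(33, 77), "left")$bfr_affected,
               tolerance = 1e-12)
  expect_error(blood_flow_ratio(mk(0, 0), "left"), "no perfusion signal")
})

test_that("an empty lung mask is rejected", {
  m <- square_masks()
  no_right <- anatomy_masks(matrix(FALSE, 16, 16), m$left_lung, m$ventricle_roi)
  expect_error(sum_max_ccv(fake_map(matrix(1, 16, 16)), no_right), "nonempty")
})

test_that("left:right amplitude asymmetry is recovered as BFR below 0.5, monotonically", {
  bfr_at <- function(ratio, seed) {
    sim <- generate_sequence(synth_imaging_params(
      image_height_px = 32, image_width_px = 32, n_frames = 150,
      noise_sd = 80, resp_amplitude = 0,
      perfusion_amplitude_left = 200 * ratio,
      perfusion_amplitude_right = 200, rng_seed = seed))
    cs <- extract_ventricle_signal(sim$sequence, sim$masks)
    map <- compute_ccv(sim$sequence, cs, sim$masks, store_ccv = FALSE)
    blood_flow_ratio(sum_max_ccv(map, sim$masks), "left")$bfr_affected
  }
  ratios <- c(1, 0.7, 0.4)
  bfrs <- sapply(ratios, function(rt) mean(sapply(101:103, bfr_at, ratio = rt)))
  expect_lt(bfrs[2], 0.5)
  expect_true(all(diff(bfrs) < 0))
})
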