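test_that("the cardiac period is recovered from the spectral peak", {
  sim <- generate_sequence(tiny_params(cardiac_freq_hz = 1.25, n_frames = 150))
  cs <- extract_ventricle_signal(sim$sequence, sim$masks)
  expect_identical(cs$estimated_period_frames, 12L)  # 15 fps / 1.25 Hz
  expect_lt(abs(mean(cs$pc_lv)), 1e-9 * sd(cs$pc_lv) + 1e-12)

  sim2 <- generate_sequence(tiny_params(cardiac_freq_hz = 1.5, n_frames = 150))
  cs2 <- extract_ventricle_signal(sim2$sequence, sim2$masks)
  expect_identical(cs2$estimated_period_frames, 10L)
})

test_that("the noiseless reference equals the generator's ventricle waveform", {
  # 2.5 Hz sits deep in the filter pass band, so amplitude error is tiny
  p <- tiny_params(noise_sd = 0, resp_amplitude = 0, cardiac_freq_hz = 2.5,
                   n_frames = 150)
  sim <- generate_sequence(p)
  cs <- extract_ventricle_signal(sim$sequence, sim$masks)
  truth <- sim$truth$waveforms$ventricle - mean(sim$truth$waveforms$ventricle)
  # compare away from the edges, where the zero-phase filter's finite-length
  # transients live (about one settling length, ~15 frames, per side)
  mid <- 16:135
  rel_rms <- sqrt(mean((cs$pc_lv[mid] - truth[mid])^2)) / sqrt(mean(truth[mid]^2))
  expect_lt(rel_rms, 0.05)
  expect_gt(stats::cor(cs$pc_lv[mid], truth[mid]), 0.999)
})

test_that("degenerate ventricle signals raise a no-cardiac-component error", {
  h <- 32; w <- 32
  m <- default_anatomy_masks(h, w, 3.3)
  const_seq <- frame_sequence(array(30000, c(h, w, 100)), 15, 3.3, 58000)
  expect_error(extract_ventricle_signal(const_seq, m), "no cardiac component")
  set.seed(4)
  noise_seq <- frame_sequence(array(30000 + rnorm(h * w * 100, sd = 50),
                                    c(h, w, 100)), 15, 3.3, 58000)
  expect_error(extract_ventricle_signal(noise_seq, m), "no cardiac component")
})

test_that("perfect anti-phase pixels give CCv 1 and in-phase pixels give -1", {
  p <- tiny_params(noise_sd = 0, resp_amplitude = 0)
  sim <- generate_sequence(p)
  # flip the left lung into phase with the ventricle (perfusion signal is
  # generated in anti-phase, so unmodified pixels correlate at +1)
  px <- sim$sequence$pixels
  base <- p$baseline_level
  for (t in seq_len(dim(px)[3])) {
    fr <- px[, , t]
    fr[sim$masks$left_lung] <- 2 * base - fr[sim$masks$left_lung]
    px[, , t] <- fr
  }
  seq2 <- frame_sequence(px, 15, p$pixel_spacing_mm, p$saturation_level)
  cs <- extract_ventricle_signal(seq2, sim$masks)
  map <- compute_ccv(seq2, cs, sim$masks)
  right_vals <- apply(map$ccv, 3, function(fr) fr[sim$masks$right_lung])
  left_vals <- apply(map$ccv, 3, function(fr) fr[sim$masks$left_lung])
  expect_true(all(abs(right_vals - 1) < 1e-9))
  expect_true(all(abs(left_vals + 1) < 1e-9))
  expect_true(all(abs(map$max_ccv[sim$masks$right_lung] - 1) < 1e-9))
  expect_true(all(abs(map$max_ccv[sim$masks$left_lung] + 1) < 1e-9))
})

test_that("CCv is invariant to per-pixel affine rescaling", {
  p <- tiny_params(rng_seed = 6)
  sim <- generate_sequence(p)
  cs <- extract_ventricle_signal(sim$sequence, sim$masks)
  map1 <- compute_ccv(sim$sequence, cs, sim$masks)
  px <- sim$sequence$pixels * 0.25 + 5000  # gain + offset, applied globally
  seq2 <- frame_sequence(px, 15, p$pixel_spacing_mm, p$saturation_level)
  map2 <- compute_ccv(seq2, cs, sim$masks)
  expect_equal(map1$ccv, map2$ccv, tolerance = 1e-9)
})

test_that("all defined CCv values lie in [-1, 1] for random inputs", {
  for (s in 1:4) {
    sim <- generate_sequence(tiny_params(rng_seed = s, noise_sd = 200,
                                         resp_amplitude = 40))
    cs <- extract_ventricle_signal(sim$sequence, sim$masks)
    map <- compute_ccv(sim$sequence, cs, sim$masks)
    v <- map$ccv[!is.na(map$ccv)]
    expect_gte(min(v), -1)
    expect_lte(max(v), 1)
  }
})

test_that("zero-variance and saturated pixels are flagged undefined, not fatal", {
  p <- tiny_params(noise_sd = 10)
  sim <- generate_sequence(p)
  px <- sim$sequence$pixels
  dead <- which(sim$masks$left_lung)[1]
  sat <- which(sim$masks$left_lung)[2]
  ij_dead <- arrayInd(dead, dim(px)[1:2])
  ij_sat <- arrayInd(sat, dim(px)[1:2])
  px[ij_dead[1], ij_dead[2], ] <- 12000                      # constant pixel
  px[ij_sat[1], ij_sat[2], ] <- p$saturation_level           # saturated pixel
  seq2 <- frame_sequence(px, 15, p$pixel_spacing_mm, p$saturation_level)
  cs <- extract_ventricle_signal(seq2, sim$masks)
  map <- compute_ccv(seq2, cs, sim$masks)
  expect_true(map$undefined[ij_dead[1], ij_dead[2]])
  expect_true(map$undefined[ij_sat[1], ij_sat[2]])
  expect_true(is.na(map$max_ccv[ij_dead[1], ij_dead[2]]))
  expect_true(is.na(map$max_ccv[ij_sat[1], ij_sat[2]]))
  # other pixels unaffected
  expect_gt(sum(!is.na(map$max_ccv)), 100)
})

test_that("geometry and window preconditions are enforced", {
  sim <- generate_sequence(tiny_params())
  cs <- extract_ventricle_signal(sim$sequence, sim$masks)
  expect_error(compute_ccv(sim$sequence, cs, sim$masks, window_frames = 61),
               "does not fit")
  no_left <- anatomy_masks(right_lung = sim$masks$right_lung,
                           left_lung = matrix(FALSE, 16, 16),
                           ventricle_roi = sim$masks$ventricle_roi)
  expect_error(compute_ccv(sim$sequence, cs, no_left), "nonempty")
})

test_that("expected MaxCCv rises monotonically with cardiac amplitude", {
  amps <- c(50, 100, 200, 400)
  means <- sapply(amps, function(a) {
    sim <- generate_sequence(synth_imaging_params(
      image_height_px = 24, image_width_px = 24, n_frames = 150,
      noise_sd = 100, resp_amplitude = 0,
      perfusion_amplitude_left = a, perfusion_amplitude_right = a,
      rng_seed = 31))
    cs <- extract_ventricle_signal(sim$sequence, sim$masks)
    map <- compute_ccv(sim$sequence, cs, sim$masks, store_ccv = FALSE)
    mean(map$max_ccv, na.rm = TRUE)  # > 200 lung pixels as replicates
  })
  expect_true(all(diff(means) > 0))
})
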