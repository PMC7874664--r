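test_that("an exact linear relation yields r = 1 with the generating line", {
  x <- 1:10
  pr <- pearson_regression(x, 2 * x + 1)
  expect_equal(pr$r, 1, tolerance = 1e-12)
  expect_equal(pr$slope, 2, tolerance = 1e-12)
  expect_equal(pr$intercept, 1, tolerance = 1e-12)
  # null case: independent y
  set.seed(10)
  pr0 <- pearson_regression(rnorm(5000), rnorm(5000))
  expect_lt(abs(pr0$r), 0.05)
  expect_error(pearson_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_regression(1:2, 1:2), "at least 3")
})

test_that("correlation and regression match the direct-formula oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_regression(x, y)
    want <- pearson_oracle(x, y)
    for (f in c("r", "slope", "intercept", "r_squared", "p_value"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    # r is symmetric under exchanging x and y
    expect_equal(pearson_regression(y, x)$r, got$r, tolerance = 1e-12)
  }
})

test_that("Bland-Altman handles identity, constant offset and random data", {
  a <- c(1.4, 2.2, 3.8, 4.1, 5.5)
  ba <- bland_altman(a, a)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 0)
  expect_equal(ba$pct_within_2sd, 100)

  ba2 <- bland_altman(a, a - 0.75)
  expect_equal(ba2$mean_difference, 0.75, tolerance = 1e-12)
  expect_equal(ba2$sd_difference, 0, tolerance = 1e-12)

  for (s in 1:3) {
    set.seed(100 + s)
    x <- rnorm(6, 50, 10); y <- x + rnorm(6, 1, 2)
    got <- bland_altman(x, y)
    want <- bland_altman_oracle(x, y)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    expect_lte(got$loa_low, got$mean_difference)
    expect_gte(got$loa_high, got$mean_difference)
  }
  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("the unpaired t test matches the pooled-variance formula and conventions", {
  tt <- unpaired_t_test(c(3, 3, 3), c(3, 3, 3, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  # clear separation with tiny jitter
  set.seed(1)
  tt2 <- unpaired_t_test(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6))
  expect_lt(tt2$p_value, 0.001)
  # zero variance with unequal means: infinite evidence
  tt3 <- unpaired_t_test(c(2, 2), c(5, 5))
  expect_true(is.infinite(tt3$t))
  expect_equal(tt3$p_value, 0)
  for (s in 1:4) {
    set.seed(200 + s)
    a <- rnorm(5, 1); b <- rnorm(7, 1.4)
    got <- unpaired_t_test(a, b)
    want <- t_test_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  expect_error(unpaired_t_test(1, c(2, 3)), "at least 2")
})

test_that("complication rate tables report per-band and overall percentages", {
  bands <- c(rep("<40", 4), rep("40-60", 8), rep(">=60", 11))
  events <- c(rep(TRUE, 2), rep(FALSE, 2),
              rep(TRUE, 2), rep(FALSE, 6),
              rep(TRUE, 2), rep(FALSE, 9))
  rt <- as.data.frame(complication_rates(bands, events))
  expect_equal(rt$rate_pct[rt$band == "<40"], 50)
  expect_equal(rt$rate_pct[rt$band == "40-60"], 25)
  expect_equal(rt$rate_pct[rt$band == ">=60"], 100 * 2 / 11, tolerance = 1e-12)
  expect_equal(rt$n[rt$band == "overall"], 23)
  # zero events in a band give 0.0%, an empty band is absent
  rt2 <- as.data.frame(complication_rates(factor(rep("a", 5), levels = c("a", "b")),
                                          rep(FALSE, 5)))
  expect_equal(rt2$rate_pct[rt2$band == "a"], 0)
  expect_false("b" %in% rt2$band)
  expect_error(complication_rates(bands, events[-1]), "equal length")
})

test_that("cohort agreement battery runs end to end on a predicted cohort", {
  co <- ppo_cohort(generate_cohort(cohort_params(n_patients = 40, rng_seed = 17)))
  rep_ <- cohort_agreement(co)
  expect_true(all(c("bfr_methods", "predicted_vs_measured_fev1_m1",
                    "complication_summary") %in% names(rep_)))
  expect_gt(rep_$predicted_vs_measured_fev1_m1$r, 0.5)
  expect_lte(abs(rep_$bfr_methods$pearson$r), 1)
  ba <- rep_$bfr_methods$bland_altman
  expect_lte(ba$loa_low, ba$mean_difference)
  expect_gte(ba$pct_within_2sd, 0)
})
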