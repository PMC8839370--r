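test_that("stride counts follow the walk arithmetic and scale with duration", {
  w <- generate_walk(walk_spec(rng_seed = 1L))
  n_l <- length(w$ground_truth$foot_contacts$left) - 1
  # (120 - 2x5 s bookends, minus edge margins) / 1.2 s per stride
  expect_true(abs(n_l - 91) <= 2)
  n_r <- length(w$ground_truth$foot_contacts$right) - 1
  expect_lte(abs(n_l - n_r), 1)

  w2 <- generate_walk(walk_spec(duration_s = 240, rng_seed = 1L))
  n2 <- length(w2$ground_truth$foot_contacts$left) - 1
  expect_lt(abs(n2 / n_l - (240 - 10) / (120 - 10)), 0.07)
})

test_that("the same seed reproduces bit-identical recordings", {
  a <- generate_walk(walk_spec(rng_seed = 42L))
  b <- generate_walk(walk_spec(rng_seed = 42L))
  expect_identical(a$recording$streams$left_foot$accel,
                   b$recording$streams$left_foot$accel)
  expect_identical(a$recording$streams$low_back$gyro,
                   b$recording$streams$low_back$gyro)
  expect_identical(a$ground_truth$foot_contacts, b$ground_truth$foot_contacts)
})

test_that("noise-free, bias-free stance phases carry exactly zero angular velocity", {
  spec <- walk_spec(noise_sd_accel = 0, noise_sd_gyro = 0,
                    gyro_bias = list(left_foot = c(0, 0, 0),
                                     right_foot = c(0, 0, 0),
                                     low_back = c(0, 0, 0)),
                    rng_seed = 2L)
  w <- generate_walk(spec)
  gy <- w$recording$streams$left_foot$gyro
  fs <- spec$sample_rate_hz
  for (k in seq_len(nrow(w$ground_truth$stance_intervals$left))) {
    iv <- w$ground_truth$stance_intervals$left[k, ]
    idx <- (floor(iv[1] * fs) + 2):(ceiling(iv[2] * fs) - 1)
    expect_identical(max(abs(gy[idx, ])), 0)
  }
})

test_that("every ground-truth contact sits on a local maximum of vertical foot acceleration", {
  spec <- walk_spec(noise_sd_accel = 0, rng_seed = 3L)
  w <- generate_walk(spec)
  fs <- spec$sample_rate_hz
  for (foot in c("left", "right")) {
    vt <- w$recording$streams[[paste0(foot, "_foot")]]$accel[, 3]
    ok <- vapply(w$ground_truth$foot_contacts[[foot]], function(tc) {
      i <- round(tc * fs) + 1
      which.max(vt[(i - 3):(i + 3)]) %in% 3:5
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("invalid walk specifications are rejected naming the field", {
  expect_error(walk_spec(stance_fraction = 1.2), "stance_fraction",
               class = "gaitreliab_validation_error")
  expect_error(walk_spec(duration_s = 8, standstill_bookend_s = 5),
               "duration_s", class = "gaitreliab_validation_error")
  expect_error(walk_spec(noise_sd_accel = -1), "noise_sd_accel",
               class = "gaitreliab_validation_error")
  expect_error(walk_spec(stride_time_mean_s = c(left = 1.0, right = 2.0)),
               "stride_time_mean_s", class = "gaitreliab_validation_error")
})

test_that("cohort generation carries the analytic ICC of its variance components", {
  m <- generate_cohort(cohort_spec(10, between_subject_sd = 1,
                                   within_subject_sd = 0))
  expect_identical(attr(m, "analytic_icc"), 1)
  m <- generate_cohort(cohort_spec(10, between_subject_sd = 1,
                                   within_subject_sd = 1))
  expect_identical(attr(m, "analytic_icc"), 0.5)
  expect_error(cohort_spec(10, between_subject_sd = -1),
               class = "gaitreliab_validation_error")
  expect_error(cohort_spec(1), class = "gaitreliab_validation_error")
  expect_error(cohort_spec(10, between_subject_sd = 0,
                           within_subject_sd = 0),
               class = "gaitreliab_validation_error")
})

test_that("empirical cohort ICC tracks the analytic value", {
  # n = 29, between 1.0, within 0.5: analytic ICC = 0.8
  est <- vapply(1:200, function(s) {
    m <- generate_cohort(cohort_spec(29, between_subject_sd = 1,
                                     within_subject_sd = 0.5,
                                     rng_seed = s))
    icc21(m)$icc
  }, 0)
  expect_lt(abs(mean(est) - 0.8), 0.15)
})
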