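test_that("the catalogue holds exactly 166 uniquely named features with the printed counts", {
  cat <- feature_catalogue()
  expect_identical(nrow(cat), 166L)
  expect_identical(anyDuplicated(cat$name), 0L)
  counts <- table(cat$domain)
  expect_identical(counts[["spatio_temporal"]], 56L)
  expect_identical(counts[["frequency"]], 26L)
  expect_identical(counts[["complexity"]], 63L)
  expect_identical(counts[["asymmetry"]], 14L)
  by_src <- table(cat$source)
  expect_identical(by_src[["left_foot"]], 46L)
  expect_identical(by_src[["right_foot"]], 46L)
  expect_identical(by_src[["low_back"]], 54L)
  expect_identical(by_src[["combined"]], 20L)
})

test_that("per-10-stride blocking drops the partial final block", {
  x <- c(rep(1, 10), rep(3, 10), rep(100, 5))   # 25 strides -> 2 blocks
  bs <- gaitreliab:::block_stats(x, 10)
  expect_identical(bs$blocks, 2L)
  expect_identical(bs$mean, 2)                  # last 5 strides unused
  expect_identical(bs$sd, 0)
  bs2 <- gaitreliab:::block_stats(x[1:9], 10)
  expect_identical(bs2$blocks, 0L)
  expect_true(is.na(bs2$mean))
})

test_that("regular events yield the textbook spatio-temporal values", {
  evL <- regular_events(offset = 1L, foot = "left")        # 1.2 s strides
  evR <- regular_events(offset = 61L, foot = "right")
  dL <- regular_disp(evL, 1.3); dR <- regular_disp(evR, 1.3)
  st <- spatio_temporal_features(evL, evR, dL, dR, NULL,
                                 list(height_m = 1.8,
                                      paretic_side = "left"), 100)
  expect_equal(st$left_foot_stride_time_mean, 1.2)
  expect_equal(st$left_foot_cadence, 100)            # 2 steps per 1.2 s
  expect_equal(st$left_foot_stride_length_mean, 1.3)
  expect_equal(st$left_foot_stride_length_norm, 1.3 / 1.8) # 0.7222
  expect_equal(st$left_foot_stance_time_mean, 0.72)
  expect_equal(st$left_foot_swing_time_mean, 0.48)
  expect_equal(st$left_foot_step_time_mean, 0.6)
  expect_equal(st$left_foot_stride_time_sd, 0)
})

test_that("too few strides yield missing features with a reason code", {
  evL <- regular_events(n_contacts = 8)
  evR <- regular_events(n_contacts = 8, offset = 61L, foot = "right")
  st <- spatio_temporal_features(evL, evR, regular_disp(evL),
                                 regular_disp(evR), NULL,
                                 list(height_m = 1.8), 100)
  expect_true(is.na(st$left_foot_stride_time_mean))
  expect_identical(attr(st, "reasons")$left_foot_stride_time_mean,
                   "insufficient_strides")
})

test_that("dominant-frequency features behave on constructed spectra", {
  fs <- 100; tt <- (0:5999) / fs
  sig1 <- sin(2 * pi * 1 * tt)
  dp <- gaitreliab:::dominant_peak_features(sig1, fs, 10)
  expect_equal(dp$dom_freq, 1, tolerance = 0.011)
  expect_gt(dp$dom_density, 0.95)
  expect_equal(dp$dom_amp, 1, tolerance = 0.05)

  sig2 <- sin(2 * pi * 1 * tt) + sin(2 * pi * 2.2 * tt)
  dp2 <- gaitreliab:::dominant_peak_features(sig2, fs, 10)
  expect_lt(abs(dp2$dom_density - 0.5), 0.05)

  expect_null(gaitreliab:::dominant_peak_features(rep(1, 6000), fs, 10))
})

test_that("walk frequency features recover the step and stride rates", {
  fv <- fixture_features()
  v <- stats::setNames(fv$value, fv$name)
  expect_lt(abs(v[["lb_vt_dom_freq"]] - 2 / 1.2), 0.06)   # step frequency
  expect_lt(abs(v[["lb_ml_dom_freq"]] - 1 / 1.2), 0.06)   # stride frequency
  expect_lt(abs(v[["left_foot_vt_dom_freq"]] - 1 / 1.2), 0.06)
  expect_gt(v[["lb_vt_harmonicity"]], 0.9)  # near-sinusoidal VT component
})

test_that("entropies match naive quadratic-time oracles to 1e-8", {
  set.seed(77)
  fixtures <- list(
    sin(2 * pi * (0:299) / 25) + 0.2 * rnorm(300),
    rnorm(300),
    as.numeric(stats::arima.sim(list(ar = 0.8), 300)))
  for (x in fixtures) {
    r <- 0.2 * sd(x)
    expect_lt(abs(sample_entropy(x, 2L, r) - sampen_naive(x, 2, r)), 1e-8)
    expect_lt(abs(approx_entropy(x, 2L, r) - apen_naive(x, 2, r)), 1e-8)
  }
})

test_that("complexity statistics separate regular from irregular signals", {
  # an exactly repeating pattern of well-separated levels: the only
  # template matches are at multiples of the period, so entropy -> 0
  set.seed(12)
  x_rep <- rep(sample(0:9) / 3, 30)
  expect_lt(sample_entropy(x_rep, 2L, 0.2 * sd(x_rep)), 0.05)
  period <- 100
  x_per <- rep(sin(2 * pi * (1:period) / period) +
                 0.3 * sin(4 * pi * (1:period) / period), 25)
  r <- 0.2 * sd(x_per)
  ac <- gaitreliab:::lagged_autocov(x_per, period)
  expect_equal(ac$autocorr, 1, tolerance = 1e-9)

  set.seed(8)
  x_noise <- rnorm(2500)
  expect_gt(sample_entropy(x_noise, 2L, 0.2 * sd(x_noise)),
            sample_entropy(x_per, 2L, r))  # noise is less regular
})

test_that("complexity features consume exactly 25 strides", {
  fx <- fixture_walk()
  o <- fx$oriented$left_foot
  cts <- fx$events$left$contacts
  full <- complexity_features(o, cts, "left_foot")
  first26 <- complexity_features(o, cts[1:26], "left_foot")
  expect_identical(full, first26)   # contacts beyond stride 25 are unused
  few <- complexity_features(o, cts[1:20], "left_foot")
  expect_true(all(is.na(unlist(few))))
  expect_identical(unique(unlist(attr(few, "reasons"))),
                   "insufficient_strides")
})

test_that("the symmetry index and ratio follow their closed forms", {
  st <- list(left_foot_swing_time_mean = 0.44,
             right_foot_swing_time_mean = 0.40,
             left_foot_stance_time_mean = 0.7,
             right_foot_stance_time_mean = 0.7)
  a <- asymmetry_features(st, list(paretic_side = "left"))
  expect_equal(a$asym_swing_time_si, abs(0.04) / 0.42 * 100) # 9.5238%
  expect_equal(a$asym_swing_time_ratio, 1.1)
  expect_equal(a$asym_stance_time_si, 0)
  expect_equal(a$asym_stance_time_ratio, 1)
  expect_true(is.na(a$asym_stride_length_si))
  expect_identical(attr(a, "reasons")$asym_stride_length_si,
                   "missing_foot_features")
})

test_that("an undefined paretic side falls back to the left foot", {
  st <- list(left_foot_swing_time_mean = 0.44,
             right_foot_swing_time_mean = 0.40)
  for (side in list("unknown", "both", NULL)) {
    a <- asymmetry_features(st, list(paretic_side = side))
    expect_equal(a$asym_swing_time_ratio, 1.1)   # P = left
  }
  a_r <- asymmetry_features(st, list(paretic_side = "right"))
  expect_equal(a_r$asym_swing_time_ratio, 0.40 / 0.44)
})

test_that("assembly enforces the catalogue and repeated runs are identical", {
  fv <- fixture_features()
  expect_identical(nrow(fv), 166L)
  expect_identical(sum(is.na(fv$value)), 0L)
  fv2 <- run_assessment(fixture_walk()$recording)
  expect_identical(fv$value, fv2$value)

  expect_error(assemble_features(list(bogus_feature = 1)),
               class = "gaitreliab_catalogue_error")
})

test_that("doubling accelerometer gain leaves temporal and asymmetry features unchanged", {
  fx <- fixture_walk()
  rec2 <- fx$recording
  for (s in names(rec2$streams)) {
    a <- rec2$streams[[s]]$accel
    g <- 9.80665
    a[, 3] <- (a[, 3] - g) * 2 + g   # double the motion component
    a[, 1:2] <- a[, 1:2] * 2
    rec2$streams[[s]]$accel <- a
  }
  fv1 <- fixture_features()
  fv2 <- run_assessment(rec2)
  v1 <- stats::setNames(fv1$value, fv1$name)
  v2 <- stats::setNames(fv2$value, fv2$name)
  temporal <- c("left_foot_stride_time_mean", "right_foot_stride_time_mean",
                "left_foot_stance_time_mean", "left_foot_cadence",
                "asym_stride_time_si", "asym_swing_time_ratio",
                "asym_stride_length_ratio")
  for (nm in temporal)
    expect_equal(v1[[nm]], v2[[nm]], tolerance = 0.02)
  # amplitude-bearing features scale with the gain
  expect_equal(v2[["left_foot_vt_dom_amp"]] / v1[["left_foot_vt_dom_amp"]],
               2, tolerance = 0.05)
  expect_equal(v2[["left_foot_stride_length_mean"]] /
                 v1[["left_foot_stride_length_mean"]], 2, tolerance = 0.05)
})
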