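test_that("the stride-time prior is the reciprocal dominant ML frequency", {
  fs <- 100; tt <- (0:(11999)) / fs
  p <- estimate_stride_prior(sin(2 * pi * 0.8 * tt), fs)
  expect_equal(p$average_stride_time_s, 1.25, tolerance = 0.01)

  fx <- fixture_walk()
  wb <- fx$pre$walk_bounds
  ml <- fx$oriented$left_foot$accel[wb[1]:wb[2], "ml"]
  p2 <- estimate_stride_prior(ml, fs)
  expect_lt(abs(p2$average_stride_time_s - 1.2), 0.05)

  set.seed(9)
  expect_error(estimate_stride_prior(rnorm(6000), fs),
               class = "gaitreliab_prior_error")
  expect_error(estimate_stride_prior(sin(2 * pi * 0.8 * tt[1:500]), fs),
               class = "gaitreliab_prior_error")
})

test_that("peak detection matches a brute-force height/distance oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- 300
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 3, 3),
                                  sides = 2))
    x[is.na(x)] <- 0
    h <- stats::quantile(x, runif(1, 0.5, 0.95))
    d <- sample(2:25, 1)
    expect_identical(find_peaks(x, height = h, distance = d),
                     find_peaks_oracle(x, height = h, distance = d))
  }
})

test_that("of two close peaks only the higher is retained and flats yield none", {
  x <- numeric(200); x[80] <- 5; x[120] <- 7
  prior <- structure(list(average_stride_time_s = 1,
                          dominant_frequency_hz = 1),
                     class = "stride_prior")
  # 0.5 x prior apart (< 0.75 distance): only the higher peak
  got <- detect_foot_contacts(x, prior, 100)
  expect_identical(got, 120L)
  expect_length(detect_foot_contacts(rep(3, 200), prior, 100), 0)
})

test_that("false-negative repair recovers contacts attenuated below the first-pass threshold", {
  att_idx <- seq(10, 80, by = 10)
  missed_first <- 0L; recovered <- 0L; total <- 0L
  for (seed in 1:3) {
    sp <- walk_spec(attenuate_contacts = list(left = att_idx,
                                              right = integer(0)),
                    attenuation_factor = 0.4, rng_seed = 6000 + seed)
    w <- generate_walk(sp)
    pre <- preprocess(w$recording,
                      structure(sp$gyro_bias, class = "gyro_bias"))
    o <- orient(pre$streams$left_foot)
    wb <- pre$walk_bounds; fs <- 100
    ml <- o$accel[wb[1]:wb[2], "ml"]; vt <- o$accel[wb[1]:wb[2], "vt"]
    prior <- estimate_stride_prior(ml, fs)
    cand <- detect_foot_contacts(vt, prior, fs)
    rep_ <- repair_false_negatives(cand, vt, prior, fs)
    t_att <- w$ground_truth$foot_contacts$left[att_idx]
    t_cand <- (cand + wb[1] - 2) / fs + 2
    t_rep <- (rep_$contacts + wb[1] - 2) / fs + 2
    missed_first <- missed_first +
      sum(!vapply(t_att, function(tc) any(abs(t_cand - tc) <= 0.05), TRUE))
    recovered <- recovered +
      sum(vapply(t_att, function(tc) any(abs(t_rep - tc) <= 0.05), TRUE))
    total <- total + length(t_att)
  }
  expect_gt(missed_first, 0.5 * total)   # the first pass does miss them
  expect_gte(recovered / total, 0.9)     # the repair pass recovers them
})

test_that("repair is a no-op without over-long gaps and ignores noise-only gaps", {
  fx <- fixture_walk()
  wb <- fx$pre$walk_bounds; fs <- 100
  vt <- fx$oriented$left_foot$accel[wb[1]:wb[2], "vt"]
  ml <- fx$oriented$left_foot$accel[wb[1]:wb[2], "ml"]
  prior <- estimate_stride_prior(ml, fs)
  cand <- detect_foot_contacts(vt, prior, fs)
  rep_ <- repair_false_negatives(cand, vt, prior, fs)
  expect_identical(rep_$contacts, cand)
  expect_identical(rep_$inserted, 0L)

  # an artificial gap containing only noise gains no insertion
  set.seed(31)
  vt2 <- rep(0.2 * rnorm(3000), 1)
  impacts <- seq(100, 2900, by = 120)
  impacts <- impacts[impacts < 1300 | impacts > 1700]  # one missing stride
  vt2[impacts] <- vt2[impacts] + 10
  prior2 <- structure(list(average_stride_time_s = 1.2,
                           dominant_frequency_hz = 1 / 1.2),
                      class = "stride_prior")
  cand2 <- detect_foot_contacts(vt2, prior2, 100)
  rep2 <- repair_false_negatives(cand2, vt2, prior2, 100)
  expect_identical(rep2$inserted, 0L)
})

test_that("stance durations match the generated stance fraction", {
  fx <- fixture_walk()
  for (foot in c("left", "right")) {
    ev <- fx$events[[foot]]
    durs <- (ev$stance[, 2] - ev$stance[, 1]) / 100
    expect_lt(abs(mean(durs) - 0.72), 0.05)   # 0.6 x 1.2 s
  }
})

test_that("a spurious mid-swing peak is removed by the false-positive pass", {
  fx <- fixture_walk()
  wb <- fx$pre$walk_bounds; fs <- 100
  o <- fx$oriented$left_foot
  idx <- wb[1]:wb[2]
  amag <- sqrt(rowSums(o$accel[idx, ]^2))
  gmag <- sqrt(rowSums(o$gyro[idx, ]^2))
  cts <- fx$events$left$contacts - wb[1] + 1L
  # inject a bogus contact in the middle of a swing phase
  k <- 40
  bogus <- cts[k] + round(0.9 * (cts[k + 1] - cts[k]))
  ev <- segment_stance_swing(sort(c(cts, bogus)), amag, gmag, fs,
                             foot = "left")
  expect_gte(ev$repair_log["false_positive_removed"][[1]], 1L)
  expect_lte(abs(length(ev$contacts) - length(cts)), 1)
})

test_that("continuous motion without quiescence fails stance detection", {
  n <- 2000
  amag <- rep(5, n)
  gmag <- 100 + 50 * sin(2 * pi * (1:n) / 80)
  expect_error(segment_stance_swing(c(100L, 400L, 700L, 1000L),
                                    amag, gmag, 100),
               class = "gaitreliab_detection_error")
})

test_that("stance and swing intervals tile the span between first and last contact", {
  ev <- fixture_walk()$events$left
  iv <- rbind(cbind(ev$stance, 1), cbind(ev$swing, 2))
  iv <- iv[order(iv[, 1]), ]
  expect_identical(unname(iv[1, 1]), ev$contacts[1])
  expect_identical(unname(iv[nrow(iv), 2]),
                   ev$contacts[length(ev$contacts)])
  expect_true(all(iv[-1, 1] == iv[-nrow(iv), 2]))  # contiguous, no overlap
})

test_that("left/right stride counts agree and clean input needs no repairs", {
  ev <- fixture_walk()$events
  expect_lte(abs(length(ev$left$contacts) - length(ev$right$contacts)), 1)
  for (foot in c("left", "right"))
    expect_identical(sum(ev[[foot]]$repair_log), 0L)
})
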