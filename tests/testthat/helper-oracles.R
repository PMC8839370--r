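# Independent naive oracles and shared fixtures for the test suite.

# sample entropy, direct O(N^2) double loop (Chebyshev distance,
# self-matches excluded)
sampen_naive <- function(x, m = 2, r) {
  n <- length(x)
  # both template lengths range over the first n - m starting points,
  # the standard sample-entropy convention
  B <- 0L; A <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
      }
    }
  }
  -log(A / B)
}

# approximate entropy, direct implementation (self-matches included)
apen_naive <- function(x, m = 2, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    s <- 0
    for (i in seq_len(nm)) {
      cnt <- 0L
      for (j in seq_len(nm))
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1L
      s <- s + log(cnt / nm)
    }
    s / nm
  }
  phi(m) - phi(m + 1)
}

# ICC(2,1) through variance components extracted from aov() mean squares
icc21_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]
  msr <- a["subj", "Mean Sq"]
  msc <- a["sess", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  vr <- (msr - mse) / k
  vc <- (msc - mse) / n
  vr / (vr + vc + mse)
}

# brute-force peak selection: local maxima above height, then repeatedly
# keep the globally highest remaining candidate and discard all others
# closer than `distance`
find_peaks_oracle <- function(x, height = -Inf, distance = 0) {
  n <- length(x)
  cand <- which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] && x[i] > x[i + 1], TRUE)) + 1L
  cand <- cand[x[cand] >= height]
  kept <- integer(0)
  d <- ceiling(distance)
  while (length(cand)) {
    best <- cand[which.max(x[cand])]
    kept <- c(kept, best)
    cand <- cand[abs(cand - best) >= max(d, 1)]
  }
  sort(kept)
}

# match detected event times against truth at a tolerance (seconds)
event_match <- function(detected_s, truth_s, tol = 0.05) {
  recall <- mean(vapply(truth_s, function(tc)
    any(abs(detected_s - tc) <= tol), TRUE))
  precision <- if (length(detected_s) == 0) NA_real_ else
    mean(vapply(detected_s, function(td)
      any(abs(truth_s - td) <= tol), TRUE))
  c(recall = recall, precision = precision)
}

# shared fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_walk <- function() {
  if (is.null(.fixtures$walk)) {
    spec <- walk_spec(rng_seed = 7L)
    w <- generate_walk(spec)
    bias <- structure(spec$gyro_bias, class = "gyro_bias")
    pre <- preprocess(w$recording, bias)
    oriented <- lapply(pre$streams, orient)
    events <- list(
      left = detect_strides(oriented$left_foot, pre$walk_bounds, "left"),
      right = detect_strides(oriented$right_foot, pre$walk_bounds, "right"))
    .fixtures$walk <- list(spec = spec, recording = w$recording,
                           gt = w$ground_truth, pre = pre,
                           oriented = oriented, events = events)
  }
  .fixtures$walk
}

fixture_features <- function() {
  if (is.null(.fixtures$fv))
    .fixtures$fv <- run_assessment(fixture_walk()$recording)
  .fixtures$fv
}

# fabricated perfectly regular gait events (sample domain)
regular_events <- function(n_contacts = 31, stride_samples = 120,
                           stance_samples = 72, offset = 1L,
                           foot = "left", fs = 100) {
  contacts <- seq(offset, by = stride_samples, length.out = n_contacts)
  stance <- cbind(contacts[-n_contacts],
                  contacts[-n_contacts] + stance_samples)
  structure(list(foot = foot, contacts = contacts, stance = stance,
                 swing = cbind(stance[, 2],
                               contacts[-1]),
                 sample_rate_hz = fs,
                 repair_log = c(false_negative_inserted = 0L,
                                false_positive_removed = 0L)),
            class = "gait_events")
}

regular_disp <- function(events, length_m = 1.3) {
  anchors <- round(rowMeans(events$stance))
  k <- length(anchors) - 1
  data.frame(start_sample = anchors[-length(anchors)],
             end_sample = anchors[-1],
             disp_vt = 0, disp_ml = 0, disp_ap = length_m,
             length_m = length_m)
}
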