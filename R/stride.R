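#' Estimate the average stride time from medio-lateral acceleration
#'
#' The dominant frequency of the mean-removed ML acceleration spectrum
#' within a physiological band gives the gait-cycle rate; its reciprocal
#' is the stride-time prior that parameterises peak detection. An error
#' is raised when the spectrum is flat (no in-band peak at least
#' `peak_factor` times the in-band median magnitude).
#'
#' @param ml_accel medio-lateral acceleration over the walking span.
#' @param sample_rate_hz sampling rate, Hz.
#' @param band search band, Hz.
#' @param peak_factor required ratio of the dominant magnitude to the
#'   in-band median.
#' @param prior_limits_s admissible stride-time range, seconds.
#' @return a `stride_prior` with `average_stride_time_s` and
#'   `dominant_frequency_hz`.
#' @export
estimate_stride_prior <- function(ml_accel, sample_rate_hz,
                                  band = c(0.2, 2.5), peak_factor = 3,
                                  prior_limits_s = c(0.4, 5)) {
  x <- ml_accel - mean(ml_accel)
  n <- length(x)
  if (n < 10 * sample_rate_hz)
    abort("need at least 10 s of walking signal for the stride prior",
          "gaitreliab_prior_error")
  mag <- Mod(fft(x))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * sample_rate_hz / n
  in_band <- freq >= band[1] & freq <= band[2]
  if (max(mag[in_band]) < peak_factor * median(mag[in_band]))
    abort("flat spectrum: no dominant stride frequency found",
          "gaitreliab_prior_error")
  f_dom <- freq[in_band][which.max(mag[in_band])]
  stride_time <- min(max(1 / f_dom, prior_limits_s[1]), prior_limits_s[2])
  structure(list(average_stride_time_s = stride_time,
                 dominant_frequency_hz = 1 / stride_time),
            class = "stride_prior")
}

#' @export
print.stride_prior <- function(x, ...) {
  cat(sprintf("<stride_prior> %.3f s/stride (%.3f Hz)\n",
              x$average_stride_time_s, x$dominant_frequency_hz))
  invisible(x)
}

#' Detect foot-contact candidates in vertical acceleration
#'
#' Peak detection with a minimal distance of `distance_factor` times the
#' average stride time and a minimal height of mean plus one SD of the
#' vertical acceleration.
#'
#' @param vt_accel vertical acceleration over the walking span.
#' @param prior a `stride_prior`.
#' @param sample_rate_hz sampling rate, Hz.
#' @param distance_factor fraction of the stride-time prior used as the
#'   minimal peak spacing.
#' @param height_factor scale applied to the mean + SD height threshold
#'   (1 for the first pass).
#' @return integer candidate indices, ascending (possibly empty).
#' @export
detect_foot_contacts <- function(vt_accel, prior, sample_rate_hz,
                                 distance_factor = 0.75,
                                 height_factor = 1) {
  height <- height_factor * (mean(vt_accel) + sd(vt_accel))
  distance <- distance_factor * prior$average_stride_time_s * sample_rate_hz
  find_peaks(vt_accel, height = height, distance = distance)
}

#' Recover missed foot contacts in over-long inter-peak gaps
#'
#' Every gap between consecutive candidates longer than `gap_factor`
#' times the stride-time prior is re-searched with the height threshold
#' scaled by `height_factor` (the minimal peak distance unchanged, also
#' enforced against the gap's bounding peaks). The pass runs once per
#' gap.
#'
#' @param candidates sorted candidate indices from
#'   [detect_foot_contacts()].
#' @param vt_accel the same vertical acceleration series.
#' @param prior a `stride_prior`.
#' @param sample_rate_hz sampling rate, Hz.
#' @param gap_factor gap length threshold, in stride-time priors.
#' @param height_factor scale on the first-pass height threshold.
#' @param distance_factor as in [detect_foot_contacts()].
#' @return list with `contacts` (repaired indices) and `inserted` count.
#' @export
repair_false_negatives <- function(candidates, vt_accel, prior,
                                   sample_rate_hz, gap_factor = 1.5,
                                   height_factor = 0.75,
                                   distance_factor = 0.75) {
  if (length(candidates) < 2)
    return(list(contacts = candidates, inserted = 0L))
  expected <- prior$average_stride_time_s * sample_rate_hz
  dist <- distance_factor * expected
  height <- height_factor * (mean(vt_accel) + sd(vt_accel))
  inserted <- 0L
  out <- candidates[1]
  for (k in seq_len(length(candidates) - 1)) {
    a <- candidates[k]; bnd <- candidates[k + 1]
    if ((bnd - a) > gap_factor * expected) {
      lo <- a + ceiling(dist); hi <- bnd - ceiling(dist)
      if (hi - lo + 1 >= 3) {
        found <- find_peaks(vt_accel[lo:hi], height = height,
                            distance = dist) + lo - 1L
        inserted <- inserted + length(found)
        out <- c(out, found)
      }
    }
    out <- c(out, bnd)
  }
  list(contacts = sort(unique(out)), inserted = inserted)
}

#' Segment stance and swing phases between foot contacts
#'
#' Between each pair of consecutive contacts the longest span of at
#' least `min_stance_s` seconds with acceleration magnitude below its
#' mean + SD and gyroscope magnitude below its mean is taken as the
#' stance phase. If a gap holds no such span, the lower of its two
#' bounding peaks is removed (false-positive repair) and the merged gap
#' re-examined. Swing phases are the residual spans between stances; the
#' stance and swing intervals tile the span between the first and last
#' contact.
#'
#' @param contacts sorted contact indices (>= 2).
#' @param accel_mag gravity-free acceleration magnitude series.
#' @param gyro_mag gyroscope magnitude series.
#' @param sample_rate_hz sampling rate, Hz.
#' @param min_stance_s minimal stationary duration, seconds.
#' @param foot `"left"` or `"right"` (annotation only).
#' @return a `gait_events` object: `contacts`, `stance` and `swing`
#'   interval matrices (sample indices), and a `repair_log`.
#' @export
segment_stance_swing <- function(contacts, accel_mag, gyro_mag,
                                 sample_rate_hz, min_stance_s = 0.2,
                                 foot = "unknown") {
  if (length(contacts) < 2)
    abort("need at least two contacts to segment phases",
          "gaitreliab_detection_error")
  thr_a <- mean(accel_mag) + sd(accel_mag)
  thr_g <- mean(gyro_mag)
  quiet <- accel_mag < thr_a & gyro_mag < thr_g
  min_len <- ceiling(min_stance_s * sample_rate_hz)
  removed <- 0L

  stance_in_gap <- function(a, b) {
    if (b - a < 2) return(NULL)
    seg <- quiet[a:(b - 1)]
    runs <- true_runs(seg)
    if (nrow(runs) == 0) return(NULL)
    runs <- runs[runs[, 2] - runs[, 1] + 1 >= min_len, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    best <- which.max(runs[, 2] - runs[, 1])
    runs[best, ] + a - 1L
  }

  cts <- contacts
  stances <- list()
  i <- 1L
  while (i < length(cts)) {
    s <- stance_in_gap(cts[i], cts[i + 1])
    if (is.null(s)) {
      if (length(cts) <= 2) break
      # remove the lower of the two bounding peaks and merge the gaps
      drop <- if (accel_mag[cts[i]] <= accel_mag[cts[i + 1]]) i else i + 1L
      cts <- cts[-drop]
      removed <- removed + 1L
      i <- max(1L, i - 1L)
      stances <- list()   # re-segment from scratch over the kept peaks
      i <- 1L
    } else {
      stances[[length(stances) + 1L]] <- s
      i <- i + 1L
    }
  }
  if (length(stances) == 0)
    abort(sprintf("no stance phase found for %s foot", foot),
          "gaitreliab_detection_error")
  stance <- do.call(rbind, stances)
  colnames(stance) <- c("start", "end")

  # swing = residual spans between stances, tiling [first, last] contact
  span <- c(cts[1], cts[length(cts)])
  edges <- rbind(c(NA, span[1]), stance, c(span[2], NA))
  swing <- cbind(start = edges[-nrow(edges), 2], end = edges[-1, 1])
  swing <- swing[swing[, 2] > swing[, 1], , drop = FALSE]

  structure(list(foot = foot, contacts = cts, stance = stance,
                 swing = swing, sample_rate_hz = sample_rate_hz,
                 repair_log = c(false_negative_inserted = 0L,
                                false_positive_removed = removed)),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>", x$foot, "foot:", length(x$contacts), "contacts,",
      nrow(x$stance), "stances; repairs FN", x$repair_log[1],
      "/ FP", x$repair_log[2], "\n")
  invisible(x)
}

#' Detect strides of one foot from an oriented signal
#'
#' Binds the full per-foot chain: stride-time prior from ML
#' acceleration, first-pass peak detection on vertical acceleration,
#' false-negative repair, and stance/swing segmentation, all restricted
#' to the walking span. Returned sample indices refer to the oriented
#' (trimmed) signal.
#'
#' @param oriented an `oriented_signal` of a foot sensor.
#' @param walk_bounds c(start, end) sample span of walking.
#' @param foot `"left"` or `"right"`.
#' @param config pipeline constants, see [default_config()].
#' @return a `gait_events`.
#' @export
detect_strides <- function(oriented, walk_bounds, foot,
                           config = default_config()) {
  fs <- oriented$sample_rate_hz
  idx <- walk_bounds[1]:walk_bounds[2]
  ml <- oriented$accel[idx, "ml"]
  vt <- oriented$accel[idx, "vt"]
  prior <- estimate_stride_prior(ml, fs, band = config$prior_band_hz)
  cand <- detect_foot_contacts(vt, prior, fs,
                               distance_factor = config$peak_distance_factor)
  rep <- repair_false_negatives(cand, vt, prior, fs,
                                gap_factor = config$gap_factor,
                                height_factor = config$fn_height_factor,
                                distance_factor = config$peak_distance_factor)
  amag <- vec_norm(oriented$accel[idx, , drop = FALSE])
  gmag <- vec_norm(oriented$gyro[idx, , drop = FALSE])
  ev <- segment_stance_swing(rep$contacts, amag, gmag, fs,
                             min_stance_s = config$stance_min_s,
                             foot = foot)
  ev$repair_log["false_negative_inserted"] <- rep$inserted
  # shift indices back into the trimmed-signal frame
  off <- walk_bounds[1] - 1L
  ev$contacts <- ev$contacts + off
  ev$stance <- ev$stance + off
  ev$swing <- ev$swing + off
  ev$prior <- prior
  ev
}

#' Export gait events as a data frame (CSV-ready)
#'
#' @param events a `gait_events` or `lowback_events`.
#' @param source annotation for the `source` column.
#' @return data frame with columns `foot,event,sample,time_s,source`.
#' @export
events_table <- function(events, source = NULL) {
  fs <- events$sample_rate_hz
  rows <- list()
  add <- function(foot, event, sample)
    data.frame(foot = foot, event = event, sample = sample,
               time_s = (sample - 1) / fs)
  if (inherits(events, "gait_events")) {
    src <- source %||% paste0(events$foot, "_foot")
    rows <- list(add(events$foot, "contact", events$contacts),
                 add(events$foot, "stance_start", events$stance[, 1]),
                 add(events$foot, "stance_end", events$stance[, 2]))
  } else {
    src <- source %||% "low_back"
    rows <- list(add("left", "contact", events$contacts$left),
                 add("right", "contact", events$contacts$right))
  }
  out <- do.call(rbind, rows)
  out$source <- src
  out[order(out$sample), ]
}
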