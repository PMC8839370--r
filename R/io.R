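#' Write a recording to per-sensor CSV files plus a JSON manifest
#'
#' One CSV per sensor with header `t,ax,ay,az,gx,gy,gz` (`t` seconds,
#' acceleration m/s^2, angular velocity deg/s), and a `manifest.json`
#' mapping sensors to files and carrying the subject metadata.
#'
#' @param recording a `raw_recording`.
#' @param dir output directory (created if needed).
#' @param ground_truth optional `ground_truth` written as a JSON sidecar.
#' @return path to the manifest, invisibly.
#' @export
write_recording <- function(recording, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- recording$sample_rate_hz
  files <- list()
  for (sensor in names(recording$streams)) {
    st <- recording$streams[[sensor]]
    n <- nrow(st$accel)
    df <- data.frame(t = round((0:(n - 1)) / fs, 6),
                     round(st$accel, 6), round(st$gyro, 6))
    names(df) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
    f <- paste0(sensor, ".csv")
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
    files[[sensor]] <- f
  }
  manifest <- c(recording$meta,
                list(sample_rate_hz = fs, files = files))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  if (!is.null(ground_truth)) {
    gt <- ground_truth[setdiff(names(ground_truth), "spec")]
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(mf)
}

#' Read a recording from a JSON manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_recording()] (sensor file paths are resolved relative to it).
#' @return a `raw_recording`.
#' @export
read_recording <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort(paste("manifest not found:", manifest_path), "gaitreliab_io_error")
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  missing <- setdiff(SENSORS, names(man$files))
  if (length(missing))
    abort(paste("missing sensor:", paste(missing, collapse = ", ")),
          "gaitreliab_missing_sensor_error", list(missing = missing))
  streams <- list()
  for (sensor in SENSORS) {
    f <- file.path(base, man$files[[sensor]])
    if (!file.exists(f))
      abort(paste("missing sensor file:", f),
            "gaitreliab_missing_sensor_error", list(missing = sensor))
    df <- read.csv(f)
    need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
    if (!all(need %in% names(df)))
      abort(paste("malformed sensor CSV:", f), "gaitreliab_io_error")
    fs <- man$sample_rate_hz %||% (1 / median(diff(df$t)))
    streams[[sensor]] <- structure(
      list(accel = as.matrix(df[, c("ax", "ay", "az")]),
           gyro = as.matrix(df[, c("gx", "gy", "gz")]),
           sample_rate_hz = fs, placement = sensor),
      class = "imu_stream")
  }
  meta <- list(subject_id = man$subject_id %||% NA_character_,
               session_id = man$session_id %||% NA_character_,
               height_m = man$height_m %||% NA_real_,
               paretic_side = man$paretic_side %||% "unknown",
               expected_duration_s = man$expected_duration_s %||% NA_real_)
  structure(list(streams = streams,
                 sample_rate_hz = streams[[1]]$sample_rate_hz, meta = meta),
            class = "raw_recording")
}

#' Estimate gyroscope bias from a stationary recording
#'
#' The per-axis mean angular velocity over the whole recording, per
#' sensor. The recording must contain no motion: an error is raised if
#' the gyroscope SD on any axis exceeds `motion_sd_threshold`.
#'
#' @param stationary_recording a `raw_recording` of a standstill.
#' @param motion_sd_threshold maximal per-axis gyroscope SD, deg/s.
#' @return named list of per-sensor 3-vectors (deg/s), class `gyro_bias`.
#' @export
estimate_gyro_bias <- function(stationary_recording,
                               motion_sd_threshold = 3) {
  bias <- list()
  for (sensor in names(stationary_recording$streams)) {
    gy <- stationary_recording$streams[[sensor]]$gyro
    if (any(apply(gy, 2, sd) > motion_sd_threshold))
      abort(paste("motion detected in stationary recording for", sensor),
            "gaitreliab_calibration_error", list(sensor = sensor))
    bias[[sensor]] <- colMeans(gy)
  }
  structure(bias, class = "gyro_bias")
}

zero_bias <- function() {
  structure(list(left_foot = c(0, 0, 0), right_foot = c(0, 0, 0),
                 low_back = c(0, 0, 0)), class = "gyro_bias")
}

# rational resampling by FIR anti-aliasing + windowed-sinc interpolation,
# with the FIR group delay compensated so event timing is preserved
resample_channel <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  r <- fs_out / fs_in
  ord <- 10L
  n_in <- length(x)
  if (r < 1) {
    b <- signal::fir1(2L * ord + 1L, r)
    xf <- as.numeric(signal::fftfilt(b, c(x, numeric(length(b)))))
    delay <- (length(b) - 1) / 2
  } else {
    xf <- x
    delay <- 0
  }
  tt <- seq(1, n_in + 1 - 1 / r, by = 1 / r) + delay
  idx <- trunc(tt)
  frac <- tt - idx
  xp <- c(numeric(ord), xf, numeric(2L * ord))
  y <- numeric(length(idx))
  sinc <- function(z) ifelse(z == 0, 1, sin(pi * z) / (pi * z))
  for (i in (-ord):ord) {
    w <- sinc(frac - i) * (0.5 + 0.5 * cos(pi * (frac - i) / (ord + 0.5)))
    y <- y + xp[idx + i + ord] * w
  }
  y
}

# walking-span location by thresholding rolling mean magnitudes; returns
# c(start, end) sample indices or NULL when nothing exceeds the thresholds
locate_walk_bounds <- function(accel, gyro, fs, window_s = 0.5) {
  ma <- abs(vec_norm(accel) - GRAVITY_MS2)
  mg <- vec_norm(gyro)
  ra <- roll_mean(ma, window_s * fs)
  rg <- roll_mean(mg, window_s * fs)
  walking <- ra > mean(ma) | rg > mean(mg)
  if (!any(walking)) return(NULL)
  bounds <- range(which(walking))
  # a genuine walk is bracketed by stationary bookends that are clearly
  # quieter than the walking span; threshold flicker on a stationary
  # recording is not a walk
  outside <- c(seq_len(bounds[1] - 1),
               seq(bounds[2] + 1, length.out = length(ma) - bounds[2]))
  if (length(outside) < 0.25 * fs) return(NULL)
  if (mean(ma[bounds[1]:bounds[2]]) < 1.5 * mean(ma[outside]) &&
      mean(mg[bounds[1]:bounds[2]]) < 1.5 * mean(mg[outside]))
    return(NULL)
  bounds
}

#' Preprocess a raw recording
#'
#' Fixed order of operations: (1) resample every channel to 100 Hz by
#' polyphase rational resampling; (2) subtract the gyroscope bias;
#' (3) drop the first and last two seconds (transitional phases);
#' (4) locate the pre- and post-walk stationary periods per sensor by
#' thresholding 0.5 s rolling means of the acceleration magnitude (1 g
#' offset removed) and gyroscope magnitude against their global means;
#' (5) take the residual span between the stationary periods as the walk.
#'
#' @param raw a `raw_recording`.
#' @param bias a `gyro_bias` (deg/s per sensor); defaults to zero.
#' @param target_rate_hz output rate, Hz.
#' @param trim_s seconds removed from each end after resampling.
#' @param stationary_window_s rolling-window length for the stationary
#'   thresholding, seconds.
#' @return a `preprocessed_recording`: trimmed 100 Hz streams,
#'   `walk_bounds` (sample span of the union of per-sensor walking
#'   periods), per-sensor bounds, and a log of decisions.
#' @export
preprocess <- function(raw, bias = zero_bias(), target_rate_hz = 100,
                       trim_s = 2, stationary_window_s = 0.5) {
  missing <- setdiff(SENSORS, names(raw$streams))
  if (length(missing))
    abort(paste("missing sensor:", paste(missing, collapse = ", ")),
          "gaitreliab_missing_sensor_error", list(missing = missing))
  fs_in <- raw$sample_rate_hz
  n_min <- 2 * (trim_s + 1) * fs_in
  if (nrow(raw$streams[[1]]$accel) < n_min)
    abort("signal too short to preprocess", "gaitreliab_io_error")

  log <- character(0)
  streams <- list(); sensor_bounds <- list()
  for (sensor in SENSORS) {
    st <- raw$streams[[sensor]]
    acc <- apply(st$accel, 2, resample_channel, fs_in = fs_in,
                 fs_out = target_rate_hz)
    gyr <- apply(st$gyro, 2, resample_channel, fs_in = fs_in,
                 fs_out = target_rate_hz)
    gyr <- sweep(gyr, 2, bias[[sensor]] %||% c(0, 0, 0))
    keep <- (trim_s * target_rate_hz + 1):(nrow(acc) - trim_s * target_rate_hz)
    acc <- acc[keep, , drop = FALSE]
    gyr <- gyr[keep, , drop = FALSE]
    bounds <- locate_walk_bounds(acc, gyr, target_rate_hz,
                                 stationary_window_s)
    if (is.null(bounds)) {
      log <- c(log, sprintf("%s: no walking period found", sensor))
    } else {
      sensor_bounds[[sensor]] <- bounds
      log <- c(log, sprintf("%s: walking span %.2f-%.2f s", sensor,
                            (bounds[1] - 1) / target_rate_hz,
                            (bounds[2] - 1) / target_rate_hz))
    }
    streams[[sensor]] <- structure(
      list(accel = acc, gyro = gyr, sample_rate_hz = target_rate_hz,
           placement = sensor), class = "imu_stream")
  }
  if (length(sensor_bounds) == 0)
    abort("no walking period found", "gaitreliab_no_walk_error",
          list(log = log))
  walk_bounds <- c(min(vapply(sensor_bounds, `[`, 0, 1)),
                   max(vapply(sensor_bounds, `[`, 0, 2)))
  structure(list(streams = streams, sample_rate_hz = target_rate_hz,
                 walk_bounds = walk_bounds, sensor_bounds = sensor_bounds,
                 meta = raw$meta, log = log),
            class = "preprocessed_recording")
}

#' @export
print.preprocessed_recording <- function(x, ...) {
  cat("<preprocessed_recording>", nrow(x$streams[[1]]$accel), "samples @",
      x$sample_rate_hz, "Hz; walk",
      round((x$walk_bounds[1] - 1) / x$sample_rate_hz, 2), "-",
      round((x$walk_bounds[2] - 1) / x$sample_rate_hz, 2), "s\n")
  invisible(x)
}

#' Validate the residual walking duration against the expected duration
#'
#' A sensor fails when its residual walking duration deviates from the
#' expected duration by strictly more than `tolerance_s` seconds; the
#' measurement as a whole passes only if all sensors pass.
#'
#' @param pre a `preprocessed_recording`.
#' @param expected_duration_s expected walking duration, seconds.
#' @param tolerance_s maximal absolute deviation, seconds.
#' @return a `length_verdict`: per-sensor residual durations, deviations,
#'   verdicts, and the combined `pass`.
#' @export
validate_length <- function(pre, expected_duration_s, tolerance_s = 10) {
  fs <- pre$sample_rate_hz
  res <- vapply(pre$sensor_bounds, function(b) (b[2] - b[1] + 1) / fs, 0)
  res <- res[SENSORS[SENSORS %in% names(res)]]
  missing <- setdiff(SENSORS, names(res))
  dev <- res - expected_duration_s
  pass <- abs(dev) <= tolerance_s
  structure(list(residual_s = res, deviation_s = dev, sensor_pass = pass,
                 missing = missing,
                 pass = length(missing) == 0 && all(pass),
                 expected_duration_s = expected_duration_s,
                 tolerance_s = tolerance_s),
            class = "length_verdict")
}

#' @export
print.length_verdict <- function(x, ...) {
  cat("<length_verdict>", if (x$pass) "PASS" else "FAIL", "\n")
  for (s in names(x$residual_s))
    cat(sprintf("  %-11s residual %.2f s (deviation %+.2f s) %s\n", s,
                x$residual_s[s], x$deviation_s[s],
                if (x$sensor_pass[s]) "ok" else "excluded"))
  invisible(x)
}
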