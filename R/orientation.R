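#' Align an IMU stream with the anatomical axes and remove gravity
#'
#' Tracks the sensor attitude with a gradient-descent (Madgwick-class)
#' quaternion filter initialised from the static lead-in, rotates the
#' acceleration into the earth frame, subtracts gravity, and relabels the
#' axes as vertical (VT, upward positive), medio-lateral (ML, right
#' positive) and anterior-posterior (AP, anterior positive). The vertical
#' axis comes from the attitude track; the anterior axis is the dominant
#' horizontal acceleration direction, signed so that the net horizontal
#' progression over the first seconds of movement is positive (a static
#' pose alone cannot fix the heading).
#'
#' @param stream an `imu_stream` (accelerometer m/s^2, gyroscope deg/s,
#'   gyroscope already bias-corrected).
#' @param sample_rate_hz sampling rate; defaults to the stream's.
#' @param beta filter gain (gradient-descent step weight).
#' @param static_lead_s length of the quasi-static lead-in used for the
#'   initial gravity estimate, seconds (>= 1 s required).
#' @return an `oriented_signal` with `accel` and `gyro` matrices
#'   (columns `vt`, `ml`, `ap`; accel gravity-free m/s^2, gyro deg/s)
#'   plus the quaternion track.
#' @export
orient <- function(stream, sample_rate_hz = NULL, beta = 0.05,
                   static_lead_s = 1) {
  fs <- sample_rate_hz %||% stream$sample_rate_hz
  acc <- stream$accel
  gyr <- stream$gyro
  n <- nrow(acc)
  lead <- seq_len(min(n, round(static_lead_s * fs)))
  if (length(lead) < fs * 0.5 ||
      sd(vec_norm(acc[lead, , drop = FALSE])) > 2 ||
      max(apply(gyr[lead, , drop = FALSE], 2, sd)) > 5)
    abort("no quasi-static lead-in: cannot initialise orientation",
          "gaitreliab_orientation_error")

  a0 <- colMeans(acc[lead, , drop = FALSE])
  q0 <- quat_from_two_vectors(a0 / sqrt(sum(a0^2)), c(0, 0, 1))
  q <- madgwick_filter(acc, gyr * pi / 180, 1 / fs, beta, q0)
  acc_e <- quat_rotate(q, acc)
  acc_e[, 3] <- acc_e[, 3] - GRAVITY_MS2
  gyr_e <- quat_rotate(q, gyr)

  # heading: principal horizontal acceleration direction; the sign is
  # fixed by the forward-progression asymmetry of gait -- integrated
  # acceleration along the anterior axis is a train of positive
  # (forward-push) velocity bumps, so its band-passed version is
  # positively skewed, whereas slow attitude-drift leakage is not
  h <- acc_e[, 1:2, drop = FALSE]
  moving <- which(roll_mean(vec_norm(acc_e), round(0.5 * fs)) > 1)
  span <- if (length(moving)) moving[1]:min(n, moving[1] + 10 * fs) else 1:n
  ev <- eigen(crossprod(scale(h[span, , drop = FALSE], scale = FALSE)),
              symmetric = TRUE)
  u <- ev$vectors[, 1]
  vu <- cumtrapz(as.numeric(h[span, , drop = FALSE] %*% u), 1 / fs)
  bw <- signal::butter(2, c(0.25, 15) / (fs / 2), type = "pass")
  vf <- as.numeric(signal::filtfilt(bw, vu))
  if (mean(vf^3) < 0) u <- -u
  ap_axis <- c(u, 0)
  ml_axis <- c(u[2], -u[1], 0)            # right of travel, VT up
  accel <- cbind(vt = acc_e[, 3],
                 ml = as.numeric(acc_e %*% ml_axis),
                 ap = as.numeric(acc_e %*% ap_axis))
  gyro <- cbind(vt = gyr_e[, 3],
                ml = as.numeric(gyr_e %*% ml_axis),
                ap = as.numeric(gyr_e %*% ap_axis))
  structure(list(accel = accel, gyro = gyro,
                 sample_rate_hz = fs, source = stream$placement,
                 quaternions = q),
            class = "oriented_signal")
}

quat_from_two_vectors <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(a[2] * ax[3] - a[3] * ax[2], a[3] * ax[1] - a[1] * ax[3],
              a[1] * ax[2] - a[2] * ax[1])
    axis <- axis / sqrt(sum(axis^2))
    return(c(0, axis))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  q <- c(1 + d, axis)
  q / sqrt(sum(q^2))
}

#' @export
print.oriented_signal <- function(x, ...) {
  cat("<oriented_signal>", x$source, ":", nrow(x$accel), "samples @",
      x$sample_rate_hz, "Hz (VT/ML/AP, gravity removed)\n")
  invisible(x)
}

#' Per-stride displacement by zero-velocity-update integration
#'
#' For each pair of consecutive stance intervals, the gravity-free
#' acceleration is integrated to velocity between the stance midpoints,
#' the velocity is linearly de-drifted so it is exactly zero at both
#' anchors (the foot is stationary mid-stance), and integrated again to
#' displacement. Stride length is the horizontal norm of the per-stride
#' displacement.
#'
#' @param oriented an `oriented_signal` (foot sensor).
#' @param stance_intervals two-column matrix of stance (start, end)
#'   sample indices, ordered.
#' @return data frame with one row per stride: anchor samples,
#'   displacement components (m) and `length_m`.
#' @export
zupt_stride_displacement <- function(oriented, stance_intervals) {
  fs <- oriented$sample_rate_hz
  if (is.null(stance_intervals) || nrow(stance_intervals) < 2) {
    warning("no stride is bounded by two stance phases; nothing to integrate")
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      disp_ap = numeric(0), disp_ml = numeric(0),
                      disp_vt = numeric(0), length_m = numeric(0)))
  }
  anchors <- round(rowMeans(stance_intervals))
  out <- vector("list", length(anchors) - 1)
  for (k in seq_len(length(anchors) - 1)) {
    idx <- anchors[k]:anchors[k + 1]
    seg <- oriented$accel[idx, , drop = FALSE]
    disp <- numeric(3)
    for (j in 1:3) {
      v <- cumtrapz(seg[, j], 1 / fs)
      v <- v - seq(0, 1, length.out = length(v)) * v[length(v)]
      p <- cumtrapz(v, 1 / fs)
      disp[j] <- p[length(p)]
    }
    out[[k]] <- data.frame(start_sample = anchors[k],
                           end_sample = anchors[k + 1],
                           disp_vt = disp[1], disp_ml = disp[2],
                           disp_ap = disp[3],
                           length_m = sqrt(disp[2]^2 + disp[3]^2))
  }
  do.call(rbind, out)
}
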