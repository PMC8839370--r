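#' Specify a synthetic walking assessment
#'
#' Builds the parameter set for [generate_walk()]. Defaults emulate the
#' standard assessment protocol: a two-minute walk recorded at 104 Hz by
#' three IMUs (both feet and the low back), with five-second stationary
#' standstills at both ends. Gait morphology parameters control the
#' vertical contact transients, swing-phase rotation bursts, stance-phase
#' quiescence, lumbar step periodicity and left-right asymmetry.
#'
#' Per-foot parameters (`stride_time_mean_s`, `stance_fraction`,
#' `stride_length_m`) accept a scalar or a `c(left = , right = )` pair.
#' Asymmetric gait is expressed through per-foot stance fractions and the
#' `step_phase` (fraction of the gait cycle at which the right foot
#' contacts after the left); per-foot stride times must imply the same
#' stride count within one stride over the walk, since the feet alternate.
#'
#' @param duration_s total recording length, seconds.
#' @param sample_rate_hz sampling rate, Hz.
#' @param stride_time_mean_s mean gait-cycle time per foot, seconds.
#' @param stride_time_cv coefficient of variation of stride times.
#' @param stance_fraction fraction of the stride spent in stance, per foot.
#' @param step_phase fraction of the left stride time after which the
#'   right foot contacts (0.5 = symmetric).
#' @param stride_length_m mean stride length per foot, metres.
#' @param stride_length_cv coefficient of variation of stride lengths.
#' @param impact_amplitude peak vertical foot acceleration at contact,
#'   m/s^2 (a wide stride-periodic pedestal plus a 50 ms transient).
#' @param swing_gyro_amplitude peak foot pitch rate during swing, deg/s.
#' @param ml_sway_amplitude medio-lateral acceleration sway amplitude at
#'   stride frequency, m/s^2 (drives the FFT stride-time prior).
#' @param foot_lift_m peak vertical foot displacement during swing, m.
#' @param lumbar_ap_amplitude peak lumbar anterior-posterior acceleration
#'   of the biphasic per-step pulse, m/s^2.
#' @param lumbar_vt_amplitude lumbar vertical acceleration amplitude at
#'   step frequency, m/s^2.
#' @param lumbar_ml_amplitude lumbar medio-lateral sway amplitude at
#'   stride frequency, m/s^2 (right positive during right steps).
#' @param lumbar_roll_gyro_amplitude lumbar roll rate amplitude, deg/s.
#' @param noise_sd_accel accelerometer white-noise SD, m/s^2.
#' @param noise_sd_gyro gyroscope white-noise SD, deg/s.
#' @param gyro_bias named list of per-sensor constant gyroscope bias
#'   3-vectors, deg/s.
#' @param standstill_bookend_s stationary period at each end, seconds.
#' @param mounting_yaw_deg named vector of sensor mounting yaw offsets.
#' @param attenuate_contacts list with `left`/`right` integer contact
#'   indices whose vertical contact waveform is scaled by
#'   `attenuation_factor` (emulates weak paretic-side contacts).
#' @param attenuation_factor scale applied to attenuated contacts.
#' @param turn_segments if `TRUE`, a 180-degree turn is inserted halfway
#'   (approximate; off by default).
#' @param height_m,paretic_side subject metadata passed through.
#' @param rng_seed integer seed; all randomness derives from it.
#' @return a `walk_spec` object.
#' @export
walk_spec <- function(duration_s = 120, sample_rate_hz = 104,
                      stride_time_mean_s = 1.2, stride_time_cv = 0.03,
                      stance_fraction = 0.6, step_phase = 0.5,
                      stride_length_m = 1.3, stride_length_cv = 0.03,
                      impact_amplitude = 10, swing_gyro_amplitude = 200,
                      ml_sway_amplitude = 0.5, foot_lift_m = 0.015,
                      lumbar_ap_amplitude = 1.5, lumbar_vt_amplitude = 1.0,
                      lumbar_ml_amplitude = 0.5,
                      lumbar_roll_gyro_amplitude = 5,
                      noise_sd_accel = 0.3, noise_sd_gyro = 1,
                      gyro_bias = list(left_foot = c(0.4, -0.2, 0.1),
                                       right_foot = c(-0.3, 0.1, 0.2),
                                       low_back = c(0.2, 0.3, -0.1)),
                      standstill_bookend_s = 5,
                      mounting_yaw_deg = c(left_foot = 0, right_foot = 0,
                                           low_back = 0),
                      attenuate_contacts = list(left = integer(0),
                                                right = integer(0)),
                      attenuation_factor = 1,
                      turn_segments = FALSE,
                      height_m = 1.75, paretic_side = "left",
                      rng_seed = 1L) {
  pair <- function(x, nm) {
    x <- if (length(x) == 1) c(left = unname(x), right = unname(x))
         else c(left = unname(x[["left"]]), right = unname(x[["right"]]))
    if (any(!is.finite(x))) validation_error(nm, "must be finite")
    x
  }
  spec <- list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    stride_time_mean_s = pair(stride_time_mean_s, "stride_time_mean_s"),
    stride_time_cv = stride_time_cv,
    stance_fraction = pair(stance_fraction, "stance_fraction"),
    step_phase = step_phase,
    stride_length_m = pair(stride_length_m, "stride_length_m"),
    stride_length_cv = stride_length_cv,
    impact_amplitude = impact_amplitude,
    swing_gyro_amplitude = swing_gyro_amplitude,
    ml_sway_amplitude = ml_sway_amplitude, foot_lift_m = foot_lift_m,
    lumbar_ap_amplitude = lumbar_ap_amplitude,
    lumbar_vt_amplitude = lumbar_vt_amplitude,
    lumbar_ml_amplitude = lumbar_ml_amplitude,
    lumbar_roll_gyro_amplitude = lumbar_roll_gyro_amplitude,
    noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
    gyro_bias = gyro_bias, standstill_bookend_s = standstill_bookend_s,
    mounting_yaw_deg = mounting_yaw_deg,
    attenuate_contacts = attenuate_contacts,
    attenuation_factor = attenuation_factor,
    turn_segments = turn_segments,
    height_m = height_m, paretic_side = paretic_side,
    rng_seed = as.integer(rng_seed))
  class(spec) <- "walk_spec"
  validate_walk_spec(spec)
  spec
}

validate_walk_spec <- function(s) {
  if (any(s$stride_time_mean_s <= 0))
    validation_error("stride_time_mean_s", "must be > 0 for both feet")
  if (any(s$stance_fraction <= 0 | s$stance_fraction >= 1))
    validation_error("stance_fraction", "must be in (0, 1)")
  if (s$duration_s <= 2 * s$standstill_bookend_s)
    validation_error("duration_s",
                     "must exceed twice the standstill bookend")
  if (s$sample_rate_hz <= 0)
    validation_error("sample_rate_hz", "must be > 0")
  if (s$noise_sd_accel < 0) validation_error("noise_sd_accel", "must be >= 0")
  if (s$noise_sd_gyro < 0) validation_error("noise_sd_gyro", "must be >= 0")
  if (s$stride_time_cv < 0) validation_error("stride_time_cv", "must be >= 0")
  if (s$step_phase <= 0 || s$step_phase >= 1)
    validation_error("step_phase", "must be in (0, 1)")
  # alternating feet: per-foot stride times must imply equal counts +/- 1
  walk <- s$duration_s - 2 * s$standstill_bookend_s - 1
  n <- floor(walk / s$stride_time_mean_s)
  if (abs(diff(n)) > 1)
    validation_error("stride_time_mean_s",
                     "left/right stride times imply stride counts differing by more than 1")
  invisible(s)
}

# raised-cosine pulse centred at tc with full width w, added onto y over t
add_pulse <- function(y, t, tc, w, amp, deriv = FALSE) {
  fs <- 1 / (t[2] - t[1])
  i0 <- max(1L, floor((tc - w / 2) * fs) + 1L)
  i1 <- min(length(y), ceiling((tc + w / 2) * fs) + 1L)
  if (i0 > i1) return(y)
  u <- t[i0:i1] - tc
  inside <- abs(u) <= w / 2
  val <- if (deriv) -amp * (pi / w) * sin(2 * pi * u / w) else
    amp * 0.5 * (1 + cos(2 * pi * u / w))
  y[i0:i1] <- y[i0:i1] + val * inside
  y
}

# cosine-tapered on/off window over [t0, t1]
taper_window <- function(t, t0, t1, ramp = 0.15) {
  w <- numeric(length(t))
  on <- t >= t0 & t <= t1
  w[on] <- 1
  up <- t >= t0 & t < t0 + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  dn <- t > t1 - ramp & t <= t1
  w[dn] <- 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  w
}

draw_intervals <- function(mean, cv, t_start, t_max) {
  times <- t_start
  repeat {
    z <- max(-3, min(3, rnorm(1)))
    step <- mean * (1 + cv * z)
    nxt <- times[length(times)] + step
    if (nxt > t_max) break
    times <- c(times, nxt)
  }
  times
}

#' Generate a synthetic three-sensor walking recording
#'
#' Produces raw IMU streams (3-axis accelerometer in m/s^2 including
#' gravity, 3-axis gyroscope in deg/s including constant bias and white
#' noise) for the left foot, right foot and low back, together with the
#' ground truth used by the tests: per-foot contact times, stance
#' intervals, stride lengths, and the stationary bounds of the walk.
#'
#' Foot vertical acceleration carries a stride-periodic pedestal peaking
#' exactly at each contact plus a 50 ms contact transient; swing phases
#' carry a biphasic pitch-rate burst (so the foot returns to its stance
#' attitude) and the anterior acceleration of a smooth swing velocity
#' profile whose integral is the stride length. Stance phases have zero
#' angular velocity by construction. The lumbar stream carries biphasic
#' anterior-posterior pulses at every (left and right) foot contact -- so
#' that the time-integrated, band-passed signal peaks at the contacts --
#' plus vertical step-frequency and medio-lateral stride-frequency
#' components, the latter positive (rightward) during right steps.
#' Signals are synthesised in the earth frame and rotated through the
#' instantaneous sensor attitude (swing pitch for the feet, roll sway for
#' the lumbar sensor, plus any mounting yaw), so attitude, gravity and
#' angular velocity are mutually consistent for the sensor-fusion filter.
#'
#' @param spec a [walk_spec()].
#' @return list with elements `recording` (a `raw_recording`) and
#'   `ground_truth` (a `ground_truth`).
#' @export
generate_walk <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  validate_walk_spec(spec)
  set.seed(spec$rng_seed)
  fs <- spec$sample_rate_hz
  g <- GRAVITY_MS2
  n <- round(spec$duration_s * fs)
  t <- (0:(n - 1)) / fs
  b <- spec$standstill_bookend_s
  walk0 <- b
  walk1 <- spec$duration_s - b

  Tm <- spec$stride_time_mean_s
  f_st <- spec$stance_fraction
  # keep contact pedestals and final stances inside the walk span
  lead <- pmax(0.25 * Tm + 0.2, 0.6)
  tail <- pmax(f_st * Tm + 0.25 * Tm + 0.1, 0.6)
  # the feet are mechanically coupled: both feet share the gait-cycle
  # sequence (cycle time = mean of the per-foot stride times, which the
  # +/- 1 stride-count invariant constrains to be nearly equal), with the
  # right contact placed step_phase into each cycle
  T_cycle <- mean(Tm)
  left <- draw_intervals(T_cycle, spec$stride_time_cv,
                         walk0 + max(lead), walk1 - max(tail))
  Tk_cycle <- c(diff(left), T_cycle)
  right <- left + spec$step_phase * Tk_cycle
  right <- right[right <= walk1 - max(tail)]
  contacts <- list(left = left, right = right)
  t0 <- c(left = left[1], right = right[1])

  win <- taper_window(t, walk0, walk1)
  streams <- list()
  gt_stance <- list(); gt_len <- list()

  for (foot in c("left", "right")) {
    cts <- contacts[[foot]]
    nc <- length(cts)
    Tk <- diff(cts)
    Tbar <- if (length(Tk)) mean(Tk) else Tm[[foot]]
    fstance <- f_st[[foot]]
    att <- rep(1, nc)
    ai <- spec$attenuate_contacts[[foot]]
    att[ai[ai >= 1 & ai <= nc]] <- spec$attenuation_factor

    vt <- numeric(n); ap <- numeric(n); gy_ml <- numeric(n)
    # contact pedestal + transient (vertical)
    for (k in seq_len(nc)) {
      Tloc <- if (k > 1) Tk[k - 1] else if (length(Tk)) Tk[1] else Tbar
      vt <- add_pulse(vt, t, cts[k], 0.5 * Tloc,
                      0.7 * spec$impact_amplitude * att[k])
      vt <- add_pulse(vt, t, cts[k], 0.05,
                      0.3 * spec$impact_amplitude * att[k])
    }
    # swing phases: pitch burst, anterior progression, vertical lift
    L <- spec$stride_length_m[[foot]] *
      (1 + spec$stride_length_cv * pmax(-3, pmin(3, rnorm(max(nc - 1, 0)))))
    stance <- cbind(cts, cts + fstance * c(Tk, Tbar))
    for (k in seq_len(max(nc - 1, 0))) {
      toe_off <- cts[k] + fstance * Tk[k]
      tau <- cts[k + 1] - toe_off
      idx <- which(t >= toe_off & t < cts[k + 1])
      s <- (t[idx] - toe_off) / tau
      u <- 2 * pi * s
      gy_ml[idx] <- gy_ml[idx] + spec$swing_gyro_amplitude * sin(u)
      V <- 2 * L[k] / tau
      ap[idx] <- ap[idx] + V * (pi / tau) * sin(u)
      vt[idx] <- vt[idx] + (2 * pi^2 * spec$foot_lift_m / tau^2) *
        (sin(u)^2 + cos(u) - cos(u)^2)
    }
    ml <- spec$ml_sway_amplitude *
      sin(2 * pi * (t - t0[[foot]]) / Tbar) * win
    streams[[paste0(foot, "_foot")]] <- assemble_stream(
      ap, ml, vt, gy_ml, axis = "pitch", t = t, fs = fs, g = g, spec = spec,
      sensor = paste0(foot, "_foot"))
    gt_stance[[foot]] <- unname(stance)
    gt_len[[foot]] <- as.numeric(L)
  }

  # lumbar stream: AP acceleration is the derivative of a zero-mean AP
  # velocity fluctuation peaking at every contact, so its time integral
  # has no baseline step at the walking onset
  all_cts <- sort(c(contacts$left, contacts$right))
  Tbar_all <- mean(c(diff(contacts$left), diff(contacts$right)))
  v_ap <- numeric(n)
  A_int <- spec$lumbar_ap_amplitude * 0.3 / pi
  for (tc in all_cts) v_ap <- add_pulse(v_ap, t, tc, 0.3, A_int)
  in_walk <- t >= walk0 & t <= walk1
  v_ap <- (v_ap - mean(v_ap[in_walk])) * win
  ap <- c(0, diff(v_ap, lag = 2) / 2, 0) * fs
  vt <- spec$lumbar_vt_amplitude *
    sin(2 * pi * 2 * (t - t0[["left"]]) / Tbar_all) * win
  ml <- spec$lumbar_ml_amplitude *
    sin(2 * pi * (t - t0[["right"]]) / Tbar_all) * win
  gy_roll <- spec$lumbar_roll_gyro_amplitude *
    sin(2 * pi * (t - t0[["left"]]) / Tbar_all) * win
  streams$low_back <- assemble_stream(
    ap, ml, vt, gy_roll, axis = "roll", t = t, fs = fs, g = g, spec = spec,
    sensor = "low_back")

  meta <- list(subject_id = "synthetic", session_id = "1",
               height_m = spec$height_m, paretic_side = spec$paretic_side,
               expected_duration_s = spec$duration_s)
  rec <- structure(list(streams = streams, sample_rate_hz = fs, meta = meta),
                   class = "raw_recording")
  gt <- structure(list(
    foot_contacts = lapply(contacts, as.numeric),
    stance_intervals = gt_stance,
    stride_lengths = gt_len,
    stationary_bounds = c(walk0, walk1),
    first_foot = "left",
    attenuated = spec$attenuate_contacts,
    spec = spec), class = "ground_truth")
  list(recording = rec, ground_truth = gt)
}

# rotate earth-frame specific force through the instantaneous attitude
# (single-axis sway + constant mounting yaw), add gravity, bias and noise
assemble_stream <- function(ap, ml, vt, gy_sway, axis, t, fs, g, spec,
                            sensor) {
  n <- length(t)
  if (isTRUE(spec$turn_segments)) {
    mid <- spec$duration_s / 2
    heading <- pi * pmin(1, pmax(0, (t - (mid - 1)) / 2))
    yaw_rate <- c(0, diff(heading)) * fs * 180 / pi
  } else {
    heading <- numeric(n)
    yaw_rate <- numeric(n)
  }
  # earth frame: x anterior, y left, z up; ml is right-positive
  ex <- cos(heading) * ap - sin(heading) * (-ml)
  ey <- sin(heading) * ap + cos(heading) * (-ml)
  ez <- vt + g
  theta <- cumtrapz(gy_sway * pi / 180, 1 / fs)   # sway angle, rad
  if (axis == "pitch") {
    sx <- cos(theta) * ex - sin(theta) * ez
    sy <- ey
    sz <- sin(theta) * ex + cos(theta) * ez
    gyr <- cbind(0, gy_sway, 0)
  } else {
    sx <- ex
    sy <- cos(theta) * ey + sin(theta) * ez
    sz <- -sin(theta) * ey + cos(theta) * ez
    gyr <- cbind(gy_sway, 0, 0)
  }
  gyr[, 3] <- gyr[, 3] + yaw_rate
  acc <- cbind(sx, sy, sz)
  psi <- spec$mounting_yaw_deg[[sensor]] * pi / 180
  if (psi != 0) {
    Rz <- rot_z(psi)
    acc <- acc %*% Rz          # x' = t(Rz) %*% x, row-wise
    gyr <- gyr %*% Rz
  }
  bias <- spec$gyro_bias[[sensor]] %||% c(0, 0, 0)
  acc <- acc + matrix(rnorm(3 * n, 0, spec$noise_sd_accel), n, 3)
  gyr <- gyr + matrix(rnorm(3 * n, 0, spec$noise_sd_gyro), n, 3) +
    matrix(bias, n, 3, byrow = TRUE)
  colnames(acc) <- c("ax", "ay", "az")
  colnames(gyr) <- c("gx", "gy", "gz")
  structure(list(accel = acc, gyro = gyr, sample_rate_hz = fs,
                 placement = sensor), class = "imu_stream")
}

#' @export
print.walk_spec <- function(x, ...) {
  cat("<walk_spec>", x$duration_s, "s @", x$sample_rate_hz, "Hz;",
      "stride", paste(round(x$stride_time_mean_s, 3), collapse = "/"),
      "s; bookends", x$standstill_bookend_s, "s; seed", x$rng_seed, "\n")
  invisible(x)
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$streams[[1]]$accel)
  cat("<raw_recording>", length(x$streams), "sensors,",
      n, "samples @", x$sample_rate_hz, "Hz (",
      round(n / x$sample_rate_hz, 1), "s )\n")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> contacts L/R:",
      length(x$foot_contacts$left), "/", length(x$foot_contacts$right),
      "; walk", x$stationary_bounds[1], "-", x$stationary_bounds[2], "s\n")
  invisible(x)
}

#' Specify a synthetic test-retest cohort
#'
#' Variance structure for a feature measured on `n_subjects` across
#' `sessions` repeated assessments: each observation is
#' `feature_mean + subject effect + session noise`, with the subject
#' effect drawn once per subject (SD `between_subject_sd`) and the noise
#' drawn per observation (SD `within_subject_sd`). The implied analytic
#' intraclass correlation is `between^2 / (between^2 + within^2)`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sessions number of sessions per subject (>= 2).
#' @param between_subject_sd,within_subject_sd variance components, in
#'   feature units; must be non-negative and not both zero.
#' @param feature_mean grand mean, feature units.
#' @param rng_seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, sessions = 2, between_subject_sd = 1,
                        within_subject_sd = 0.5, feature_mean = 0,
                        rng_seed = 1L) {
  if (n_subjects < 2) validation_error("n_subjects", "must be >= 2")
  if (sessions < 2) validation_error("sessions", "must be >= 2")
  if (between_subject_sd < 0)
    validation_error("between_subject_sd", "must be >= 0")
  if (within_subject_sd < 0)
    validation_error("within_subject_sd", "must be >= 0")
  if (between_subject_sd == 0 && within_subject_sd == 0)
    validation_error("between_subject_sd",
                     "between- and within-subject SD cannot both be zero")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions = as.integer(sessions),
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 feature_mean = feature_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Draw a test-retest feature matrix from a cohort specification
#'
#' @param cohort a [cohort_spec()].
#' @return numeric matrix (subjects x sessions) with attribute
#'   `analytic_icc`, the population intraclass correlation implied by the
#'   variance components.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$rng_seed)
  n <- cohort$n_subjects; k <- cohort$sessions
  subj <- rnorm(n, 0, cohort$between_subject_sd)
  m <- cohort$feature_mean + matrix(subj, n, k) +
    matrix(rnorm(n * k, 0, cohort$within_subject_sd), n, k)
  rownames(m) <- sprintf("S%02d", seq_len(n))
  colnames(m) <- sprintf("session%d", seq_len(k))
  attr(m, "analytic_icc") <- cohort$between_subject_sd^2 /
    (cohort$between_subject_sd^2 + cohort$within_subject_sd^2)
  m
}
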