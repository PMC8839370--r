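#' The 166-feature gait catalogue
#'
#' Returns the catalogue manifest: one row per feature with its domain
#' (`spatio_temporal`, `frequency`, `complexity`, `asymmetry`,
#' `general`), source sensor (`left_foot`, `right_foot`, `low_back`,
#' `combined`), units, and normalisation (`none`, `height`,
#' `paretic_reference`). The catalogue holds exactly 166 uniquely named
#' features: 56 spatio-temporal, 26 frequency, 63 complexity and 14
#' asymmetry, plus 7 general walk descriptors; per sensor, 46 are
#' computed from each foot, 54 from the low back and 20 are combined.
#'
#' @return data frame with columns `name`, `domain`, `source`, `units`,
#'   `normalisation`.
#' @export
feature_catalogue <- function() {
  rows <- list()
  add <- function(name, domain, source, units, normalisation = "none")
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, domain = domain, source = source, units = units,
      normalisation = normalisation)

  for (foot in c("left", "right")) {
    p <- paste0(foot, "_foot_")
    src <- paste0(foot, "_foot")
    for (q in c("stride_time", "stance_time", "swing_time", "step_time"))
      for (s in c("mean", "sd", "cv"))
        add(paste0(p, q, "_", s), "spatio_temporal", src,
            if (s == "cv") "%" else "s")
    for (s in c("mean", "sd", "cv"))
      add(paste0(p, "stride_length_", s), "spatio_temporal", src,
          if (s == "cv") "%" else "m")
    add(paste0(p, "stride_length_norm"), "spatio_temporal", src,
        "stride/height", "height")
    for (s in c("mean", "sd", "cv"))
      add(paste0(p, "stride_velocity_", s), "spatio_temporal", src,
          if (s == "cv") "%" else "m/s")
    add(paste0(p, "stride_velocity_norm"), "spatio_temporal", src,
        "height/s", "height")
    add(paste0(p, "cadence"), "spatio_temporal", src, "steps/min")
  }
  for (q in c("stride_time_left", "stride_time_right", "step_time_left",
              "step_time_right"))
    for (s in c("mean", "sd", "cv"))
      add(paste0("lb_", q, "_", s), "spatio_temporal", "low_back",
          if (s == "cv") "%" else "s")
  add("lb_cadence", "spatio_temporal", "low_back", "steps/min")
  add("lb_stride_time_mean", "spatio_temporal", "low_back", "s")

  for (foot in c("left", "right")) {
    p <- paste0(foot, "_foot_vt_")
    src <- paste0(foot, "_foot")
    add(paste0(p, "dom_freq"), "frequency", src, "Hz")
    add(paste0(p, "dom_amp"), "frequency", src, "m/s^2")
    add(paste0(p, "dom_width"), "frequency", src, "Hz")
    add(paste0(p, "dom_density"), "frequency", src, "fraction")
  }
  for (ax in c("vt", "ml", "ap")) {
    p <- paste0("lb_", ax, "_")
    add(paste0(p, "dom_freq"), "frequency", "low_back", "Hz")
    add(paste0(p, "dom_amp"), "frequency", "low_back", "m/s^2")
    add(paste0(p, "dom_width"), "frequency", "low_back", "Hz")
    add(paste0(p, "dom_density"), "frequency", "low_back", "fraction")
    add(paste0(p, "harmonicity"), "frequency", "low_back", "fraction")
  }
  for (ax in c("vt", "ml", "ap"))
    add(paste0("lb_harmonic_ratio_", ax), "frequency", "low_back", "ratio")

  for (sensor in c("left_foot", "right_foot", "lb")) {
    src <- if (sensor == "lb") "low_back" else sensor
    for (ax in c("vt", "ml", "ap")) {
      p <- paste0(sensor, "_accel_", ax, "_")
      add(paste0(p, "sampen"), "complexity", src, "nat")
      add(paste0(p, "apen"), "complexity", src, "nat")
      add(paste0(p, "stride_autocorr"), "complexity", src, "correlation")
      add(paste0(p, "stride_autocov"), "complexity", src, "(m/s^2)^2")
      add(paste0(p, "lyap"), "complexity", src, "1/stride")
    }
    for (ax in c("vt", "ml", "ap")) {
      p <- paste0(sensor, "_gyro_", ax, "_")
      add(paste0(p, "sampen"), "complexity", src, "nat")
      add(paste0(p, "lyap"), "complexity", src, "1/stride")
    }
  }

  for (q in c("stride_time", "stance_time", "swing_time", "step_time",
              "stride_length", "stride_velocity", "swing_stance_ratio")) {
    add(paste0("asym_", q, "_si"), "asymmetry", "combined", "%",
        "paretic_reference")
    add(paste0("asym_", q, "_ratio"), "asymmetry", "combined", "ratio",
        "paretic_reference")
  }

  add("walk_duration_s", "general", "combined", "s")
  add("total_strides", "general", "combined", "count")
  add("distance_m", "general", "combined", "m")
  add("gait_speed", "general", "combined", "m/s")
  add("gait_speed_norm", "general", "combined", "height/s", "height")
  add("cadence_overall", "general", "combined", "steps/min")
  add("lb_step_count", "general", "low_back", "count")

  catal <- do.call(rbind, rows)
  stopifnot(nrow(catal) == 166, !anyDuplicated(catal$name),
            sum(catal$domain == "spatio_temporal") == 56,
            sum(catal$domain == "frequency") == 26,
            sum(catal$domain == "complexity") == 63,
            sum(catal$domain == "asymmetry") == 14,
            sum(catal$source == "left_foot") == 46,
            sum(catal$source == "right_foot") == 46,
            sum(catal$source == "low_back") == 54,
            sum(catal$source == "combined") == 20)
  catal
}

#' Write the feature catalogue as a JSON manifest
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(path) {
  jsonlite::write_json(feature_catalogue(), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

# mean of per-block statistics over consecutive blocks of `block` strides;
# the final partial block is dropped
block_stats <- function(x, block = 10) {
  x <- x[is.finite(x)]
  nb <- as.integer(length(x) %/% block)
  if (nb < 1)
    return(list(mean = NA_real_, sd = NA_real_, cv = NA_real_, blocks = 0L))
  xb <- matrix(x[seq_len(nb * block)], nrow = block)
  bm <- colMeans(xb)
  bs <- apply(xb, 2, sd)
  list(mean = mean(bm), sd = mean(bs), cv = mean(100 * bs / bm),
       blocks = nb)
}

paretic_foot <- function(paretic_side) {
  if (identical(paretic_side, "left") || identical(paretic_side, "right"))
    paretic_side else "left"   # undefined (unknown/both): left-foot fallback
}

# per-stride interval series for one foot, seconds
stride_series <- function(events, other_events, disp, fs) {
  cts <- events$contacts
  stride_t <- diff(cts) / fs
  stance_t <- (events$stance[, 2] - events$stance[, 1]) / fs
  nst <- min(length(stride_t), length(stance_t))
  swing_t <- stride_t[seq_len(nst)] - stance_t[seq_len(nst)]
  # step time: from the preceding contralateral contact to each contact
  step_t <- vapply(cts, function(ct) {
    prev <- other_events$contacts[other_events$contacts < ct]
    if (length(prev)) (ct - max(prev)) / fs else NA_real_
  }, 0)
  step_t <- step_t[is.finite(step_t)]
  len <- disp$length_m
  vel <- len / ((disp$end_sample - disp$start_sample) / fs)
  list(stride_time = stride_t, stance_time = stance_t[seq_len(nst)],
       swing_time = swing_t, step_time = step_t,
       stride_length = len, stride_velocity = vel)
}

#' Spatio-temporal gait features
#'
#' Per-foot stride, stance, swing and step times, stride length and
#' velocity (from the ZUPT displacements), each summarised as the mean of
#' per-`block`-stride block means (mean), mean of per-block SDs (sd) and
#' mean of per-block CVs (cv, %), the final partial block being dropped;
#' length and velocity additionally height-normalised; cadence per foot;
#' and the low-back equivalents from the lumbar-matched contacts.
#'
#' @param events_left,events_right foot `gait_events`.
#' @param disp_left,disp_right ZUPT displacement frames
#'   ([zupt_stride_displacement()]).
#' @param lb_events a `lowback_events`, or `NULL` (features missing).
#' @param meta subject metadata list (`height_m`, `paretic_side`).
#' @param sample_rate_hz sampling rate, Hz.
#' @param block strides per summary block.
#' @return named list of feature values; missing features are `NA` with
#'   reasons in `attr(, "reasons")`.
#' @export
spatio_temporal_features <- function(events_left, events_right, disp_left,
                                     disp_right, lb_events, meta,
                                     sample_rate_hz, block = 10) {
  out <- list(); reasons <- list()
  height <- meta$height_m %||% NA_real_
  ev <- list(left = events_left, right = events_right)
  dp <- list(left = disp_left, right = disp_right)
  for (foot in c("left", "right")) {
    p <- paste0(foot, "_foot_")
    other <- ev[[setdiff(c("left", "right"), foot)]]
    if (is.null(ev[[foot]]) || length(ev[[foot]]$contacts) < block + 1) {
      for (q in c("stride_time", "stance_time", "swing_time", "step_time",
                  "stride_length", "stride_velocity"))
        for (s in c("mean", "sd", "cv")) {
          out[[paste0(p, q, "_", s)]] <- NA_real_
          reasons[[paste0(p, q, "_", s)]] <- "insufficient_strides"
        }
      for (nm in c("stride_length_norm", "stride_velocity_norm", "cadence")) {
        out[[paste0(p, nm)]] <- NA_real_
        reasons[[paste0(p, nm)]] <- "insufficient_strides"
      }
      next
    }
    ser <- stride_series(ev[[foot]], other, dp[[foot]], sample_rate_hz)
    for (q in names(ser)) {
      bs <- block_stats(ser[[q]], block)
      out[[paste0(p, q, "_mean")]] <- bs$mean
      out[[paste0(p, q, "_sd")]] <- bs$sd
      out[[paste0(p, q, "_cv")]] <- bs$cv
      if (bs$blocks == 0)
        for (s in c("mean", "sd", "cv"))
          reasons[[paste0(p, q, "_", s)]] <- "insufficient_strides"
    }
    out[[paste0(p, "stride_length_norm")]] <-
      out[[paste0(p, "stride_length_mean")]] / height
    out[[paste0(p, "stride_velocity_norm")]] <-
      out[[paste0(p, "stride_velocity_mean")]] / height
    out[[paste0(p, "cadence")]] <- 120 / out[[paste0(p, "stride_time_mean")]]
  }

  lb_names <- c(paste0("lb_", rep(c("stride_time_left", "stride_time_right",
                                    "step_time_left", "step_time_right"),
                                  each = 3),
                       "_", c("mean", "sd", "cv")),
                "lb_cadence", "lb_stride_time_mean")
  if (is.null(lb_events)) {
    for (nm in lb_names) { out[[nm]] <- NA_real_
      reasons[[nm]] <- "lowback_events_unavailable" }
  } else {
    fs <- sample_rate_hz
    merged <- sort(c(lb_events$contacts$left, lb_events$contacts$right))
    for (foot in c("left", "right")) {
      cts <- lb_events$contacts[[foot]]
      other <- lb_events$contacts[[setdiff(c("left", "right"), foot)]]
      stride_t <- diff(cts) / fs
      step_t <- vapply(cts, function(ct) {
        prev <- other[other < ct]
        if (length(prev)) (ct - max(prev)) / fs else NA_real_
      }, 0)
      for (q in list(c("stride_time", "stride"), c("step_time", "step"))) {
        x <- if (q[2] == "stride") stride_t else step_t[is.finite(step_t)]
        bs <- block_stats(x, block)
        for (s in c("mean", "sd", "cv")) {
          nm <- paste0("lb_", q[1], "_", foot, "_", s)
          out[[nm]] <- bs[[s]]
          if (bs$blocks == 0) reasons[[nm]] <- "insufficient_strides"
        }
      }
    }
    pooled <- c(diff(lb_events$contacts$left),
                diff(lb_events$contacts$right)) / fs
    out$lb_stride_time_mean <- if (length(pooled)) mean(pooled) else NA_real_
    out$lb_cadence <- if (length(merged) > 1)
      60 * (length(merged) - 1) / ((max(merged) - min(merged)) / fs)
      else NA_real_
  }
  attr(out, "reasons") <- reasons
  out
}

#' Welch averaged periodogram
#'
#' Hann-windowed, mean-removed, 50%-overlapping segments; one-sided
#' power spectral density.
#'
#' @param x series. @param fs sampling rate, Hz.
#' @param segment_s segment length, seconds.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, segment_s = 10) {
  nseg <- min(length(x), round(segment_s * fs))
  step <- max(1, nseg %/% 2)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  acc <- numeric(nseg %/% 2)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(nseg %/% 2)]
  }
  psd <- 2 * acc / (length(starts) * fs * sum(w^2))
  freq <- (seq_len(nseg %/% 2) - 1) * fs / nseg
  list(freq = freq, psd = psd)
}

dominant_peak_features <- function(x, fs, segment_s, band = c(0.3, 10),
                                   density_halfwidth = 0.25,
                                   peak_factor = 3) {
  ps <- welch_psd(x, fs, segment_s)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  freq <- ps$freq[sel]; psd <- ps$psd[sel]
  if (length(psd) < 3 || max(psd) <= 0 ||
      max(psd) < peak_factor * median(psd))
    return(NULL)
  i <- which.max(psd)
  f0 <- freq[i]
  df <- freq[2] - freq[1]
  # half-power width: contiguous bins around the peak above half maximum
  lo <- i; while (lo > 1 && psd[lo - 1] >= 0.5 * psd[i]) lo <- lo - 1
  hi <- i; while (hi < length(psd) && psd[hi + 1] >= 0.5 * psd[i]) hi <- hi + 1
  width <- (hi - lo + 1) * df
  nb <- abs(freq - f0) <= density_halfwidth
  density <- sum(psd[nb]) / sum(psd)
  amp <- sqrt(2 * sum(psd[nb]) * df)
  list(dom_freq = f0, dom_amp = amp, dom_width = width,
       dom_density = density, psd = ps)
}

harmonicity_index <- function(ps, f0, n_harm = 6) {
  df <- ps$freq[2] - ps$freq[1]
  hp <- vapply(seq_len(n_harm), function(h) {
    sel <- abs(ps$freq - h * f0) <= df
    if (any(sel)) max(ps$psd[sel]) else 0
  }, 0)
  if (sum(hp) == 0) return(NA_real_)
  hp[1] / sum(hp)
}

harmonic_ratio <- function(x, fs, stride_freq, n_harm = 20,
                           even_over_odd = TRUE) {
  n <- length(x)
  mag <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  amp <- vapply(seq_len(n_harm), function(h)
    mag[which.min(abs(freq - h * stride_freq))], 0)
  ev <- sum(amp[seq(2, n_harm, by = 2)])
  od <- sum(amp[seq(1, n_harm, by = 2)])
  if (even_over_odd) ev / od else od / ev
}

#' Frequency-domain gait features
#'
#' Per sensor and axis: dominant frequency, its amplitude, half-power
#' width, and density (power within +/- `density_halfwidth` Hz of the
#' dominant peak over total in-band power) from a Welch periodogram;
#' for the lumbar sensor additionally the index of harmonicity (dominant
#' power over the first six harmonics) and the harmonic ratio (even/odd
#' harmonics of the stride frequency; odd/even for ML).
#'
#' @param oriented named list of `oriented_signal`s (`left_foot`,
#'   `right_foot`, `low_back`).
#' @param walk_bounds walking-span sample bounds.
#' @param stride_freq_hz stride frequency from the foot prior, Hz.
#' @param segment_s Welch segment length, seconds.
#' @param min_duration_s minimal walking duration, seconds.
#' @param density_halfwidth half-width of the dominant band, Hz.
#' @return named list of feature values with missing reasons.
#' @export
frequency_features <- function(oriented, walk_bounds, stride_freq_hz,
                               segment_s = 10, min_duration_s = 30,
                               density_halfwidth = 0.25) {
  out <- list(); reasons <- list()
  idx <- walk_bounds[1]:walk_bounds[2]
  fs <- oriented$low_back$sample_rate_hz
  nm_feet <- c("dom_freq", "dom_amp", "dom_width", "dom_density")
  too_short <- length(idx) < min_duration_s * fs

  set_missing <- function(names, why)
    for (nm in names) { out[[nm]] <<- NA_real_; reasons[[nm]] <<- why }

  for (foot in c("left_foot", "right_foot")) {
    nms <- paste0(gsub("_foot", "_foot_vt_", foot), nm_feet)
    if (too_short || is.null(oriented[[foot]])) {
      set_missing(nms, if (too_short) "insufficient_duration"
                  else "sensor_unavailable")
      next
    }
    dp <- dominant_peak_features(oriented[[foot]]$accel[idx, "vt"], fs,
                                 segment_s,
                                 density_halfwidth = density_halfwidth)
    if (is.null(dp)) set_missing(nms, "flat_spectrum")
    else for (k in nm_feet) out[[paste0(gsub("_foot", "_foot_vt_", foot), k)]] <- dp[[k]]
  }

  for (ax in c("vt", "ml", "ap")) {
    p <- paste0("lb_", ax, "_")
    nms <- c(paste0(p, c(nm_feet, "harmonicity")),
             paste0("lb_harmonic_ratio_", ax))
    if (too_short || is.null(oriented$low_back)) {
      set_missing(nms, if (too_short) "insufficient_duration"
                  else "sensor_unavailable")
      next
    }
    x <- oriented$low_back$accel[idx, ax]
    dp <- dominant_peak_features(x, fs, segment_s,
                                 density_halfwidth = density_halfwidth)
    if (is.null(dp)) { set_missing(nms, "flat_spectrum"); next }
    for (k in nm_feet) out[[paste0(p, k)]] <- dp[[k]]
    out[[paste0(p, "harmonicity")]] <- harmonicity_index(dp$psd, dp$dom_freq)
    out[[paste0("lb_harmonic_ratio_", ax)]] <-
      if (is.finite(stride_freq_hz))
        harmonic_ratio(x, fs, stride_freq_hz,
                       even_over_odd = (ax != "ml"))
      else NA_real_
  }
  attr(out, "reasons") <- reasons
  out
}

# time-normalise the first n_strides strides to samples_per_stride samples
time_normalize_strides <- function(x, contacts, n_strides,
                                   samples_per_stride) {
  segs <- vector("list", n_strides)
  for (k in seq_len(n_strides)) {
    seg <- x[contacts[k]:contacts[k + 1]]
    segs[[k]] <- approx(seq_along(seg), seg,
                        xout = seq(1, length(seg),
                                   length.out = samples_per_stride))$y
  }
  unlist(segs)
}

lagged_autocov <- function(x, lag) {
  n <- length(x)
  xc <- x - mean(x)
  acv <- sum(xc[seq_len(n - lag)] * xc[(lag + 1):n]) / (n - lag)
  list(autocov = acv, autocorr = acv / (sum(xc^2) / n))
}

lyapunov_exponent <- function(x, samples_per_stride, dim = 5,
                              delay_frac = 0.25, fit_frac = 0.5) {
  tau <- max(1L, round(delay_frac * samples_per_stride))
  K <- round(fit_frac * samples_per_stride)
  curve <- lyap_divergence(x, dim, tau, samples_per_stride, K)
  if (length(curve) == 0 || all(!is.finite(curve))) return(NA_real_)
  k <- which(is.finite(curve)) - 1L
  fit <- lm(curve[k + 1L] ~ k)
  unname(coef(fit)[2]) * samples_per_stride   # log divergence per stride
}

#' Complexity (nonlinear dynamics) gait features
#'
#' Computed on exactly `n_strides` strides (the first ones available),
#' each time-normalised to `samples_per_stride` samples. Per axis of the
#' sensor's acceleration: sample entropy and approximate entropy
#' (m = 2, r = 0.2 x SD), stride-lagged autocorrelation and unbiased
#' autocovariance, and the largest Lyapunov exponent (Rosenstein
#' divergence slope over half a stride; embedding dimension 5, delay a
#' quarter stride). Per gyroscope axis: sample entropy and Lyapunov
#' exponent.
#'
#' @param oriented `oriented_signal` of the sensor.
#' @param contacts stride-defining contact samples for this sensor.
#' @param prefix feature-name prefix (`left_foot`, `right_foot`, `lb`).
#' @param n_strides fixed analysis window, strides.
#' @param samples_per_stride time-normalised samples per stride.
#' @return named list of feature values with missing reasons.
#' @export
complexity_features <- function(oriented, contacts, prefix,
                                n_strides = 25, samples_per_stride = 100) {
  out <- list(); reasons <- list()
  axes <- c("vt", "ml", "ap")
  acc_stats <- c("sampen", "apen", "stride_autocorr", "stride_autocov",
                 "lyap")
  gyr_stats <- c("sampen", "lyap")
  all_names <- c(
    as.vector(t(outer(paste0(prefix, "_accel_", axes, "_"), acc_stats,
                      paste0))),
    as.vector(t(outer(paste0(prefix, "_gyro_", axes, "_"), gyr_stats,
                      paste0))))
  if (is.null(contacts) || length(contacts) < n_strides + 1) {
    for (nm in all_names) { out[[nm]] <- NA_real_
      reasons[[nm]] <- "insufficient_strides" }
    attr(out, "reasons") <- reasons
    return(out)
  }
  for (part in c("accel", "gyro")) {
    sig <- oriented[[part]]
    stats <- if (part == "accel") acc_stats else gyr_stats
    for (ax in axes) {
      x <- time_normalize_strides(sig[, ax], contacts, n_strides,
                                  samples_per_stride)
      r <- 0.2 * sd(x)
      p <- paste0(prefix, "_", part, "_", ax, "_")
      if ("sampen" %in% stats)
        out[[paste0(p, "sampen")]] <- sample_entropy(x, 2L, r)
      if ("apen" %in% stats)
        out[[paste0(p, "apen")]] <- approx_entropy(x, 2L, r)
      if ("stride_autocorr" %in% stats) {
        ac <- lagged_autocov(x, samples_per_stride)
        out[[paste0(p, "stride_autocorr")]] <- ac$autocorr
        out[[paste0(p, "stride_autocov")]] <- ac$autocov
      }
      if ("lyap" %in% stats)
        out[[paste0(p, "lyap")]] <- lyapunov_exponent(x, samples_per_stride)
    }
  }
  attr(out, "reasons") <- reasons
  out
}

#' Gait asymmetry features
#'
#' For each of seven quantities (stride, stance, swing and step time,
#' stride length, stride velocity, and the swing/stance ratio), the
#' symmetry index `SI = |P - NP| / (0.5 (P + NP)) x 100` and the
#' symmetry ratio `P / NP`, where P is the paretic side (left-foot
#' fallback when the paretic side is unknown or both).
#'
#' @param st spatio-temporal partial ([spatio_temporal_features()]).
#' @param meta subject metadata (`paretic_side`).
#' @return named list of the 14 asymmetry features with missing reasons.
#' @export
asymmetry_features <- function(st, meta) {
  out <- list(); reasons <- list()
  p_side <- paretic_foot(meta$paretic_side %||% "unknown")
  np_side <- setdiff(c("left", "right"), p_side)
  quantities <- c("stride_time", "stance_time", "swing_time", "step_time",
                  "stride_length", "stride_velocity")
  val <- function(side, q) {
    v <- if (q == "swing_stance_ratio")
      st[[paste0(side, "_foot_swing_time_mean")]] /
        st[[paste0(side, "_foot_stance_time_mean")]]
    else st[[paste0(side, "_foot_", q, "_mean")]]
    if (length(v) != 1) NA_real_ else v
  }
  for (q in c(quantities, "swing_stance_ratio")) {
    P <- val(p_side, q); NP <- val(np_side, q)
    nm_si <- paste0("asym_", q, "_si")
    nm_r <- paste0("asym_", q, "_ratio")
    if (!is.finite(P) || !is.finite(NP)) {
      out[[nm_si]] <- NA_real_; out[[nm_r]] <- NA_real_
      reasons[[nm_si]] <- reasons[[nm_r]] <- "missing_foot_features"
    } else {
      out[[nm_si]] <- abs(P - NP) / (0.5 * (P + NP)) * 100
      out[[nm_r]] <- P / NP
    }
  }
  attr(out, "reasons") <- reasons
  out
}

#' General walk descriptors
#'
#' @param events_left,events_right foot `gait_events`.
#' @param disp_left,disp_right ZUPT displacement frames.
#' @param lb_events `lowback_events` or `NULL`.
#' @param walk_bounds walking-span sample bounds.
#' @param meta subject metadata.
#' @param sample_rate_hz sampling rate, Hz.
#' @return named list of the 7 general features.
#' @export
general_features <- function(events_left, events_right, disp_left,
                             disp_right, lb_events, walk_bounds, meta,
                             sample_rate_hz) {
  out <- list(); reasons <- list()
  dur <- (walk_bounds[2] - walk_bounds[1] + 1) / sample_rate_hz
  out$walk_duration_s <- dur
  n_l <- max(length(events_left$contacts) - 1, 0)
  n_r <- max(length(events_right$contacts) - 1, 0)
  out$total_strides <- n_l + n_r
  dist <- mean(c(sum(disp_left$length_m), sum(disp_right$length_m)))
  out$distance_m <- dist
  out$gait_speed <- dist / dur
  out$gait_speed_norm <- out$gait_speed / (meta$height_m %||% NA_real_)
  steps <- sort(c(events_left$contacts, events_right$contacts))
  out$cadence_overall <- if (length(steps) > 1)
    60 * (length(steps) - 1) / ((max(steps) - min(steps)) / sample_rate_hz)
    else NA_real_
  if (is.null(lb_events)) {
    out$lb_step_count <- NA_real_
    reasons$lb_step_count <- "lowback_events_unavailable"
  } else {
    out$lb_step_count <- length(lb_events$contacts$left) +
      length(lb_events$contacts$right)
  }
  attr(out, "reasons") <- reasons
  out
}

#' Assemble partial feature lists into a feature vector
#'
#' Merges the per-domain partials, checks the result against the
#' catalogue (exactly 166 keys, per-domain counts 56/26/63/14 + 7), and
#' carries missing values with their reason codes.
#'
#' @param ... named partial feature lists (with optional `reasons`
#'   attributes).
#' @param catalogue the feature catalogue.
#' @param meta assessment metadata carried along.
#' @return a `feature_vector`: data frame `name, value, domain, source`
#'   with attributes `reasons` and `meta`.
#' @export
assemble_features <- function(..., catalogue = feature_catalogue(),
                              meta = list()) {
  partials <- list(...)
  values <- list(); reasons <- list()
  for (p in partials) {
    r <- attr(p, "reasons") %||% list()
    for (nm in names(p)) values[[nm]] <- p[[nm]]
    for (nm in names(r)) reasons[[nm]] <- r[[nm]]
  }
  extra <- setdiff(names(values), catalogue$name)
  lacking <- setdiff(catalogue$name, names(values))
  if (length(extra) || length(lacking))
    abort(sprintf(
      "catalogue mismatch: %d unknown, %d absent feature(s) [%s]",
      length(extra), length(lacking),
      paste(utils::head(c(extra, lacking), 5), collapse = ", ")),
      "gaitreliab_catalogue_error")
  vec <- vapply(catalogue$name, function(nm) {
    v <- values[[nm]]
    if (is.null(v) || !is.finite(v)) NA_real_ else as.numeric(v)
  }, 0)
  for (nm in catalogue$name[is.na(vec)])
    if (is.null(reasons[[nm]])) reasons[[nm]] <- "not_computed"
  out <- data.frame(name = catalogue$name, value = unname(vec),
                    domain = catalogue$domain, source = catalogue$source)
  structure(out, reasons = reasons, meta = meta,
            class = c("feature_vector", "data.frame"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>", nrow(x), "features;",
      sum(is.na(x$value)), "missing\n")
  tab <- table(x$domain[!is.na(x$value)])
  for (d in names(tab)) cat(sprintf("  %-16s %d\n", d, tab[[d]]))
  invisible(x)
}
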