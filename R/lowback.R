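#' Integrate and band-pass the lumbar anterior-posterior acceleration
#'
#' The AP acceleration is integrated over time (trapezoidal) and filtered
#' with a second-order Butterworth band-pass, applied forward and
#' backward (zero phase), so peaks in the result align with foot
#' contacts rather than lagging them.
#'
#' @param oriented_lowback an `oriented_signal` of the lumbar sensor.
#' @param band pass band, Hz.
#' @param order filter order.
#' @return filtered series, same length as the input.
#' @export
bandpass_ap <- function(oriented_lowback, band = c(0.25, 15), order = 2) {
  fs <- oriented_lowback$sample_rate_hz
  v <- cumtrapz(oriented_lowback$accel[, "ap"], 1 / fs)
  bw <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bw, v))
}

#' Detect the first foot contact in the processed lumbar signal
#'
#' Peak detection with a minimal distance of `distance_factor` stride
#' times and a minimal height of mean + SD of the processed AP signal;
#' the first qualifying peak is the first contact.
#'
#' @param filtered_ap output of [bandpass_ap()] over the walking span.
#' @param prior the foot-derived `stride_prior`.
#' @param sample_rate_hz sampling rate, Hz.
#' @param distance_factor minimal peak spacing, in stride-time priors.
#' @return first contact sample index.
#' @export
detect_first_contact <- function(filtered_ap, prior, sample_rate_hz,
                                 distance_factor = 0.75) {
  peaks <- find_peaks(filtered_ap,
                      height = mean(filtered_ap) + sd(filtered_ap),
                      distance = distance_factor *
                        prior$average_stride_time_s * sample_rate_hz)
  if (length(peaks) == 0)
    abort("no contact peak found in low-back signal",
          "gaitreliab_lowback_error")
  peaks[1]
}

#' Lateralise the first low-back contact and match all strides
#'
#' The sign of the mean medio-lateral acceleration over the first step
#' (positive = rightward sway) assigns the first contact to a foot. The
#' corresponding foot's inter-contact intervals are then projected
#' forward from that anchor, each projected contact snapped to the
#' nearest local maximum of the processed AP signal within a tolerance
#' of the projected interval. The other foot is anchored by a windowed
#' peak search between the first and second matched contact and matched
#' the same way.
#'
#' @param filtered_ap processed lumbar AP series (walking span).
#' @param ml_accel lumbar ML acceleration (same span, right positive).
#' @param foot_events_left,foot_events_right `gait_events` of the feet,
#'   with contact indices in the same sample frame as `filtered_ap`.
#' @param first_contact sample index from [detect_first_contact()].
#' @param sample_rate_hz sampling rate, Hz.
#' @param snap_tolerance half-width of the snapping window, as a
#'   fraction of the projected interval.
#' @return a `lowback_events`: per-foot contact samples, `first_foot`,
#'   `template_source`, and a log of unmatched projections.
#' @export
lateralize_and_match <- function(filtered_ap, ml_accel, foot_events_left,
                                 foot_events_right, first_contact,
                                 sample_rate_hz, snap_tolerance = 0.25) {
  if (is.null(foot_events_left) || is.null(foot_events_right))
    abort("template unavailable: both feet's events are required",
          "gaitreliab_lowback_error")
  prior_samp <- mean(c(diff(foot_events_left$contacts),
                       diff(foot_events_right$contacts)))
  step_win <- first_contact:min(length(ml_accel),
                                first_contact + round(prior_samp / 2))
  first_foot <- if (mean(ml_accel[step_win]) > 0) "right" else "left"

  # cumulative projection: consecutive template intervals telescope, so
  # each target inherits only the anchor error, not chained snap errors
  match_foot <- function(anchor, template) {
    cts <- anchor
    missed <- 0L
    targets <- anchor + cumsum(template)
    for (k in seq_along(template)) {
      target <- targets[k]
      tol <- round(snap_tolerance * template[k])
      lo <- max(1L, round(target - tol))
      hi <- min(length(filtered_ap), round(target + tol))
      hit <- NA_integer_
      if (hi - lo >= 2) {
        loc <- find_peaks(filtered_ap[lo:hi])
        if (length(loc)) {
          loc <- loc + lo - 1L
          hit <- loc[which.min(abs(loc - target))]
        }
      }
      if (is.na(hit)) missed <- missed + 1L else cts <- c(cts, hit)
    }
    list(contacts = cts, missed = missed)
  }

  tpl <- list(left = diff(foot_events_left$contacts),
              right = diff(foot_events_right$contacts))
  other <- setdiff(c("left", "right"), first_foot)
  m1 <- match_foot(first_contact, tpl[[first_foot]])

  # anchor the other foot between the first and second matched contact
  second <- if (length(m1$contacts) >= 2) m1$contacts[2] else
    first_contact + round(prior_samp)
  win <- (first_contact + 3):(second - 3)
  anchor2 <- NA_integer_
  if (length(win) >= 3) {
    loc <- find_peaks(filtered_ap[win])
    if (length(loc)) {
      loc <- loc + win[1] - 1L
      anchor2 <- loc[which.max(filtered_ap[loc])]
    }
  }
  if (is.na(anchor2))
    abort("could not anchor the second foot in the low-back signal",
          "gaitreliab_lowback_error")
  m2 <- match_foot(anchor2, tpl[[other]])

  contacts <- list()
  contacts[[first_foot]] <- m1$contacts
  contacts[[other]] <- m2$contacts
  merged <- sort(c(contacts$left, contacts$right))
  lab <- ifelse(merged %in% contacts$left, "left", "right")
  alternating <- all(lab[-1] != lab[-length(lab)])
  structure(list(contacts = contacts, first_foot = first_foot,
                 template_source = c(left = foot_events_left$foot,
                                     right = foot_events_right$foot),
                 missed = c(m1$missed, m2$missed),
                 alternating = alternating,
                 sample_rate_hz = sample_rate_hz),
            class = "lowback_events")
}

#' @export
print.lowback_events <- function(x, ...) {
  cat("<lowback_events> first foot:", x$first_foot, "; contacts L/R:",
      length(x$contacts$left), "/", length(x$contacts$right),
      "; alternating:", x$alternating, "\n")
  invisible(x)
}

#' Detect low-back gait events for a full assessment
#'
#' Runs [bandpass_ap()], [detect_first_contact()] and
#' [lateralize_and_match()] over the walking span; returned contact
#' indices are in the trimmed-signal frame. Failure is non-fatal at the
#' pipeline level: features that need lumbar events are marked missing.
#'
#' @param oriented_lowback lumbar `oriented_signal`.
#' @param walk_bounds c(start, end) walking span.
#' @param foot_events_left,foot_events_right foot `gait_events`
#'   (trimmed-signal frame).
#' @param config pipeline constants, see [default_config()].
#' @return a `lowback_events`.
#' @export
detect_lowback_events <- function(oriented_lowback, walk_bounds,
                                  foot_events_left, foot_events_right,
                                  config = default_config()) {
  fs <- oriented_lowback$sample_rate_hz
  idx <- walk_bounds[1]:walk_bounds[2]
  off <- walk_bounds[1] - 1L
  fap <- bandpass_ap(oriented_lowback,
                     band = config$bandpass_hz,
                     order = config$bandpass_order)[idx]
  prior <- foot_events_left$prior %||%
    structure(list(average_stride_time_s =
                     mean(diff(foot_events_left$contacts)) / fs,
                   dominant_frequency_hz = NA_real_),
              class = "stride_prior")
  fc <- detect_first_contact(fap, prior, fs,
                             distance_factor = config$peak_distance_factor)
  shift <- function(ev) { ev$contacts <- ev$contacts - off; ev }
  lb <- lateralize_and_match(fap, oriented_lowback$accel[idx, "ml"],
                             shift(foot_events_left),
                             shift(foot_events_right), fc, fs,
                             snap_tolerance = config$snap_tolerance)
  lb$contacts <- lapply(lb$contacts, function(v) sort(v) + off)
  lb
}
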