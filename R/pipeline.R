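#' Default pipeline configuration
#'
#' All pipeline constants in one auditable list. The signal-processing
#' and detection constants default to the values the method prescribes:
#' 100 Hz target rate, 2 s end trims, a strict 10 s length-validation
#' tolerance, peak distance factor 0.75, false-negative gap factor 1.5
#' with height factor 0.75, a 0.2 s minimal stance, 10-stride summary
#' blocks and a 25-stride complexity window.
#'
#' @param ... overrides for individual entries.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    expected_duration_s = 120,
    standstill_bookend_s = 5,
    target_rate_hz = 100,
    trim_s = 2,
    length_tolerance_s = 10,
    stationary_window_s = 0.5,
    prior_band_hz = c(0.2, 2.5),
    peak_distance_factor = 0.75,
    gap_factor = 1.5,
    fn_height_factor = 0.75,
    stance_min_s = 0.2,
    bandpass_hz = c(0.25, 15),
    bandpass_order = 2,
    snap_tolerance = 0.25,
    madgwick_beta = 0.05,
    block_strides = 10,
    complexity_strides = 25,
    samples_per_stride = 100,
    welch_segment_s = 10,
    density_halfwidth_hz = 0.25,
    min_freq_duration_s = 30,
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  num <- vapply(cfg, is.numeric, TRUE)
  if (any(vapply(cfg[num], function(v) any(v <= 0),
                 TRUE)[names(cfg)[num] != "seed"]))
    abort("all configuration constants must be positive",
          "gaitreliab_validation_error")
  cfg
}

#' Load a configuration from YAML, merged over the defaults
#'
#' @param path YAML file with any subset of [default_config()] entries.
#' @return configuration list.
#' @export
load_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Run one assessment end to end
#'
#' Reads the three-sensor recording named by the manifest, preprocesses
#' (resample, bias correction, trims, stationary bounds), validates the
#' residual length against the expected walking duration (expected
#' assessment duration minus both standstill bookends; strictly more
#' than `length_tolerance_s` deviation excludes the measurement),
#' orients all sensors, detects foot strides and low-back events,
#' reconstructs stride displacements by ZUPT, and assembles the
#' 166-feature vector. Every exclusion or repair decision is logged
#' with its triggering rule.
#'
#' @param manifest path to a recording manifest
#'   ([write_recording()] / [read_recording()]), or a `raw_recording`.
#' @param config pipeline constants, see [default_config()].
#' @param out_dir optional directory for `features.csv`, `events.csv`
#'   and `log.txt`.
#' @param bias optional `gyro_bias`; when absent it is estimated from
#'   the pre-walk standstill bookend.
#' @return a `feature_vector`, with attributes `events` and `log`.
#' @export
run_assessment <- function(manifest, config = default_config(),
                           out_dir = NULL, bias = NULL) {
  raw <- if (inherits(manifest, "raw_recording")) manifest
         else read_recording(manifest)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.null(bias)) {
    # calibrate on the pre-walk standstill (skip the very first samples)
    fs <- raw$sample_rate_hz
    idx <- seq_len(min(nrow(raw$streams[[1]]$gyro),
                       round(0.8 * config$standstill_bookend_s * fs)))
    still <- structure(list(streams = lapply(raw$streams, function(st) {
      st$gyro <- st$gyro[idx, , drop = FALSE]
      st$accel <- st$accel[idx, , drop = FALSE]
      st
    }), sample_rate_hz = fs, meta = raw$meta), class = "raw_recording")
    bias <- estimate_gyro_bias(still)
    note("gyro bias estimated from pre-walk standstill")
  }

  pre <- preprocess(raw, bias, target_rate_hz = config$target_rate_hz,
                    trim_s = config$trim_s,
                    stationary_window_s = config$stationary_window_s)
  log <- c(log, pre$log)

  expected_walk <- (raw$meta$expected_duration_s %||%
                      config$expected_duration_s) -
    2 * config$standstill_bookend_s
  verdict <- validate_length(pre, expected_walk,
                             tolerance_s = config$length_tolerance_s)
  if (!verdict$pass) {
    note("excluded: residual length deviates more than %g s from %g s",
         config$length_tolerance_s, expected_walk)
    abort(paste0("measurement excluded by the length rule (residual ",
                 paste(round(verdict$residual_s, 1), collapse = "/"),
                 " s vs expected ", round(expected_walk, 1), " s)"),
          "gaitreliab_exclusion_error", list(verdict = verdict, log = log))
  }
  note("length validation passed (expected walk %.1f s)", expected_walk)

  oriented <- lapply(pre$streams, orient, beta = config$madgwick_beta)
  wb <- pre$walk_bounds
  events <- list()
  for (foot in c("left", "right")) {
    ev <- detect_strides(oriented[[paste0(foot, "_foot")]], wb, foot,
                         config)
    note("%s foot: %d contacts, %d FN inserted, %d FP removed", foot,
         length(ev$contacts), ev$repair_log["false_negative_inserted"],
         ev$repair_log["false_positive_removed"])
    events[[foot]] <- ev
  }
  disp <- list(
    left = zupt_stride_displacement(oriented$left_foot,
                                    events$left$stance),
    right = zupt_stride_displacement(oriented$right_foot,
                                     events$right$stance))
  lb <- tryCatch(
    detect_lowback_events(oriented$low_back, wb, events$left,
                          events$right, config),
    gaitreliab_error = function(e) {
      note("low-back events unavailable: %s", conditionMessage(e))
      NULL
    })

  st <- spatio_temporal_features(events$left, events$right, disp$left,
                                 disp$right, lb, raw$meta,
                                 config$target_rate_hz,
                                 block = config$block_strides)
  fq <- frequency_features(oriented, wb,
                           stride_freq_hz =
                             events$left$prior$dominant_frequency_hz,
                           segment_s = config$welch_segment_s,
                           min_duration_s = config$min_freq_duration_s,
                           density_halfwidth = config$density_halfwidth_hz)
  cxs <- list(
    complexity_features(oriented$left_foot, events$left$contacts,
                        "left_foot", config$complexity_strides,
                        config$samples_per_stride),
    complexity_features(oriented$right_foot, events$right$contacts,
                        "right_foot", config$complexity_strides,
                        config$samples_per_stride),
    complexity_features(oriented$low_back,
                        if (!is.null(lb)) lb$contacts$left
                        else events$left$contacts,
                        "lb", config$complexity_strides,
                        config$samples_per_stride))
  cx <- do.call(c, cxs)
  attr(cx, "reasons") <- do.call(c, lapply(cxs, attr, "reasons"))
  asym <- asymmetry_features(st, raw$meta)
  gen <- general_features(events$left, events$right, disp$left,
                          disp$right, lb, wb, raw$meta,
                          config$target_rate_hz)
  fv <- assemble_features(st, fq, cx, asym, gen, meta = raw$meta)
  attr(fv, "events") <- list(left = events$left, right = events$right,
                             low_back = lb)
  attr(fv, "log") <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(feature_row(fv), file.path(out_dir, "features.csv"),
              row.names = FALSE)
    ev_tab <- rbind(events_table(events$left), events_table(events$right),
                    if (!is.null(lb)) events_table(lb))
    write.csv(ev_tab, file.path(out_dir, "events.csv"), row.names = FALSE)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  fv
}

#' One-row data frame representation of a feature vector
#'
#' Metadata columns followed by the 166 feature columns (CSV export
#' format: one row per assessment).
#'
#' @param fv a `feature_vector`.
#' @return one-row data frame.
#' @export
feature_row <- function(fv) {
  meta <- attr(fv, "meta") %||% list()
  row <- as.data.frame(as.list(stats::setNames(fv$value, fv$name)),
                       check.names = FALSE)
  cbind(data.frame(subject_id = meta$subject_id %||% NA,
                   session_id = meta$session_id %||% NA),
        row)
}

#' Run the test-retest reliability analysis over two session files
#'
#' @param session1,session2 paths to feature CSVs (one row per subject,
#'   as written by [feature_row()]) or data frames.
#' @param config pipeline constants (unused entries ignored).
#' @param out_dir optional directory for `reliability.csv` and
#'   `summary.json`.
#' @return a `reliability_table`.
#' @export
run_reliability <- function(session1, session2,
                            config = default_config(), out_dir = NULL) {
  load <- function(x) if (is.character(x)) read.csv(x, check.names = FALSE)
                      else x
  s1 <- load(session1); s2 <- load(session2)
  drop <- intersect("session_id", names(s1))
  s1 <- s1[, setdiff(names(s1), drop), drop = FALSE]
  s2 <- s2[, setdiff(names(s2), drop), drop = FALSE]
  tab <- reliability_table(s1, s2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reliability(tab, file.path(out_dir, "reliability.csv"),
                      file.path(out_dir, "summary.json"))
  }
  tab
}

#' Simulate and write a synthetic assessment
#'
#' Convenience wrapper: generates a synthetic walk and writes the
#' three-sensor CSVs, the manifest and the ground-truth sidecar.
#'
#' @param dir output directory.
#' @param spec a [walk_spec()].
#' @return path to the manifest, invisibly.
#' @export
simulate_assessment <- function(dir, spec = walk_spec()) {
  w <- generate_walk(spec)
  write_recording(w$recording, dir, ground_truth = w$ground_truth)
}
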