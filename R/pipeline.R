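#' Run the trial-based analysis for one session
#'
#' Trajectory to classified trials: binned speed, stimulus-aligned traces,
#' threshold classification, and stop-duration measurement in the full
#' session series (capped at the next onset).
#'
#' @param session A [tracked_session()].
#' @param schedule A [stimulus_schedule()].
#' @param config Configuration list ([default_config()]).
#' @return data.frame: `fly_id, genotype, trial, label, v_pre, peak_accel,
#'   first_crossing_sign, min_post_speed, stop_duration_s, censored, valid`.
#' @export
analyze_session <- function(session, schedule, config = default_config()) {
  series <- compute_speed_series(session, bin_s = config$bin_s,
                                 max_gap = config$max_gap_frames)
  traces <- extract_trials(series, schedule, window = config$window_s,
                           smooth_s = config$accel_smooth_s)
  cls <- classify_trials(traces, accel_threshold = config$accel_threshold,
                         v_zero = config$v_zero)
  cls$genotype <- session$genotype
  cls$stop_duration_s <- NA_real_
  cls$censored <- NA
  stops <- which(!is.na(cls$label) & cls$label == "stop")
  bounds <- c(schedule$onsets, max(session$timestamps))
  for (i in stops) {
    sd <- measure_stop_duration(series, schedule$onsets[i],
                                next_onset = bounds[i + 1L],
                                v_zero = config$v_zero,
                                sustain_s = config$stop_sustain_s)
    cls$stop_duration_s[i] <- sd$duration
    cls$censored[i] <- sd$censored
  }
  cls[, c("fly_id", "genotype", "trial", "label", "v_pre", "peak_accel",
          "first_crossing_sign", "min_post_speed", "stop_duration_s",
          "censored", "valid")]
}

#' Run the trial-based analysis for a cohort
#'
#' @param sessions List of [tracked_session()].
#' @param schedules One [stimulus_schedule()] shared by all sessions, or a
#'   parallel list of schedules.
#' @param config Configuration list.
#' @return List: `trials` (pooled classified trials), `profiles` (per-fly
#'   [summarize_profile()]), `curve` (pooled [build_curve()]).
#' @export
analyze_cohort <- function(sessions, schedules, config = default_config()) {
  shared <- inherits(schedules, "stimulus_schedule")
  trials <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    sch <- if (shared) schedules else schedules[[i]]
    analyze_session(sessions[[i]], sch, config)
  }))
  edges <- speed_bins(v_zero = config$v_zero, width = config$speed_bin_width,
                      max = config$speed_bin_max)
  list(trials = trials,
       profiles = summarize_profile(trials, by = "fly_id"),
       curve = build_curve(trials, edges = edges))
}
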