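#' Classify one trial into stop / slow down / speed up / no reaction
#'
#' Threshold rules: a reaction is robust only if |acceleration| reaches
#' `accel_threshold` (200 mm/s^2) somewhere in the 1 s post-stimulus window;
#' otherwise the trial is a no-reaction trial. The sign of the first
#' threshold-magnitude crossing defines the first reaction. A negative first
#' reaction in a fly that had been moving (`v_pre > v_zero`) is a stop if
#' speed falls to the stationarity floor `v_zero` before the first
#' subsequent positive crossing (or window end), else a slow down. A
#' positive first reaction is a speed up. A negative first crossing with
#' `v_pre <= v_zero` can only arise from noise (a stationary fly cannot
#' meaningfully decelerate) and is remapped to no reaction.
#'
#' The threshold is applied by default to the acceleration at its native
#' 10 ms resolution (`accel_source = "raw"`): averaging over 100 ms bounds
#' the measurable deceleration of a complete stop at `v_pre / 0.1 s`, which
#' would put stops from ordinary walking speeds below any 200 mm/s^2
#' criterion. The 100 ms moving-average acceleration remains available via
#' `accel_source = "smoothed"`; see the methods vignette.
#'
#' @param trace A `trial_trace` from [get_trial()] (or an element-compatible
#'   list).
#' @param accel_threshold Robustness threshold, mm/s^2 (default 200).
#' @param v_zero Stationarity floor, mm/s (default 0.5): the operational
#'   meaning of "0 mm/s" under centroid noise, and the single most sensitive
#'   constant of the classifier.
#' @param accel_source `"raw"` (10 ms central difference, default) or
#'   `"smoothed"` (100 ms moving average).
#' @return One-row data.frame: `trial, label, v_pre, peak_accel,
#'   first_crossing_sign, min_post_speed, valid`. Invalid traces get label
#'   `NA` (unscored) and are excluded from profiles but still counted among
#'   attempted trials.
#' @export
classify_trial <- function(trace, accel_threshold = 200, v_zero = 0.5,
                           accel_source = c("raw", "smoothed")) {
  accel_source <- match.arg(accel_source)
  post <- trace$time_grid >= 0
  out <- data.frame(trial = trace$trial, label = NA_character_,
                    v_pre = trace$v_pre, peak_accel = NA_real_,
                    first_crossing_sign = "none",
                    min_post_speed = NA_real_, valid = trace$valid,
                    stringsAsFactors = FALSE)
  if (!isTRUE(trace$valid)) return(out)
  a <- if (accel_source == "raw") trace$accel_raw[post] else trace$accel[post]
  s <- trace$speed[post]
  out$peak_accel <- max(abs(a))
  out$min_post_speed <- min(s)
  cross <- which(abs(a) >= accel_threshold)
  if (!length(cross)) {
    out$label <- "no_reaction"
    return(out)
  }
  first <- cross[1]
  if (a[first] > 0) {
    out$first_crossing_sign <- "+"
    out$label <- "speed_up"
    return(out)
  }
  out$first_crossing_sign <- "-"
  if (trace$v_pre <= v_zero) {
    # stationary fly cannot slow down: noise-induced crossing, remapped
    out$label <- "no_reaction"
    return(out)
  }
  pos_after <- cross[cross > first & a[cross] > 0]
  seg_end <- if (length(pos_after)) pos_after[1] - 1L else length(s)
  out$label <- if (min(s[first:seg_end]) <= v_zero) "stop" else "slow_down"
  out
}

#' Classify all trials of a session
#'
#' @param traces A [extract_trials()] result.
#' @inheritParams classify_trial
#' @return data.frame with one row per attempted trial (see
#'   [classify_trial()]), plus `fly_id`.
#' @export
classify_trials <- function(traces, accel_threshold = 200, v_zero = 0.5,
                            accel_source = c("raw", "smoothed")) {
  accel_source <- match.arg(accel_source)
  rows <- lapply(seq_along(traces$valid), function(i)
    classify_trial(get_trial(traces, i), accel_threshold, v_zero,
                   accel_source))
  out <- do.call(rbind, rows)
  cbind(fly_id = traces$fly_id, out, stringsAsFactors = FALSE)
}

#' Measure the duration of a stop
#'
#' Searched in the full-session speed series (a freeze may outlast the 1 s
#' classification window): from the first post-onset bin with speed at or
#' below `v_zero` until the first later bin where speed exceeds `v_zero`
#' sustained for at least `sustain_s`, capped at the next trial onset. A
#' stop persisting to the cap is right-censored with the duration to the
#' cap.
#'
#' @param series The session's [compute_speed_series()] result.
#' @param onset Trial onset, s.
#' @param next_onset Next trial onset (or `Inf` / session end), s.
#' @param v_zero Stationarity floor, mm/s.
#' @param sustain_s Minimum sustained movement ending a stop, s (default
#'   0.05).
#' @return List `duration` (s), `censored` (logical), `t_start` (s, onset of
#'   immobility). Errors if no post-onset bin reaches `v_zero` (the trial is
#'   then not a stop trial, violating the precondition).
#' @export
measure_stop_duration <- function(series, onset, next_onset = Inf,
                                  v_zero = 0.5, sustain_s = 0.05) {
  bin_s <- series$bin_s
  b_on <- floor(onset / bin_s + 1e-9) + 1L
  b_cap <- min(length(series$speed),
               if (is.finite(next_onset)) floor(next_onset / bin_s) else Inf)
  s <- series$speed[b_on:b_cap]
  below <- which(!is.na(s) & s <= v_zero)
  if (!length(below))
    stop("speed never reaches v_zero after onset: not a stop trial",
         call. = FALSE)
  start <- below[1]
  k <- max(1L, round(sustain_s / bin_s))
  above <- !is.na(s) & s > v_zero
  above[seq_len(start)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit)) {
    end <- starts[hit[1]]
    list(duration = (end - start) * bin_s, censored = FALSE,
         t_start = onset + (start - 1L) * bin_s)
  } else {
    list(duration = (length(s) - start + 1L) * bin_s, censored = TRUE,
         t_start = onset + (start - 1L) * bin_s)
  }
}

#' Summarize response proportions per group
#'
#' Per-group counts and proportions of the four labels over valid trials,
#' plus stop-duration summaries. Groups with no valid trials are excluded
#' with a warning.
#'
#' @param classified data.frame from [classify_trials()] /
#'   [analyze_session()] (needs columns `label`, `valid`, the grouping
#'   column, and optionally `stop_duration_s`).
#' @param by Grouping column name (default `"fly_id"`).
#' @return data.frame of class `response_profile`: one row per group with
#'   `n_attempted`, `n_valid`, `n_<label>`, `p_<label>` (summing to 1), and
#'   `mean_stop_duration_s`.
#' @export
summarize_profile <- function(classified, by = "fly_id") {
  stopifnot(by %in% names(classified))
  groups <- split(classified, classified[[by]])
  labs <- response_labels()
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    v <- d[!is.na(d$label) & d$valid, , drop = FALSE]
    if (!nrow(v)) {
      warning(sprintf("group %s has no valid trials; excluded", g),
              call. = FALSE)
      return(NULL)
    }
    cnt <- vapply(labs, function(l) sum(v$label == l), numeric(1))
    msd <- if ("stop_duration_s" %in% names(v))
      mean(v$stop_duration_s[v$label == "stop"], na.rm = TRUE) else NA_real_
    out <- data.frame(group = g, n_attempted = nrow(d), n_valid = nrow(v),
                      stringsAsFactors = FALSE)
    for (l in labs) out[[paste0("n_", l)]] <- cnt[[l]]
    for (l in labs) out[[paste0("p_", l)]] <- cnt[[l]] / nrow(v)
    out$mean_stop_duration_s <- msd
    out
  })
  res <- do.call(rbind, rows)
  names(res)[1] <- by
  class(res) <- c("response_profile", "data.frame")
  res
}
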