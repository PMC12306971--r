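#' Compute a binned speed time series
#'
#' Per-frame speed is the Euclidean centroid displacement between consecutive
#' frames divided by the frame interval, assigned to a fixed 10 ms grid by
#' the displacement midpoint and averaged within bins. Short tracking gaps
#' are interpolated first ([interpolate_gaps()]); bins overlapping longer
#' gaps, or not covered by any frame, are `NA` and flagged.
#'
#' @param session A [tracked_session()].
#' @param bin_s Bin width in s (default 0.01).
#' @param max_gap Longest gap (frames) to interpolate.
#' @return Object of class `speed_series`: list with `t` (bin left edges, s),
#'   `speed` (mm/s, `NA` at uncovered bins), `bin_s`, `gap_bins` (logical),
#'   and `fly_id`.
#' @export
compute_speed_series <- function(session, bin_s = 0.01, max_gap = 3L) {
  if (length(session$timestamps) < 2L)
    stop("need at least 2 frames to compute speed", call. = FALSE)
  session <- interpolate_gaps(session, max_gap)
  long_gaps <- attr(session, "long_gaps")
  ts <- session$timestamps
  d <- sqrt(diff(session$x)^2 + diff(session$y)^2)
  v <- d / diff(ts)
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  nb <- max(1L, floor(max(ts) / bin_s + 1e-9))
  bin <- pmin(nb, floor(tm / bin_s) + 1L)
  ok <- !is.na(v)
  if (!any(ok)) {
    warning("session has no usable frames; empty speed series", call. = FALSE)
    return(structure(list(t = numeric(0), speed = numeric(0), bin_s = bin_s,
                          gap_bins = logical(0), fly_id = session$fly_id),
                     class = "speed_series"))
  }
  sums <- rowsum(v[ok], bin[ok])
  cnts <- rowsum(rep(1, sum(ok)), bin[ok])
  speed <- rep(NA_real_, nb)
  speed[as.integer(rownames(sums))] <- sums / cnts
  gap_bins <- is.na(speed)
  if (nrow(long_gaps)) {
    for (g in seq_len(nrow(long_gaps))) {
      lo <- floor(long_gaps$start_s[g] / bin_s) + 1L
      hi <- min(nb, floor(long_gaps$end_s[g] / bin_s) + 1L)
      gap_bins[lo:hi] <- TRUE
      speed[lo:hi] <- NA_real_
    }
  }
  structure(list(t = (seq_len(nb) - 1L) * bin_s, speed = speed, bin_s = bin_s,
                 gap_bins = gap_bins, fly_id = session$fly_id),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("<speed_series> fly %s: %d bins of %.0f ms, %d gap bins\n",
              x$fly_id, length(x$speed), x$bin_s * 1000, sum(x$gap_bins)))
  invisible(x)
}

#' Acceleration from a binned speed trace
#'
#' Central finite difference of speed (sign encodes speeding up vs slowing
#' down), optionally smoothed with a centered 100 ms moving average whose
#' window shrinks at the trace edges so the full post-stimulus window stays
#' scored.
#'
#' @param speed Numeric speed vector (mm/s) on a uniform grid.
#' @param bin_s Grid spacing, s.
#' @param smooth_s Moving-average window, s; `0` returns the unsmoothed
#'   central difference.
#' @return Acceleration per bin, mm/s^2.
#' @export
compute_acceleration <- function(speed, bin_s = 0.01, smooth_s = 0.1) {
  n <- length(speed)
  if (n < 2L) return(rep(0, n))
  a <- numeric(n)
  if (n > 2L)
    a[2:(n - 1L)] <- (speed[3:n] - speed[1:(n - 2L)]) / (2 * bin_s)
  a[1] <- (speed[2] - speed[1]) / bin_s
  a[n] <- (speed[n] - speed[n - 1L]) / bin_s
  k <- round(smooth_s / bin_s)
  if (k > 1L) a <- moving_average(a, k)
  a
}

#' Extract stimulus-aligned trial traces
#'
#' One trace per scheduled shadow onset: binned speed in the [-0.2, 1.0) s
#' peri-stimulus window (120 bins of 10 ms), the pre-stimulus baseline
#' `v_pre` (mean speed over [-0.2, 0)), baseline-subtracted normalized
#' speed, and acceleration at both the native 10 ms resolution and after
#' 100 ms moving-average smoothing. Trials whose window is not fully covered
#' by tracking, or overlaps a long gap, are marked invalid with a reason,
#' never dropped.
#'
#' @param series A [compute_speed_series()] result.
#' @param schedule A [stimulus_schedule()].
#' @param window Peri-stimulus window in s (default `c(-0.2, 1.0)`).
#' @param smooth_s Acceleration smoothing window, s.
#' @return Object of class `trial_traces`: matrices `speed`, `normalized`,
#'   `accel` (smoothed), `accel_raw` (trials x bins), vectors `v_pre`,
#'   `valid`, `reason`, `onsets`, the relative `time_grid` (bin left edges),
#'   and `fly_id`.
#' @export
extract_trials <- function(series, schedule, window = c(-0.2, 1.0),
                           smooth_s = 0.1) {
  bin_s <- series$bin_s
  rel <- seq(window[1], window[2] - bin_s / 2, by = bin_s)
  nbin <- length(rel)
  npre <- sum(rel < 0)
  nt <- schedule$n_trials
  sp <- matrix(NA_real_, nt, nbin)
  valid <- logical(nt)
  reason <- rep(NA_character_, nt)
  for (tr in seq_len(nt)) {
    b0 <- floor(schedule$onsets[tr] / bin_s + 1e-9) + 1L
    idx <- b0 + seq.int(-npre, nbin - npre - 1L)
    if (idx[1] < 1L || idx[nbin] > length(series$speed)) {
      reason[tr] <- "window not covered by recording"
      next
    }
    if (anyNA(series$speed[idx])) {
      reason[tr] <- "window overlaps tracking gap"
      next
    }
    sp[tr, ] <- series$speed[idx]
    valid[tr] <- TRUE
  }
  v_pre <- rowMeans(sp[, seq_len(npre), drop = FALSE])
  normalized <- sp - v_pre
  row_accel <- function(sm) {
    if (nt == 0L) return(matrix(NA_real_, 0L, nbin))
    t(apply(sp, 1L, compute_acceleration, bin_s = bin_s, smooth_s = sm))
  }
  accel_raw <- row_accel(0)
  accel <- row_accel(smooth_s)
  structure(list(time_grid = rel, speed = sp, normalized = normalized,
                 accel = accel, accel_raw = accel_raw,
                 v_pre = v_pre, valid = valid, reason = reason,
                 onsets = schedule$onsets, bin_s = bin_s,
                 fly_id = series$fly_id, trial = seq_len(nt)),
            class = "trial_traces")
}

#' @export
print.trial_traces <- function(x, ...) {
  cat(sprintf("<trial_traces> fly %s: %d trials (%d valid), %d bins in [%.1f, %.1f) s\n",
              x$fly_id, length(x$valid), sum(x$valid), length(x$time_grid),
              x$time_grid[1], x$time_grid[length(x$time_grid)] + x$bin_s))
  invisible(x)
}

#' Extract a single trial trace
#'
#' @param traces A [extract_trials()] result.
#' @param i Trial index.
#' @return Object of class `trial_trace` (vectors for one trial).
#' @export
get_trial <- function(traces, i) {
  stopifnot(i >= 1L, i <= length(traces$valid))
  structure(list(time_grid = traces$time_grid,
                 speed = traces$speed[i, ],
                 normalized = traces$normalized[i, ],
                 accel = traces$accel[i, ],
                 accel_raw = traces$accel_raw[i, ],
                 v_pre = traces$v_pre[i], valid = traces$valid[i],
                 reason = traces$reason[i], onset = traces$onsets[i],
                 bin_s = traces$bin_s, fly_id = traces$fly_id,
                 trial = i),
            class = "trial_trace")
}

#' Export trial traces as a tidy table
#'
#' @param traces A [extract_trials()] result.
#' @return data.frame `fly, trial, t_s, speed_mm_s, accel_mm_s2` (valid
#'   trials only).
#' @export
traces_to_table <- function(traces) {
  keep <- which(traces$valid)
  nb <- length(traces$time_grid)
  data.frame(
    fly = traces$fly_id,
    trial = rep(keep, each = nb),
    t_s = rep(traces$time_grid, times = length(keep)),
    speed_mm_s = as.vector(t(traces$speed[keep, , drop = FALSE])),
    accel_mm_s2 = as.vector(t(traces$accel[keep, , drop = FALSE])))
}
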