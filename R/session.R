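#' Tunnel dimensions of the walking arena
#'
#' Default tunnel geometry: 52 mm x 5 mm, the linear track in which a single
#' fly walks freely in two dimensions but cannot fly.
#'
#' @return Numeric vector `c(length = 52, width = 5)` in mm.
#' @export
default_tunnel <- function() c(length = 52, width = 5)

#' Construct a tracked session
#'
#' A `tracked_session` holds one fly's centroid trajectory (timestamps in
#' seconds from session start, positions in mm after calibration) together
#' with its metadata. Missing coordinates are kept as `NA` and flagged as
#' tracking gaps rather than dropped, so that downstream trial extraction can
#' invalidate affected trials.
#'
#' @param fly_id Character scalar, unique fly identifier.
#' @param timestamps Numeric vector, seconds, strictly increasing
#'   (nominal spacing 0.01 s at the 100 frames/s tracker rate).
#' @param x,y Numeric vectors, centroid coordinates in mm (same length as
#'   `timestamps`); `NA` marks a tracking dropout.
#' @param genotype Character scalar, group label.
#' @param age_days Integer >= 0.
#' @param calibration Positive scalar, mm per pixel used during conversion
#'   (1 if coordinates were already metric).
#' @param tunnel Numeric length-2, tunnel (length, width) in mm.
#' @param meta Named list of free-form annotations (keys must be unique).
#' @return Object of class `tracked_session`.
#' @export
tracked_session <- function(fly_id, timestamps, x, y,
                            genotype = "unknown", age_days = 7L,
                            calibration = 1, tunnel = default_tunnel(),
                            meta = list()) {
  stopifnot(is.character(fly_id), length(fly_id) == 1L)
  timestamps <- as.numeric(timestamps)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(timestamps) || length(y) != length(timestamps))
    stop("timestamps, x and y must have equal length", call. = FALSE)
  if (anyNA(timestamps))
    stop("timestamps must not contain NA", call. = FALSE)
  bad <- which(diff(timestamps) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L),
         call. = FALSE)
  if (!is.numeric(calibration) || length(calibration) != 1L || calibration <= 0)
    stop("calibration must be a positive scalar (mm/px)", call. = FALSE)
  if (length(tunnel) != 2L || any(tunnel <= 0))
    stop("tunnel must be positive (length, width) in mm", call. = FALSE)
  if (!is.na(age_days) && age_days < 0)
    stop("age_days must be >= 0", call. = FALSE)
  if (length(meta) && anyDuplicated(names(meta)))
    stop("meta keys must be unique", call. = FALSE)
  tol <- 0.5  # mm slack for centroid overshoot at walls
  ok <- stats::complete.cases(x, y)
  if (any(ok) &&
      (min(x[ok]) < -tol || max(x[ok]) > tunnel[1] + tol ||
       min(y[ok]) < -tol || max(y[ok]) > tunnel[2] + tol))
    warning("positions fall outside tunnel bounds beyond tolerance", call. = FALSE)
  structure(
    list(fly_id = fly_id, genotype = as.character(genotype),
         age_days = as.integer(age_days),
         timestamps = timestamps, x = x, y = y,
         calibration = calibration,
         tunnel = as.numeric(tunnel), meta = meta),
    class = "tracked_session")
}

#' @export
print.tracked_session <- function(x, ...) {
  gaps <- sum(!stats::complete.cases(x$x, x$y))
  cat(sprintf("<tracked_session> fly %s (%s, %d d): %d frames, %.1f s, %d gap frames\n",
              x$fly_id, x$genotype, x$age_days, length(x$timestamps),
              diff(range(x$timestamps)), gaps))
  invisible(x)
}

#' Construct a stimulus schedule
#'
#' Shadow-stimulus onsets (seconds from session start) plus the common shadow
#' duration. The per-tunnel shadow arrival equals the scheduled onset: the
#' arena presents the shadow to all tracks concurrently.
#'
#' @param onsets Numeric vector of onset times in s, ascending.
#' @param shadow_duration Shadow-on time in s (default 2).
#' @param session_length Total session length in s (default 2400); onsets past
#'   it trigger a warning.
#' @return Object of class `stimulus_schedule` with `n_trials = length(onsets)`.
#' @export
stimulus_schedule <- function(onsets, shadow_duration = 2, session_length = 2400) {
  onsets <- as.numeric(onsets)
  if (anyNA(onsets)) stop("onsets must not contain NA", call. = FALSE)
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("stimulus onsets must be strictly ascending", call. = FALSE)
  if (shadow_duration <= 0) stop("shadow_duration must be > 0", call. = FALSE)
  if (length(onsets) && max(onsets) > session_length)
    warning("onset(s) beyond session_length", call. = FALSE)
  structure(list(onsets = onsets, shadow_duration = shadow_duration,
                 n_trials = length(onsets), session_length = session_length),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d trials, shadow %.1f s, session %.0f s",
              x$n_trials, x$shadow_duration, x$session_length))
  if (x$n_trials > 1L)
    cat(sprintf(", mean ITI %.1f s", mean(diff(x$onsets))))
  cat("\n")
  invisible(x)
}

#' Interpolate short tracking gaps
#'
#' Gaps of at most `max_gap` consecutive missing frames are filled by linear
#' interpolation (short dropouts are tracker noise); longer gaps are left as
#' `NA` and reported so that overlapping trials can be invalidated, since
#' kinematics across a long dropout are meaningless.
#'
#' @param session A [tracked_session()].
#' @param max_gap Longest run of missing frames to interpolate (default 3).
#' @return The session with short gaps filled; attribute `"long_gaps"` holds a
#'   data.frame (start_s, end_s) of remaining gap spans.
#' @export
interpolate_gaps <- function(session, max_gap = 3L) {
  miss <- !stats::complete.cases(session$x, session$y)
  long <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      if (r$lengths[i] <= max_gap && starts[i] > 1L && ends[i] < length(miss)) {
        idx <- starts[i]:ends[i]
        anchor <- c(starts[i] - 1L, ends[i] + 1L)
        session$x[idx] <- stats::approx(session$timestamps[anchor],
                                        session$x[anchor],
                                        xout = session$timestamps[idx])$y
        session$y[idx] <- stats::approx(session$timestamps[anchor],
                                        session$y[anchor],
                                        xout = session$timestamps[idx])$y
      } else {
        long <- rbind(long, data.frame(
          start_s = session$timestamps[starts[i]],
          end_s = session$timestamps[ends[i]]))
      }
    }
  }
  attr(session, "long_gaps") <- long
  session
}
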