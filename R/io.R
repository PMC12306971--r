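#' Read a tracker CSV into a tracked session
#'
#' Expects the tracker export format `frame,timestamp_s,x,y` (extra columns
#' are ignored). If `timestamp_s` is absent, timestamps are derived from the
#' frame index at `frame_rate`. Coordinates may be in pixels (converted with
#' `calibration`) or already in mm. Rows with missing coordinates become
#' tracking gaps in the session; they are flagged, never silently dropped.
#'
#' @param path CSV file path.
#' @param calibration mm per pixel (> 0); ignored for `unit = "mm"` beyond
#'   being recorded in the session.
#' @param tunnel Tunnel (length, width) in mm.
#' @param unit `"px"` or `"mm"`, the unit of the stored coordinates.
#' @param fly_id,genotype,age_days Session metadata (fly_id defaults to the
#'   file base name).
#' @param frame_rate Frames per second used when no timestamp column exists.
#' @return A [tracked_session()].
#' @export
read_tracking <- function(path, calibration = 1, tunnel = default_tunnel(),
                          unit = c("mm", "px"), fly_id = NULL,
                          genotype = "unknown", age_days = 7L,
                          frame_rate = 100) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("x", "y") %in% names(df)))
    stop(sprintf("tracking file %s lacks x/y columns", path), call. = FALSE)
  if ("timestamp_s" %in% names(df)) {
    ts <- as.numeric(df$timestamp_s)
  } else if ("frame" %in% names(df)) {
    ts <- as.numeric(df$frame) / frame_rate
  } else {
    stop(sprintf("tracking file %s lacks a timestamp_s or frame column", path),
         call. = FALSE)
  }
  bad <- which(diff(ts) <= 0)
  if (length(bad))
    stop(sprintf("non-monotonic timestamps in %s at row %d", path, bad[1] + 1L),
         call. = FALSE)
  scale <- if (unit == "px") calibration else 1
  if (is.null(fly_id)) fly_id <- sub("\\.[^.]*$", "", basename(path))
  tracked_session(fly_id = fly_id, timestamps = ts,
                  x = as.numeric(df$x) * scale, y = as.numeric(df$y) * scale,
                  genotype = genotype, age_days = age_days,
                  calibration = calibration, tunnel = tunnel)
}

#' Write a tracked session to the tracker CSV format
#'
#' Columns `frame,timestamp_s,x,y` with coordinates in mm; the round trip
#' through [read_tracking()] reproduces positions to float precision.
#'
#' @param session A [tracked_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(session, path) {
  df <- data.frame(frame = seq_along(session$timestamps) - 1L,
                   timestamp_s = session$timestamps,
                   x = session$x, y = session$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus schedule
#'
#' Accepts CSV (`trial,onset_s,duration_s`) or JSON
#' (`{"onsets": [...], "shadow_duration": ..., "session_length": ...}`).
#'
#' @param path Schedule file.
#' @param session_length Session length in s, used when the file does not
#'   state one.
#' @return A [stimulus_schedule()]. Descending onsets are a data error;
#'   onsets beyond the session length only warn.
#' @export
read_schedule <- function(path, session_length = 2400) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(stimulus_schedule(
      onsets = as.numeric(j$onsets),
      shadow_duration = if (!is.null(j$shadow_duration)) j$shadow_duration else 2,
      session_length = if (!is.null(j$session_length)) j$session_length
                       else session_length))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"onset_s" %in% names(df))
    stop(sprintf("schedule file %s lacks an onset_s column", path), call. = FALSE)
  dur <- if ("duration_s" %in% names(df) && nrow(df)) df$duration_s[1] else 2
  stimulus_schedule(onsets = df$onset_s, shadow_duration = dur,
                    session_length = session_length)
}

#' Write a stimulus schedule CSV
#'
#' @param schedule A [stimulus_schedule()].
#' @param path Output CSV path (`trial,onset_s,duration_s`).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(trial = seq_len(schedule$n_trials),
                   onset_s = schedule$onsets,
                   duration_s = rep(schedule$shadow_duration, schedule$n_trials))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline result tables and a run manifest
#'
#' Writes tidy CSVs -- `classified_trials.csv` (one row per trial),
#' `profiles.csv` (one row per group per metric set), optional
#' `comparisons.csv` and `speed_curve.csv` -- plus `manifest.json` recording
#' the configuration, seeds and package version. Reruns with identical inputs
#' and seeds produce byte-identical tables.
#'
#' @param results Named list; recognized elements `trials`, `profiles`,
#'   `comparisons`, `curve` (data.frames) are written when present.
#' @param out_dir Output directory (created if needed).
#' @param config List stored in the manifest.
#' @param seed Seed(s) stored in the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir, config = list(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  written <- character(0)
  tabs <- c(trials = "classified_trials.csv", profiles = "profiles.csv",
            comparisons = "comparisons.csv", curve = "speed_curve.csv")
  for (nm in names(tabs)) {
    if (!is.null(results[[nm]])) {
      f <- file.path(out_dir, tabs[[nm]])
      utils::write.csv(results[[nm]], f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
  }
  manifest <- list(
    package = "shadowtrial",
    version = as.character(utils::packageVersion("shadowtrial")),
    config = config, seed = seed,
    files = basename(written))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, mf))
}

#' Default analysis configuration
#'
#' All tunable constants of the pipeline in one list: calibration, the
#' peri-stimulus window, the acceleration robustness threshold (mm/s^2), the
#' stationarity floor `v_zero` (mm/s), speed-bin layout, and seeds.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    calibration_mm_per_px = 1,
    unit = "mm",
    tunnel = c(52, 5),
    frame_rate = 100,
    bin_s = 0.01,
    window_s = c(-0.2, 1.0),
    accel_threshold = 200,
    v_zero = 0.5,
    accel_smooth_s = 0.1,
    speed_bin_width = 2,
    speed_bin_max = 20,
    stop_sustain_s = 0.05,
    max_gap_frames = 3,
    n_virtual = 3000,
    seed = 1L)
}

#' Read an analysis configuration file
#'
#' YAML or JSON; values override [default_config()].
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  for (nm in intersect(names(user), names(cfg))) cfg[[nm]] <- user[[nm]]
  cfg
}
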