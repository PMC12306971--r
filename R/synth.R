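#' Speed-bin edges for response-probability curves
#'
#' A dedicated stationary bin `[0, v_zero)`, uniform bins of `width` mm/s up
#' to `max`, and an overflow bin `[max, Inf)`.
#'
#' @param v_zero Stationarity floor in mm/s (default 0.5).
#' @param width Bin width in mm/s (default 2).
#' @param max Upper edge of the last regular bin (default 20).
#' @return Numeric vector of bin edges (left-closed), ending in `Inf`.
#' @export
speed_bins <- function(v_zero = 0.5, width = 2, max = 20) {
  stopifnot(v_zero > 0, v_zero < width, max > width)
  c(0, v_zero, seq(width, max, by = width), Inf)
}

#' Default speed-conditioned response-probability curve
#'
#' Probability of each response type as a function of pre-stimulus speed,
#' used as the generator's planted outer model. Shape: running and
#' no-reaction dominate at zero and slow (< 5 mm/s) speeds, freezing peaks in
#' the 5-13 mm/s range, slowing grows with speed. Stop and slow-down
#' probabilities are exactly 0 below 4 mm/s: a stationary fly cannot stop,
#' and a full stop from below 4 mm/s changes speed too little to ever reach
#' the 200 mm/s^2 robustness threshold at 10 ms resolution, so planting such
#' responses would create trials that are unclassifiable by construction.
#'
#' @param edges Speed-bin edges from [speed_bins()].
#' @return Matrix (bins x 4 labels) of probabilities, rows summing to 1, with
#'   attribute `"edges"`.
#' @export
default_response_curve <- function(edges = speed_bins()) {
  nb <- length(edges) - 1L
  centers <- (edges[-length(edges)] + pmin(edges[-1], edges[length(edges) - 1] + 2)) / 2
  row_for <- function(v) {
    if (v < 0.5)  return(c(0.00, 0.00, 0.30, 0.70))
    if (v < 4)    return(c(0.00, 0.00, 0.45, 0.55))
    if (v < 6)    return(c(0.12, 0.00, 0.33, 0.55))
    if (v < 8)    return(c(0.35, 0.15, 0.15, 0.35))
    if (v < 10)   return(c(0.45, 0.20, 0.10, 0.25))
    if (v < 12)   return(c(0.48, 0.22, 0.08, 0.22))
    if (v < 14)   return(c(0.42, 0.28, 0.06, 0.24))
    if (v < 16)   return(c(0.35, 0.33, 0.05, 0.27))
    if (v < 18)   return(c(0.28, 0.38, 0.04, 0.30))
    if (v < 20)   return(c(0.22, 0.42, 0.04, 0.32))
    c(0.18, 0.45, 0.03, 0.34)
  }
  m <- t(vapply(centers[seq_len(nb)], row_for, numeric(4)))
  dimnames(m) <- list(NULL, response_labels())
  attr(m, "edges") <- edges
  m
}

#' Well-separated archetype response curve
#'
#' A curve planting stop and slow-down responses only at pre-stimulus speeds
#' of at least 10 mm/s, so that every reactive motif carries a speed change
#' of >= 8.5 mm/s and hence a measured acceleration of at least twice the
#' 200 mm/s^2 threshold. Used to build cohorts of four cleanly separated
#' response archetypes.
#'
#' @inheritParams default_response_curve
#' @return Probability matrix as in [default_response_curve()].
#' @export
archetype_response_curve <- function(edges = speed_bins()) {
  nb <- length(edges) - 1L
  lo <- edges[seq_len(nb)]
  m <- t(vapply(lo, function(l) {
    if (l < 0.5) c(0, 0, 0.35, 0.65)
    else if (l < 10) c(0, 0, 0.40, 0.60)
    else c(0.40, 0.25, 0.10, 0.25)
  }, numeric(4)))
  dimnames(m) <- list(NULL, response_labels())
  attr(m, "edges") <- edges
  m
}

check_response_curve <- function(curve, v_zero = 0.5) {
  edges <- attr(curve, "edges")
  if (is.null(edges) || nrow(curve) != length(edges) - 1L)
    stop("response curve must carry bin edges matching its rows", call. = FALSE)
  if (any(abs(rowSums(curve) - 1) > 1e-9))
    stop("response-curve rows must each sum to 1", call. = FALSE)
  if (any(curve < 0)) stop("response-curve probabilities must be >= 0", call. = FALSE)
  zero_bins <- which(edges[-length(edges)] < v_zero)
  if (any(curve[zero_bins, c("stop", "slow_down")] > 0))
    stop("stop/slow_down probability must be 0 in the stationary speed bin",
         call. = FALSE)
  invisible(TRUE)
}

#' Genotype parameter set for the trajectory generator
#'
#' Bundles the locomotion model (log-normal walk-bout speeds, two-state
#' walk/pause semi-Markov bout process), the planted speed-conditioned
#' response curve, the response-motif kinematics, and the tracking-noise
#' model for one genotype.
#'
#' Key kinematic constants: `response_accel` is the motif ramp rate in
#' mm/s^2 and must exceed the 200 mm/s^2 robustness threshold so that
#' planted reactions are detectable; `transition_accel` is the gentler ramp
#' of voluntary walk/pause transitions and must stay below the threshold so
#' spontaneous bout edges never masquerade as reactions. Tracking noise is
#' AR(1)-correlated centroid jitter with marginal SD `jitter_sigma` (mm) and
#' correlation time `jitter_tau` (s); centroid error in deterministic blob
#' tracking is dominated by slowly varying segmentation bias, not white
#' per-frame noise (see the methods vignette).
#'
#' @param name Genotype label.
#' @param n_flies Default cohort size (13: one arena load, a single fly per
#'   tunnel in each of the 13 tunnels).
#' @param walk_speed_meanlog,walk_speed_sdlog Log-normal parameters of the
#'   per-bout walking speed (mm/s).
#' @param pause_probability Long-run fraction of time stationary, in [0, 1].
#' @param bout_walk_mean Mean walk-bout duration, s (pause-bout mean is
#'   derived from `pause_probability`).
#' @param response_curve Probability matrix from [default_response_curve()]
#'   or compatible.
#' @param response_latency,latency_sd Mean and SD of response latency, s.
#' @param response_accel Motif ramp rate, mm/s^2 (> 200).
#' @param transition_accel Voluntary transition ramp rate, mm/s^2 (< 200).
#' @param stop_duration_meanlog,stop_duration_sdlog,stop_duration_range
#'   Log-normal stop-duration distribution (s) and clipping range.
#' @param slow_floor,slow_floor_frac Slow-down target speed:
#'   `max(slow_floor, slow_floor_frac * speed)` mm/s.
#' @param slow_hold,speedup_hold Hold times of the slow-down / speed-up
#'   motifs, s.
#' @param speedup_boost,speedup_frac Speed-up increment:
#'   `max(speedup_boost, speedup_frac * speed)` mm/s.
#' @param max_speed Hard speed cap, mm/s.
#' @param fluct_sd,fluct_tau AR(1) within-bout speed fluctuation SD (mm/s)
#'   and correlation time (s).
#' @param jitter_sigma,jitter_tau Tracking-noise marginal SD (mm) and
#'   correlation time (s).
#' @param fps Tracker frame rate, frames/s.
#' @return Object of class `genotype_params`.
#' @export
genotype_params <- function(name = "control",
                            n_flies = 13L,
                            walk_speed_meanlog = log(9),
                            walk_speed_sdlog = 0.35,
                            pause_probability = 0.25,
                            bout_walk_mean = 3,
                            response_curve = default_response_curve(),
                            response_latency = 0.08,
                            latency_sd = 0.01,
                            response_accel = 800,
                            transition_accel = 60,
                            stop_duration_meanlog = log(0.5),
                            stop_duration_sdlog = 0.4,
                            stop_duration_range = c(0.25, 3),
                            slow_floor = 1.5,
                            slow_floor_frac = 0.25,
                            slow_hold = 0.4,
                            speedup_boost = 8,
                            speedup_frac = 0.8,
                            speedup_hold = 0.3,
                            max_speed = 35,
                            fluct_sd = 0.3,
                            fluct_tau = 0.2,
                            jitter_sigma = 0.05,
                            jitter_tau = 10,
                            fps = 100) {
  stopifnot(pause_probability >= 0, pause_probability <= 1,
            bout_walk_mean > 0, n_flies >= 1,
            response_latency > 0, latency_sd >= 0,
            stop_duration_range[1] > 0,
            stop_duration_range[2] >= stop_duration_range[1],
            jitter_sigma >= 0, jitter_tau > 0, fps > 0)
  if (response_accel <= 200)
    stop("response_accel must exceed the 200 mm/s^2 robustness threshold",
         call. = FALSE)
  if (transition_accel >= 200)
    stop("transition_accel must stay below the 200 mm/s^2 threshold",
         call. = FALSE)
  check_response_curve(response_curve)
  p <- as.list(environment())
  class(p) <- "genotype_params"
  p
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf("<genotype_params> %s: median walk %.1f mm/s, pause fraction %.2f, %d flies\n",
              x$name, exp(x$walk_speed_meanlog), x$pause_probability, x$n_flies))
  invisible(x)
}

#' Preset parameter sets
#'
#' `control_params()` is the baseline genotype. `parkin_like_params()`
#' emulates a hypokinetic mutant: walk speeds scaled by 0.75 and the
#' no-reaction probability scaled by 1.3 (rows renormalized). These presets
#' are configuration for synthetic experiments, not estimates of any real
#' fly line.
#'
#' @param ... Overrides forwarded to [genotype_params()].
#' @return A `genotype_params` object.
#' @export
control_params <- function(...) genotype_params(name = "control", ...)

#' @rdname control_params
#' @export
parkin_like_params <- function(...) {
  curve <- default_response_curve()
  curve[, "no_reaction"] <- pmin(1, curve[, "no_reaction"] * 1.3)
  other <- c("stop", "slow_down", "speed_up")
  resid <- 1 - curve[, "no_reaction"]
  base <- rowSums(curve[, other])
  scale <- ifelse(base > 0, resid / base, 0)
  curve[, other] <- curve[, other] * scale
  attr(curve, "edges") <- speed_bins()
  genotype_params(name = "parkin_like",
                  walk_speed_meanlog = log(9) + log(0.75),
                  response_curve = curve, ...)
}

#' @rdname control_params
#' @export
archetype_params <- function(...) {
  genotype_params(name = "archetype",
                  response_curve = archetype_response_curve(),
                  slow_floor_frac = 0, ...)
}

#' Generate a shadow-stimulus schedule
#'
#' Inter-trial intervals are drawn as `iti_min + Exponential(mean = iti_mean
#' - iti_min)`: approximately exponential with grand mean `iti_mean` and a
#' floor keeping consecutive shadows apart. Defaults reproduce the assay
#' protocol: 40 trials of 2 s shadows at a mean interval of 52.2 s,
#' preventing temporal expectation of the next stimulus.
#'
#' @param n_trials Number of shadow presentations (default 40).
#' @param iti_mean Mean inter-trial interval, s (default 52.2).
#' @param iti_min Minimum inter-trial interval, s (default 15).
#' @param shadow_duration Shadow-on time, s (default 2).
#' @param seed Optional seed for reproducibility.
#' @return A [stimulus_schedule()]; its `session_length` is extended past the
#'   default 2400 s when the drawn onsets require it.
#' @export
generate_schedule <- function(n_trials = 40L, iti_mean = 52.2, iti_min = 15,
                              shadow_duration = 2, seed = NULL) {
  if (n_trials < 0) stop("n_trials must be >= 0", call. = FALSE)
  if (iti_min < 0 || iti_mean <= iti_min)
    stop("need iti_mean > iti_min >= 0", call. = FALSE)
  set_seed_if(seed)
  if (n_trials == 0L)
    return(stimulus_schedule(numeric(0), shadow_duration = shadow_duration))
  itis <- iti_min + stats::rexp(n_trials, rate = 1 / (iti_mean - iti_min))
  onsets <- cumsum(itis)
  len <- max(2400, ceiling(onsets[n_trials] + shadow_duration + 30))
  stimulus_schedule(onsets, shadow_duration = shadow_duration,
                    session_length = len)
}

# Piecewise-constant bout skeleton with gentle ramps at voluntary
# transitions. Spontaneous transitions are deferred out of guard windows
# around stimulus onsets so every trial has a well-defined pre-stimulus
# state (see vignette). Returns the per-frame base speed.
build_bout_speed <- function(params, n, dt, guards) {
  if (params$pause_probability >= 1) return(numeric(n))
  pause_mean <- if (params$pause_probability > 0)
    params$bout_walk_mean * params$pause_probability /
      (1 - params$pause_probability) else 0
  in_guard <- function(t) {
    if (!nrow(guards)) return(FALSE)
    any(t >= guards$from & t <= guards$to)
  }
  guard_end <- function(t) max(guards$to[t >= guards$from & t <= guards$to])
  speed <- numeric(n)
  rate <- params$transition_accel * dt        # mm/s change per frame
  t <- 0
  cur <- 0                                    # current speed at frame edge
  walking <- stats::runif(1) > params$pause_probability
  while (t < n * dt) {
    dur <- if (walking) stats::rexp(1, 1 / params$bout_walk_mean)
           else if (pause_mean > 0) stats::rexp(1, 1 / pause_mean)
           else n * dt
    end <- t + dur
    if (in_guard(end)) end <- guard_end(end) + 0.01
    target <- if (walking)
      min(params$max_speed,
          stats::rlnorm(1, params$walk_speed_meanlog, params$walk_speed_sdlog))
    else 0
    i0 <- floor(t / dt) + 1L
    i1 <- min(n, floor(end / dt))
    if (i1 >= i0) {
      len <- i1 - i0 + 1L
      n_ramp <- min(len, ceiling(abs(target - cur) / rate))
      vals <- rep(target, len)
      if (n_ramp > 0)
        vals[seq_len(n_ramp)] <-
          cur + (target - cur) * seq_len(n_ramp) / n_ramp
      speed[i0:i1] <- vals
      cur <- vals[len]
    }
    t <- end
    walking <- !walking
  }
  speed
}

# Inject one response motif into the speed vector, in place.
# Returns the modified speed vector.
inject_motif <- function(speed, label, m0, params, dt, stop_dur) {
  n <- length(speed)
  if (m0 > n) return(speed)
  s0 <- speed[m0]
  ramp_step <- params$response_accel * dt
  gentle <- params$transition_accel * dt
  relax <- function(from_idx, start_val, sgn) {
    # ramp gently from start_val back toward the evolving baseline
    if (from_idx > n) return(speed)
    L <- min(n - from_idx + 1L, ceiling((params$max_speed + 5) / gentle))
    idx <- from_idx:(from_idx + L - 1L)
    ramp <- start_val + sgn * gentle * seq_len(L)
    speed[idx] <<- if (sgn > 0) pmin(speed[idx], ramp) else pmax(speed[idx], ramp)
    speed
  }
  if (label == "stop") {
    # ramp holds only strictly positive frames so the zero hold is exactly
    # n_hold frames long and the planted duration is recoverable
    n_ramp <- ceiling(s0 / ramp_step) - 1L
    n_hold <- max(1L, round(stop_dur / dt))
    i <- m0
    if (n_ramp > 0) {
      idx <- i:min(n, i + n_ramp - 1L)
      speed[idx] <- pmax(0, s0 - ramp_step * seq_along(idx))
      i <- i + n_ramp
    }
    idx <- i:min(n, i + n_hold - 1L)
    speed[idx] <- 0
    speed <- relax(min(n, i + n_hold), 0, +1)
  } else if (label == "slow_down") {
    floor_v <- max(params$slow_floor, params$slow_floor_frac * s0)
    if (floor_v < s0) {
      n_ramp <- ceiling((s0 - floor_v) / ramp_step)
      n_hold <- max(1L, round(params$slow_hold / dt))
      i <- m0
      idx <- i:min(n, i + n_ramp - 1L)
      speed[idx] <- pmax(floor_v, s0 - ramp_step * seq_along(idx))
      i <- i + n_ramp
      idx <- i:min(n, i + n_hold - 1L)
      speed[idx] <- floor_v
      speed <- relax(min(n, i + n_hold), floor_v, +1)
    }
  } else if (label == "speed_up") {
    target <- min(params$max_speed,
                  s0 + max(params$speedup_boost, params$speedup_frac * s0))
    n_ramp <- ceiling((target - s0) / ramp_step)
    n_hold <- max(1L, round(params$speedup_hold / dt))
    i <- m0
    idx <- i:min(n, i + n_ramp - 1L)
    speed[idx] <- pmin(target, s0 + ramp_step * seq_along(idx))
    i <- i + n_ramp
    idx <- i:min(n, i + n_hold - 1L)
    speed[idx] <- target
    speed <- relax(min(n, i + n_hold), target, -1)
  }
  speed
}

# Map cumulative path length to tunnel coordinates. The fly runs along the
# tunnel axis and reverses direction at the ends via constant-speed
# semicircular U-turns (radius r), so direction reversals never produce
# spurious speed transients in the centroid trace.
path_position <- function(arc, tunnel, r = 1.5, margin = 2, phase = 0) {
  L <- tunnel[1]; W <- tunnel[2]
  r <- min(r, (W - 1) / 2)
  xa <- margin + r
  xb <- L - margin - r
  D <- xb - xa
  yc <- W / 2
  P <- 2 * (D + pi * r)
  u <- (arc + phase) %% P
  x <- numeric(length(u)); y <- numeric(length(u))
  s1 <- u < D
  s2 <- !s1 & u < D + pi * r
  s3 <- !s1 & !s2 & u < 2 * D + pi * r
  s4 <- !(s1 | s2 | s3)
  x[s1] <- xa + u[s1];            y[s1] <- yc - r
  th <- (u[s2] - D) / r
  x[s2] <- xb + r * sin(th);      y[s2] <- yc - r * cos(th)
  x[s3] <- xb - (u[s3] - D - pi * r); y[s3] <- yc + r
  th <- (u[s4] - 2 * D - pi * r) / r
  x[s4] <- xa - r * sin(th);      y[s4] <- yc + r * cos(th)
  cbind(x = x, y = y)
}

# AR(1) noise with marginal sd sigma and correlation time tau (s).
ar1_noise <- function(n, sigma, tau, dt) {
  if (sigma <= 0) return(numeric(n))
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sigma)))
}

#' Generate one fly's tracked session with planted responses
#'
#' Builds a 100 Hz trajectory from the two-state walk/pause bout process,
#' measures the true pre-stimulus speed at each scheduled shadow onset, draws
#' a response label from the genotype's speed-conditioned curve, and injects
#' the corresponding kinematic motif after the response latency: a
#' deceleration to zero held for a drawn stop duration; a deceleration to a
#' non-zero floor; an acceleration burst; or no change. The trajectory is
#' confined to the tunnel (constant-speed U-turns at the ends) and observed
#' through AR(1)-correlated centroid jitter.
#'
#' @param params A [genotype_params()].
#' @param schedule A [stimulus_schedule()]; must fit inside its own
#'   `session_length`.
#' @param seed Optional seed.
#' @param fly_id Identifier (default derived from the genotype name).
#' @param jitter_sigma Override of the params' tracking-noise SD (mm); set 0
#'   for noise-free sessions.
#' @return List with elements `session` (a [tracked_session()]) and
#'   `ground_truth` (data.frame: trial, label, latency_s, stop_duration_s,
#'   v_pre).
#' @export
generate_fly_session <- function(params, schedule, seed = NULL,
                                 fly_id = paste0(params$name, "_01"),
                                 jitter_sigma = params$jitter_sigma) {
  stopifnot(inherits(params, "genotype_params"),
            inherits(schedule, "stimulus_schedule"))
  dt <- 1 / params$fps
  if (schedule$n_trials > 0 &&
      max(schedule$onsets) + 5 > schedule$session_length)
    stop("schedule extends past the session length", call. = FALSE)
  set_seed_if(seed)
  n <- round(schedule$session_length / dt)
  onsets <- schedule$onsets
  guards <- data.frame(from = onsets - 0.25, to = onsets + 1.5)

  speed <- build_bout_speed(params, n, dt, guards)
  # within-bout AR(1) fluctuation, faded out near zero speed
  flu <- ar1_noise(n, params$fluct_sd, params$fluct_tau, dt)
  speed <- pmax(0, speed + flu * pmin(1, speed / 2))

  labels <- response_labels()
  gt <- data.frame(trial = seq_len(schedule$n_trials),
                   label = character(schedule$n_trials),
                   latency_s = NA_real_, stop_duration_s = NA_real_,
                   v_pre = NA_real_, stringsAsFactors = FALSE)
  edges <- attr(params$response_curve, "edges")
  for (tr in seq_len(schedule$n_trials)) {
    k0 <- floor(onsets[tr] / dt) + 1L
    pre <- max(1L, k0 - 20L):(k0 - 1L)
    v_pre <- mean(speed[pre])
    bin <- findInterval(v_pre, edges)
    probs <- params$response_curve[bin, ]
    lab <- sample(labels, 1L, prob = probs)
    lat <- max(0.03, stats::rnorm(1, params$response_latency, params$latency_sd))
    stop_dur <- NA_real_
    if (lab == "stop") {
      stop_dur <- min(params$stop_duration_range[2],
                      max(params$stop_duration_range[1],
                          stats::rlnorm(1, params$stop_duration_meanlog,
                                        params$stop_duration_sdlog)))
    }
    m0 <- k0 + round(lat / dt)
    speed <- inject_motif(speed, lab, m0, params, dt, stop_dur)
    gt$label[tr] <- lab
    gt$latency_s[tr] <- lat
    gt$stop_duration_s[tr] <- stop_dur
    gt$v_pre[tr] <- v_pre
  }

  arc <- cumsum(speed) * dt
  phase <- stats::runif(1, 0, 1) * 2 * (default_tunnel()[1] - 7)
  pos <- path_position(arc, c(52, 5), phase = phase)
  ex <- ar1_noise(n, jitter_sigma, params$jitter_tau, dt)
  ey <- ar1_noise(n, jitter_sigma, params$jitter_tau, dt)
  session <- tracked_session(
    fly_id = fly_id,
    timestamps = (seq_len(n) - 1L) * dt,
    x = pos[, "x"] + ex, y = pos[, "y"] + ey,
    genotype = params$name, age_days = 7L,
    meta = list(synthetic = TRUE))
  list(session = session, ground_truth = gt)
}

#' Generate a multi-genotype synthetic cohort
#'
#' `n_flies` sessions per genotype, each with its own schedule and a child
#' seed spawned deterministically from the master seed; the manifest lists
#' every seed used.
#'
#' @param params_by_genotype Named list of [genotype_params()] (names must be
#'   unique; they become the genotype labels of the fly ids).
#' @param n_trials,iti_mean,iti_min,shadow_duration Schedule parameters, see
#'   [generate_schedule()].
#' @param seed Master seed (default 1).
#' @param n_flies Optional override of each params' `n_flies`.
#' @param jitter_sigma Optional override of the tracking-noise SD.
#' @return List with `sessions` (list of [tracked_session()]),
#'   `schedules` (parallel list), `ground_truth` (one data.frame with a
#'   `fly_id` column), and `manifest` (seeds and parameters).
#' @export
generate_cohort <- function(params_by_genotype, n_trials = 40L,
                            iti_mean = 52.2, iti_min = 15,
                            shadow_duration = 2, seed = 1L,
                            n_flies = NULL, jitter_sigma = NULL) {
  if (!length(params_by_genotype)) stop("need >= 1 genotype", call. = FALSE)
  if (is.null(names(params_by_genotype)))
    names(params_by_genotype) <- vapply(params_by_genotype, `[[`, "", "name")
  if (anyDuplicated(names(params_by_genotype)))
    stop("duplicate genotype names would create duplicate fly ids", call. = FALSE)
  sessions <- list(); schedules <- list(); gts <- list()
  seeds <- list()
  for (gi in seq_along(params_by_genotype)) {
    p <- params_by_genotype[[gi]]
    gname <- names(params_by_genotype)[gi]
    p$name <- gname
    nf <- if (is.null(n_flies)) p$n_flies else n_flies
    for (f in seq_len(nf)) {
      id <- sprintf("%s_%02d", gname, f)
      s_sched <- derive_seed(seed, gi * 10000L + f * 2L)
      s_fly <- derive_seed(seed, gi * 10000L + f * 2L + 1L)
      sched <- generate_schedule(n_trials, iti_mean, iti_min,
                                 shadow_duration, seed = s_sched)
      js <- if (is.null(jitter_sigma)) p$jitter_sigma else jitter_sigma
      out <- generate_fly_session(p, sched, seed = s_fly, fly_id = id,
                                  jitter_sigma = js)
      sessions[[id]] <- out$session
      schedules[[id]] <- sched
      gts[[id]] <- cbind(fly_id = id, genotype = gname, out$ground_truth,
                         stringsAsFactors = FALSE)
      seeds[[id]] <- c(schedule = s_sched, session = s_fly)
    }
  }
  if (anyDuplicated(names(sessions)))
    stop("duplicate fly ids in cohort", call. = FALSE)
  list(sessions = sessions, schedules = schedules,
       ground_truth = do.call(rbind, c(gts, list(make.row.names = FALSE))),
       manifest = list(master_seed = seed, seeds = seeds,
                       n_trials = n_trials, iti_mean = iti_mean,
                       iti_min = iti_min))
}
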