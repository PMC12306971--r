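# Shared fixtures and independent oracles, built in code at test time.

# Build a single trial trace from a 120-bin speed vector (10 ms bins,
# window [-0.2, 1.0) s), computing baseline and accelerations the same way
# extract_trials does.
make_trace <- function(speed, bin_s = 0.01, window = c(-0.2, 1.0)) {
  rel <- seq(window[1], window[2] - bin_s / 2, by = bin_s)
  stopifnot(length(speed) == length(rel))
  v_pre <- mean(speed[rel < 0])
  structure(list(time_grid = rel, speed = speed,
                 normalized = speed - v_pre,
                 accel = compute_acceleration(speed, bin_s, 0.1),
                 accel_raw = compute_acceleration(speed, bin_s, 0),
                 v_pre = v_pre, valid = TRUE, reason = NA_character_,
                 onset = 0, bin_s = bin_s, fly_id = "fixture", trial = 1L),
            class = "trial_trace")
}

# Speed vectors for the four archetype motifs (120 bins).
motif_speed <- function(label, v0 = 12, latency_bins = 8) {
  s <- rep(v0, 120)
  k <- 20 + latency_bins   # first post-onset motif bin
  if (label == "stop") {
    s[k:120] <- 0
    s[(k + 35):120] <- v0   # resume after 350 ms
    s[(k + 35):min(120, k + 35 + 14)] <-
      pmin(v0, 0.6 * seq_len(min(120, k + 35 + 14) - (k + 35) + 1))
  } else if (label == "slow_down") {
    s[k:120] <- v0 / 3
    s[(k + 40):120] <- pmin(v0, v0 / 3 + 0.6 * seq_len(120 - (k + 40) + 1))
  } else if (label == "speed_up") {
    s[k:120] <- v0 + 10
    s[(k + 30):120] <- pmax(v0, v0 + 10 - 0.6 * seq_len(120 - (k + 30) + 1))
  }
  s
}

# A session walking at constant speed v along the tunnel axis, bouncing via
# the in-package trajectory not used: positions built directly, slow enough
# to stay within the tunnel.
constant_speed_session <- function(v = 1, duration = 40, fps = 100,
                                   fly_id = "const") {
  n <- duration * fps
  ts <- (seq_len(n) - 1) / fps
  tracked_session(fly_id, ts, x = 1 + v * ts, y = rep(2.5, n))
}

# Exact two-sided Mann-Whitney p by full enumeration over group
# assignments (tie-free samples only); independent of stats::wilcox.test.
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Draw pre-stimulus speeds from a walk/pause mixture resembling the
# generator's stationary fraction and log-normal walking speeds.
draw_v_pre <- function(n, p_pause = 0.25, meanlog = log(9), sdlog = 0.35) {
  paused <- stats::runif(n) < p_pause
  v <- stats::rlnorm(n, meanlog, sdlog)
  v[paused] <- abs(stats::rnorm(sum(paused), 0, 0.15))
  v
}

# Draw labels from a probability matrix at given speeds and return a
# classified-trials data.frame suitable for build_curve.
draw_classified <- function(v_pre, curve) {
  edges <- attr(curve, "edges")
  bin <- findInterval(v_pre, edges)
  labs <- response_labels()
  lab <- vapply(bin, function(b) sample(labs, 1, prob = curve[b, ]), "")
  data.frame(fly_id = "sim", trial = seq_along(v_pre), label = lab,
             v_pre = v_pre, valid = TRUE, stringsAsFactors = FALSE)
}

count_labels <- function(labels) {
  vapply(response_labels(), function(l) sum(labels == l), numeric(1))
}
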