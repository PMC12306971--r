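test_that("threshold rules label the four archetype motifs correctly", {
  # constant speed: |a| = 0 < 200 everywhere
  expect_equal(classify_trial(make_trace(rep(10, 120)))$label, "no_reaction")
  # stationary fly bursting to 15 mm/s in 50 ms: speed up even from rest
  s <- rep(0, 120); s[29:33] <- 3 * (1:5); s[34:120] <- 15
  expect_equal(classify_trial(make_trace(s))$label, "speed_up")
  # planted stop 12 -> 0 over 50 ms held 300 ms
  s <- rep(12, 120); s[29:33] <- 12 - 2.4 * (1:5); s[34:63] <- 0
  s[64:120] <- 12
  got <- classify_trial(make_trace(s))
  expect_equal(got$label, "stop")
  expect_equal(got$first_crossing_sign, "-")
  # planted slow-down 10 -> 4 then gentle re-acceleration
  s <- rep(10, 120); s[29:31] <- 10 - 2 * (1:3); s[32:70] <- 4
  s[71:120] <- pmin(10, 4 + 0.5 * seq_len(50))
  got <- classify_trial(make_trace(s))
  expect_equal(got$label, "slow_down")
  expect_gt(got$min_post_speed, 0.5)
})

test_that("a hard re-acceleration after an incomplete stop is a slow down", {
  # decelerates 12 -> 4, then re-crosses +200 before ever reaching v_zero
  s <- rep(12, 120); s[29:32] <- 12 - 2 * (1:4); s[33:50] <- 4
  s[51:55] <- 4 + 2.5 * (1:5); s[56:120] <- 16.5
  got <- classify_trial(make_trace(s))
  expect_equal(got$label, "slow_down")
})

test_that("traces scaled below the threshold are always no reaction (monotonicity)", {
  set.seed(42)
  for (i in 1:50) {
    raw <- abs(stats::rnorm(120, 5, 3))
    tr <- make_trace(raw)
    peak <- max(abs(tr$accel_raw[tr$time_grid >= 0]))
    scaled <- tr$v_pre + (raw - tr$v_pre) * (150 / peak)
    scaled <- pmax(0, scaled)
    tr2 <- make_trace(scaled)
    if (max(abs(tr2$accel_raw[tr2$time_grid >= 0])) < 200)
      expect_equal(classify_trial(tr2)$label, "no_reaction")
  }
})

test_that("every valid trial gets exactly one label; stationary flies never stop or slow", {
  set.seed(7)
  labs <- response_labels()
  for (i in 1:2000) {
    v0 <- stats::runif(1, 0, 15)
    s <- pmax(0, v0 + cumsum(stats::rnorm(120, 0, stats::runif(1, 0, 2))))
    got <- classify_trial(make_trace(s))
    expect_true(got$label %in% labs)
    if (got$v_pre <= 0.5)
      expect_true(got$label %in% c("speed_up", "no_reaction"))
  }
})

test_that("invalid traces are unscored but never dropped", {
  ses <- constant_speed_session(v = 1, duration = 10)
  sch <- stimulus_schedule(c(0.1, 5), session_length = 10)
  cls <- classify_trials(extract_trials(compute_speed_series(ses), sch))
  expect_equal(nrow(cls), 2L)
  expect_true(is.na(cls$label[1]))
  prof <- summarize_profile(cls)
  expect_equal(prof$n_attempted, 2L)
  expect_equal(prof$n_valid, 1L)
})

test_that("stop durations are measured in the full series and censored at the cap", {
  bin_s <- 0.01
  sp <- rep(8, 4000)
  sp[501:530] <- 0                        # 0.30 s stop at t = 5 s
  ser <- structure(list(t = (0:3999) * bin_s, speed = sp, bin_s = bin_s,
                        gap_bins = rep(FALSE, 4000), fly_id = "m"),
                   class = "speed_series")
  got <- measure_stop_duration(ser, onset = 4.9, next_onset = 20)
  expect_equal(got$duration, 0.30, tolerance = 0.0101)
  expect_false(got$censored)

  sp2 <- rep(8, 4000); sp2[501:4000] <- 0  # never resumes
  ser2 <- structure(list(t = (0:3999) * bin_s, speed = sp2, bin_s = bin_s,
                         gap_bins = rep(FALSE, 4000), fly_id = "m"),
                    class = "speed_series")
  got2 <- measure_stop_duration(ser2, onset = 4.9, next_onset = 20)
  expect_true(got2$censored)
  expect_equal(got2$duration, 20 - 5, tolerance = 0.02)

  # a slow-down trial violates the precondition
  sp3 <- rep(8, 4000); sp3[501:600] <- 3
  ser3 <- structure(list(t = (0:3999) * bin_s, speed = sp3, bin_s = bin_s,
                         gap_bins = rep(FALSE, 4000), fly_id = "m"),
                    class = "speed_series")
  expect_error(measure_stop_duration(ser3, onset = 4.9, next_onset = 20),
               "not a stop trial")
})

test_that("profiles report proportions over valid trials that sum to one", {
  labs <- response_labels()
  cls <- data.frame(fly_id = "f1",
                    label = rep(labs, c(17, 10, 5, 8)),
                    valid = TRUE, stringsAsFactors = FALSE)
  p <- summarize_profile(cls)
  expect_equal(c(p$p_stop, p$p_slow_down, p$p_speed_up, p$p_no_reaction),
               c(0.425, 0.25, 0.125, 0.2))
  expect_equal(p$p_stop + p$p_slow_down + p$p_speed_up + p$p_no_reaction, 1)

  allnone <- data.frame(fly_id = "f2", label = rep("no_reaction", 5),
                        valid = TRUE, stringsAsFactors = FALSE)
  p2 <- summarize_profile(allnone)
  expect_equal(c(p2$p_stop, p2$p_slow_down, p2$p_speed_up, p2$p_no_reaction),
               c(0, 0, 0, 1))

  bad <- data.frame(fly_id = c("f1", "f3"), label = c("stop", NA),
                    valid = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_warning(summarize_profile(bad), "no valid trials")
})
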