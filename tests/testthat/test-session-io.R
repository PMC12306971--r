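test_that("pixel coordinates are calibrated to mm on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,timestamp_s,x,y",
               "0,0.00,10,5", "1,0.01,11,5", "2,0.02,12,5"), f)
  s <- read_tracking(f, calibration = 0.5, unit = "px")
  expect_equal(diff(s$x), c(0.5, 0.5))
  expect_equal(s$calibration, 0.5)
})

test_that("non-monotonic timestamps are a data error naming the row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,timestamp_s,x,y",
               "0,0.00,1,1", "1,0.01,2,1", "2,0.01,3,1"), f)
  expect_error(read_tracking(f), "row 3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,foo,bar", "0,1,2"), f2)
  expect_error(read_tracking(f2), "x/y")
})

test_that("session and schedule round-trip through files is the identity", {
  sch <- stimulus_schedule(c(10, 21.5), session_length = 30)
  out <- generate_fly_session(control_params(), sch, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracking(out$session, f)
  back <- read_tracking(f, fly_id = out$session$fly_id)
  expect_lt(max(abs(back$x - out$session$x)), 1e-9)
  expect_lt(max(abs(back$y - out$session$y)), 1e-9)
  expect_lt(max(abs(back$timestamps - out$session$timestamps)), 1e-9)

  g <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sch, g)
  sch2 <- read_schedule(g, session_length = 30)
  expect_equal(sch2$onsets, sch$onsets, tolerance = 1e-9)
  expect_equal(sch2$n_trials, 2L)
  expect_equal(sch2$shadow_duration, 2)
})

test_that("schedule reading validates onset order and span", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial,onset_s,duration_s", "1,10,2", "2,70,2", "3,130,2"), f)
  sch <- read_schedule(f)
  expect_equal(sch$n_trials, 3L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial,onset_s,duration_s", "1,70,2", "2,10,2"), f2)
  expect_error(read_schedule(f2), "ascending")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("trial,onset_s,duration_s", f3)
  expect_equal(read_schedule(f3)$n_trials, 0L)

  expect_warning(stimulus_schedule(c(10, 3000)), "beyond session_length")
})

test_that("empty onset lists are valid and yield no trials downstream", {
  empty <- stimulus_schedule(numeric(0))
  expect_equal(empty$n_trials, 0L)
  ses <- constant_speed_session()
  tr <- extract_trials(compute_speed_series(ses), empty)
  expect_length(tr$valid, 0L)
})

test_that("write_results emits tidy tables plus a manifest, deterministically", {
  labs <- response_labels()
  trials <- data.frame(fly_id = "a", trial = 1:40,
                       label = rep(labs, 10), stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  files <- write_results(list(trials = trials), d, config = list(x = 1),
                         seed = 7)
  tab <- read.csv(file.path(d, "classified_trials.csv"))
  expect_equal(nrow(tab), 40L)
  expect_true(all(tab$label %in% labs))
  expect_true(file.exists(file.path(d, "manifest.json")))

  d2 <- withr::local_tempdir()
  write_results(list(trials = trials), d2, config = list(x = 1), seed = 7)
  expect_identical(readLines(file.path(d, "classified_trials.csv")),
                   readLines(file.path(d2, "classified_trials.csv")))

  d3 <- withr::local_tempdir()
  write_results(list(trials = trials[0, ]), d3)
  expect_equal(nrow(read.csv(file.path(d3, "classified_trials.csv"))), 0L)
  expect_true(file.exists(file.path(d3, "manifest.json")))
})

test_that("short tracking gaps are interpolated, long gaps flagged", {
  ts <- (0:299) / 100
  x <- 1 + ts; y <- rep(2.5, 300)
  x[c(10, 11)] <- NA; y[c(10, 11)] <- NA        # 2-frame gap
  x[40:48] <- NA; y[40:48] <- NA                # 9-frame gap
  s <- tracked_session("g", ts, x, y)
  s2 <- interpolate_gaps(s, max_gap = 3)
  expect_equal(s2$x[10:11], 1 + ts[10:11], tolerance = 1e-12)
  lg <- attr(s2, "long_gaps")
  expect_equal(nrow(lg), 1L)
  expect_true(anyNA(s2$x[40:48]))

  ser <- compute_speed_series(s)
  sch <- stimulus_schedule(c(0.42), session_length = 1)
  tr <- extract_trials(ser, sch)
  expect_false(tr$valid[1])
  expect_match(tr$reason[1], "gap")
})

test_that("config files override defaults and unknown keys warn", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("v_zero: 0.8", "nonsense_key: 3"), f)
  expect_warning(cfg <- read_config(f), "nonsense_key")
  expect_equal(cfg$v_zero, 0.8)
  expect_equal(cfg$accel_threshold, default_config()$accel_threshold)
})
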