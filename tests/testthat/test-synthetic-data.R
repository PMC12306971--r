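test_that("schedule generation is reproducible and respects the ITI floor", {
  a <- generate_schedule(seed = 4)
  b <- generate_schedule(seed = 4)
  expect_identical(a$onsets, b$onsets)
  expect_equal(a$n_trials, 40L)
  expect_true(all(diff(a$onsets) >= 15))
  expect_equal(generate_schedule(n_trials = 0, seed = 1)$n_trials, 0L)
  expect_error(generate_schedule(iti_mean = 10, iti_min = 15), "iti_mean")
})

test_that("a fully paused fly has zero speed and never plants stop or slow", {
  sch <- generate_schedule(n_trials = 12, seed = 2)
  out <- generate_fly_session(control_params(pause_probability = 1), sch,
                              seed = 2, jitter_sigma = 0)
  expect_true(all(out$ground_truth$v_pre == 0))
  expect_true(all(out$ground_truth$label %in% c("speed_up", "no_reaction")))
})

test_that("a degenerate all-no-reaction curve yields only no-reaction trials", {
  cv <- default_response_curve()
  cv[] <- 0; cv[, "no_reaction"] <- 1
  attr(cv, "edges") <- speed_bins()
  sch <- generate_schedule(n_trials = 10, seed = 3)
  out <- generate_fly_session(control_params(response_curve = cv), sch,
                              seed = 3)
  cls <- analyze_session(out$session, sch)
  expect_true(all(out$ground_truth$label == "no_reaction"))
  expect_true(all(cls$label == "no_reaction"))
})

test_that("planted label frequencies match the configured curve (multinomial oracle)", {
  p <- control_params()
  sch <- generate_schedule(seed = 21)
  labs <- response_labels()
  obs <- numeric(4); expct <- numeric(4); var_sum <- numeric(4)
  edges <- attr(p$response_curve, "edges")
  for (s in 1:5) {
    out <- generate_fly_session(p, sch, seed = 300 + s, jitter_sigma = 0)
    gt <- out$ground_truth
    obs <- obs + count_labels(gt$label)
    # oracle: exact multinomial expectation from the planted v_pre values
    bins <- findInterval(gt$v_pre, edges)
    expct <- expct + colSums(p$response_curve[bins, , drop = FALSE])
    pr <- p$response_curve[bins, , drop = FALSE]
    var_sum <- var_sum + colSums(pr * (1 - pr))
  }
  z <- (obs - expct) / sqrt(pmax(var_sum, 1e-9))
  expect_true(all(abs(z) < 4))
})

test_that("generated kinematics stay physical: speeds >= 0, positions in the tunnel", {
  sch <- generate_schedule(n_trials = 5, seed = 8)
  out <- generate_fly_session(control_params(), sch, seed = 8)
  s <- out$session
  expect_true(all(s$x > -0.5 & s$x < 52.5))
  expect_true(all(s$y > -0.5 & s$y < 5.5))
  ser <- compute_speed_series(s)
  expect_true(all(ser$speed >= 0, na.rm = TRUE))
})

test_that("cohorts have unique fly ids and are reproducible from the master seed", {
  pars <- list(geno_a = control_params(), geno_b = control_params())
  c1 <- generate_cohort(pars, n_trials = 3, seed = 5, n_flies = 3)
  expect_length(c1$sessions, 6L)
  expect_false(anyDuplicated(names(c1$sessions)) > 0)
  c2 <- generate_cohort(pars, n_trials = 3, seed = 5, n_flies = 3)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$sessions[[1]]$x, c2$sessions[[1]]$x)
  expect_named(c1$manifest$seeds)

  expect_error(generate_cohort(list(a = control_params(),
                                    a = control_params()),
                               n_trials = 2, seed = 1, n_flies = 1),
               "duplicate")
})

test_that("a schedule extending past the session length is a parameter error", {
  sch <- stimulus_schedule(c(10, 29), session_length = 30)
  expect_error(generate_fly_session(control_params(), sch, seed = 1),
               "session length")
})

test_that("the pipeline recovers the planted group differences (planted effect)", {
  coh <- generate_cohort(list(control = control_params(),
                              parkin_like = parkin_like_params()),
                         seed = 202, n_flies = 20)
  res <- analyze_cohort(coh$sessions, coh$schedules)
  v <- res$trials[res$trials$valid, ]
  spd <- tapply(v$v_pre, v$fly_id, mean)
  gt <- sub("_[0-9]+$", "", names(spd))
  cmp_speed <- compare_groups(spd[gt == "control"], spd[gt == "parkin_like"],
                              metric = "mean pre-stimulus speed")
  expect_lt(cmp_speed$p_value, 0.05)
  expect_equal(cmp_speed$direction, "decrease")
  # planted effect: walk speeds scaled by 0.75, i.e. a 25% decrease
  expect_true(cmp_speed$percent_change < -15 && cmp_speed$percent_change > -35)

  pr <- res$profiles
  gt2 <- sub("_[0-9]+$", "", pr$fly_id)
  cmp_none <- compare_groups(pr$p_no_reaction[gt2 == "control"],
                             pr$p_no_reaction[gt2 == "parkin_like"],
                             metric = "no-reaction proportion")
  expect_lt(cmp_none$p_value, 0.05)
  expect_equal(cmp_none$direction, "increase")
})
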