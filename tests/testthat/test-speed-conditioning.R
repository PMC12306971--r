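test_that("curve probabilities are empirical per-bin label frequencies", {
  cls <- data.frame(fly_id = "a", trial = 1:10, label = rep("stop", 10),
                    v_pre = rep(7, 10), valid = TRUE,
                    stringsAsFactors = FALSE)
  cv <- build_curve(cls)
  b <- findInterval(7, cv$edges)
  expect_equal(unname(cv$prob[b, "stop"]), 1)
  expect_equal(cv$n[b], 10)
  # unpopulated bins are flagged, not imputed
  expect_true(all(is.na(cv$prob[cv$n == 0, ])))
  expect_error(build_curve(cls[0, ]), "no valid")
})

test_that("the zero-speed bin never carries stop or slow probability", {
  sch <- generate_schedule(n_trials = 15, seed = 13)
  out <- generate_fly_session(control_params(pause_probability = 0.8), sch,
                              seed = 13)
  cls <- analyze_session(out$session, sch)
  cv <- build_curve(cls)
  zb <- which(cv$edges[-length(cv$edges)] < 0.5 & cv$n > 0)
  if (length(zb)) {
    expect_equal(unname(cv$counts[zb, "stop"]), 0)
    expect_equal(unname(cv$counts[zb, "slow_down"]), 0)
  }
})

test_that("the recovered curve matches the planted curve per bin (noise-free)", {
  p <- control_params()
  sch <- generate_schedule(seed = 17)
  trials <- list()
  for (s in 1:5) {
    out <- generate_fly_session(p, sch, seed = 400 + s, jitter_sigma = 0)
    trials[[s]] <- analyze_session(out$session, sch)
  }
  cls <- do.call(rbind, trials)
  cv <- build_curve(cls, edges = attr(p$response_curve, "edges"))
  for (b in which(cv$n >= 15)) {
    ph <- cv$prob[b, ]
    pt <- p$response_curve[b, ]
    se <- sqrt(pt * (1 - pt) / cv$n[b])
    expect_true(all(abs(ph - pt) <= 4 * se + 0.02))
  }
})

test_that("degenerate curves drive the virtual cohort deterministically", {
  cvm <- default_response_curve()
  cls <- data.frame(fly_id = "a", trial = 1:20,
                    label = rep("no_reaction", 20),
                    v_pre = runif(20, 6, 12), valid = TRUE,
                    stringsAsFactors = FALSE)
  cv <- build_curve(cls)
  vc <- simulate_virtual_cohort(cls$v_pre, cv, n_virtual = 500, seed = 1)
  expect_equal(unname(vc$predicted["no_reaction"]), 500)
  expect_equal(sum(vc$predicted), 500)
  expect_error(simulate_virtual_cohort(numeric(0), cv), "empty speed sample")
})

test_that("all-zero speeds draw labels solely from the stationary bin", {
  cls <- data.frame(fly_id = "a", trial = 1:40,
                    label = rep(c("speed_up", "no_reaction"), 20),
                    v_pre = rep(c(0, 8), each = 20), valid = TRUE,
                    stringsAsFactors = FALSE)
  cls$label[cls$v_pre == 8] <- "stop"
  cv <- build_curve(cls)
  vc <- simulate_virtual_cohort(rep(0, 10), cv, n_virtual = 400, seed = 2)
  expect_equal(unname(vc$predicted["stop"]), 0)
  expect_equal(unname(vc$predicted["speed_up"] + vc$predicted["no_reaction"]),
               400)
})

test_that("virtual proportions converge to the exact mixture (mixture oracle)", {
  set.seed(19)
  v <- draw_v_pre(800)
  curve_true <- default_response_curve()
  cls <- draw_classified(v, curve_true)
  cv <- build_curve(cls)
  vc <- simulate_virtual_cohort(v, cv, n_virtual = 3000, seed = 3)
  # oracle: exact mixture over bins of the empirical curve
  bins <- findInterval(v, cv$edges)
  wt <- table(factor(bins, levels = seq_along(cv$n))) / length(v)
  mix <- colSums(cv$prob * as.numeric(wt), na.rm = TRUE)
  prop <- vc$predicted / vc$n_virtual
  se <- sqrt(mix * (1 - mix) / vc$n_virtual)
  expect_true(all(abs(prop - mix) <= 4 * se + 1e-6))
})

test_that("chi-square closed forms match hand computation", {
  o <- c(stop = 100, slow_down = 0, speed_up = 0, no_reaction = 0)
  e <- c(stop = 1, slow_down = 1, speed_up = 1, no_reaction = 1)
  got <- test_prediction(o, e, method = "expected")
  expect_equal(got$statistic, 300)
  expect_equal(got$df, 3)

  o2 <- c(stop = 10, slow_down = 20, speed_up = 30, no_reaction = 40)
  e2 <- 2 * o2
  expect_equal(test_prediction(o2, e2, method = "expected")$statistic, 0)
  expect_equal(test_prediction(o2, e2, method = "expected")$p_value, 1)
  expect_equal(test_prediction(o2, e2, method = "sample")$statistic, 0)
  expect_error(test_prediction(0 * o2, e2), "all-zero")
})

test_that("categories unsupported by the virtual cohort are merged", {
  o <- c(stop = 5, slow_down = 10, speed_up = 3, no_reaction = 40)
  e <- c(stop = 0, slow_down = 30, speed_up = 20, no_reaction = 50)
  expect_message(got <- test_prediction(o, e), "merged")
  expect_equal(got$df, 2)
  expect_equal(sum(got$observed), sum(o))
})

test_that("a planted curve shift is detected against speed-matched virtual flies", {
  set.seed(23)
  pool <- draw_v_pre(4000)
  cv <- build_curve(draw_classified(pool, default_response_curve()))
  # shifted behavior: 15 percentage points moved from reactive labels to
  # no-reaction in every populated bin, speeds unchanged
  shifted <- cv$prob
  pop <- which(cv$n > 0)
  for (b in pop) {
    take <- pmin(shifted[b, c("stop", "slow_down", "speed_up")], 0.05)
    shifted[b, c("stop", "slow_down", "speed_up")] <-
      shifted[b, c("stop", "slow_down", "speed_up")] - take
    shifted[b, "no_reaction"] <- shifted[b, "no_reaction"] + sum(take)
  }
  attr(shifted, "edges") <- cv$edges
  rej <- 0L
  for (r in 1:20) {
    v_obs <- sample(pool, 500, replace = TRUE)
    obs <- count_labels(draw_classified(v_obs, shifted)$label)
    vc <- simulate_virtual_cohort(v_obs, cv, n_virtual = 3000, seed = 900 + r)
    if (test_prediction(obs, vc)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 20, 0.9)
})
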