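test_that("psychometric points conserve counts and handle degenerate proportions", {
  tr <- make_trials(frequency = rep(8, 100), choice = "left")
  pts <- psychometric_points(tr)
  expect_identical(nrow(pts), 1L)
  expect_equal(pts$fraction_rightward, 0)
  expect_equal(pts$ci_low, 0)
  expect_gt(pts$ci_high, 0)

  p <- session_params(n_trials = 400, invalid_rate = 0.1, laser_fraction = 0.3,
                      seed = 41)
  sess <- simulate_discrimination_session(p)
  for (sub in c("all", "laser", "control")) {
    pts <- psychometric_points(sess, sub)
    v <- valid_trials(sess)
    v <- switch(sub, all = v, laser = v[v$laser, ], control = v[!v$laser, ])
    expect_identical(sum(pts$n_trials), nrow(v))
    expect_true(all(pts$ci_low <= pts$fraction_rightward &
                      pts$fraction_rightward <= pts$ci_high))
  }
  expect_identical(nrow(psychometric_points(sess)), 6L)  # 6 center frequencies
})

test_that("an empty subset yields an empty result rather than an error", {
  tr <- make_trials(rep(8, 10), "left", laser = FALSE)
  pts <- psychometric_points(tr, "laser")
  expect_identical(nrow(pts), 0L)
})

test_that("the fit recovers generating psychometric parameters", {
  p <- session_params(n_trials = 500 * 6, psych_midpoint = 11, psych_slope = 8,
                      lapse_low = 0.02, lapse_high = 0.02, seed = 42)
  tr <- simulate_discrimination_session(p)
  fit <- fit_logistic_psychometric(psychometric_points(tr))
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - log(11)), 0.05)
  expect_lt(abs(fit$beta - 8) / 8, 0.2)
  # no optimizer regression: likelihood at the fit beats the generating truth
  # (same convention as the fit: binomial kernel without the choose() term)
  pts <- psychometric_points(tr)
  pr <- generating_p_right(pts$frequency, p)
  gen_ll <- sum(pts$n_rightward * log(pr) +
                  (pts$n_trials - pts$n_rightward) * log(1 - pr))
  expect_gte(fit$loglik, gen_ll - 1e-6)
})

test_that("symmetric step data put the midpoint at the central geometric mean", {
  freqs <- c(6, 8, 11, 15, 20, 27)
  pts <- data.frame(frequency = freqs, n_trials = 200,
                    n_rightward = c(0, 0, 0, 200, 200, 200))
  fit <- fit_logistic_psychometric(pts)
  expect_lt(abs(fit$alpha - log(sqrt(11 * 15))), 0.07)
})

test_that("all-rightward data push the upper lapse to its bound, flagged", {
  pts <- data.frame(frequency = c(6, 8, 11, 15, 20, 27), n_trials = 100,
                    n_rightward = 100)
  fit <- fit_logistic_psychometric(pts, lapse_bounds = c(0, 0.3))
  expect_lt(fit$lapse_high, 1e-4)
  expect_true(fit$on_boundary)
})

test_that("choice-flip symmetry mirrors the fitted parameters", {
  p <- session_params(n_trials = 1500, seed = 43)
  tr <- simulate_discrimination_session(p)
  pts <- psychometric_points(tr)
  mirrored <- pts
  mirrored$n_rightward <- pts$n_trials - pts$n_rightward
  f1 <- fit_logistic_psychometric(pts)
  f2 <- fit_logistic_psychometric(mirrored)
  expect_equal(f2$alpha, f1$alpha, tolerance = 0.02)
  expect_equal(f2$beta, -f1$beta, tolerance = 0.05)
  expect_equal(f2$lapse_low, f1$lapse_high, tolerance = 0.02)
  expect_equal(f2$lapse_high, f1$lapse_low, tolerance = 0.02)
})

test_that("stimulation bias recovers null, programmed, and extreme effects", {
  tr0 <- make_trials(rep(c(8, 18), 50), rep(c("left", "right"), each = 50),
                     laser = rep(c(TRUE, FALSE), 50))
  expect_equal(stimulation_bias(tr0)$bias, 0)

  # all right with laser, all left without
  tr1 <- make_trials(rep(12.5, 40), rep(c("right", "left"), each = 20),
                     laser = rep(c(TRUE, FALSE), each = 20))
  expect_equal(stimulation_bias(tr1)$bias, 1)

  expect_error(stimulation_bias(make_trials(rep(8, 10), "left")), "laser")

  # antisymmetry under swapping the laser/control labels
  p <- session_params(n_trials = 600, laser_fraction = 0.5,
                      laser_bias_shift = 0.15, psych_slope = 2, seed = 44)
  tr <- simulate_discrimination_session(p)
  swapped <- tr; swapped$laser <- !tr$laser
  expect_equal(stimulation_bias(swapped)$bias, -stimulation_bias(tr)$bias)
})

test_that("a programmed bias shift is recovered within binomial tolerance", {
  biases <- vapply(1:4, function(s) {
    p <- session_params(n_trials = 1000, laser_fraction = 0.5,
                        laser_bias_shift = 0.2, psych_slope = 0,
                        psych_midpoint = 100, lapse_low = 0.1, lapse_high = 0,
                        seed = 100 + s)
    stimulation_bias(simulate_discrimination_session(p))$bias
  }, numeric(1))
  expect_lt(abs(mean(biases) - 0.2), 0.03)
})

test_that("switching performance tracks the oracle and the learning agent", {
  oracle <- simulate_switching_session(
    switching_params(n_blocks = 3, learning_trials = 0, error_rate = 0, seed = 45))
  perf <- switching_performance(oracle)
  expect_equal(perf$blocks$accuracy, rep(1, 3))
  expect_equal(perf$session_accuracy, 1)

  p <- switching_params(n_blocks = 4, learning_trials = 15, seed = 46)
  tr <- simulate_switching_session(p)
  perf <- switching_performance(tr, window = 30)
  # trailing moving average agrees with a brute-force scan over valid trials
  v <- valid_trials(tr)
  brute <- vapply(seq_len(nrow(v)), function(i)
    mean(v$correct[max(1, i - 29):i]), numeric(1))
  expect_equal(perf$trial$moving_accuracy, brute)
  # block accuracies agree with direct means
  direct <- vapply(split(v$correct, v$block_id), mean, numeric(1))
  expect_equal(perf$blocks$accuracy, unname(direct))
  expect_true(all(perf$blocks$accuracy >= 0.6))  # session usable downstream
  expect_error(switching_performance(tr, window = 0), "window")
})

test_that("trials to criterion counts switching-stimulus trials per switch", {
  oracle <- simulate_switching_session(
    switching_params(n_blocks = 4, learning_trials = 0, error_rate = 0, seed = 47))
  tc <- trials_to_criterion(oracle, n_consecutive = 4)
  expect_equal(tc$n_to_criterion, rep(4L, 3))

  p <- switching_params(n_blocks = 6, learning_trials = 15, error_rate = 0.02,
                        seed = 48)
  tc <- trials_to_criterion(simulate_switching_session(p))
  med <- median(tc$n_to_criterion, na.rm = TRUE)
  expect_gt(med, 4)
  expect_lte(med, 20)

  slow <- switching_params(n_blocks = 4, learning_trials = 40, error_rate = 0.02,
                           seed = 49)
  tc2 <- trials_to_criterion(simulate_switching_session(slow))
  expect_true(all(tc2$n_to_criterion > 20, na.rm = TRUE))
})
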