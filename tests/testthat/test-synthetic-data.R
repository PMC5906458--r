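test_that("generated trial tables satisfy the timing and validity invariants", {
  for (seed in 1:5) {
    p <- session_params(n_trials = 300, invalid_rate = 0.1, laser_fraction = 0.2,
                        seed = seed)
    tr <- simulate_discrimination_session(p)
    v <- valid_trials(tr)
    expect_true(all(v$t_center_in < v$t_sound_on))
    expect_true(all(v$t_sound_on < v$t_side_in))
    delay <- tr$t_sound_on - tr$t_center_in
    expect_true(all(delay >= p$delay_range[1] & delay <= p$delay_range[2]))
    # valid trials stay in the port past sound offset; invalid ones leave early
    expect_true(all(v$t_center_out >= v$t_sound_on + p$stim_duration))
    inv <- tr[!tr$valid, ]
    expect_true(all(inv$t_center_out < inv$t_sound_on + p$stim_duration))
    expect_true(all(is.na(inv$choice)))
    expect_true(all(tr$frequency %in% p$freq_set))
  }
})

test_that("fixed seed reproduces a session exactly; different seeds differ", {
  p <- session_params(n_trials = 200, laser_fraction = 0.2, seed = 11)
  expect_identical(simulate_discrimination_session(p),
                   simulate_discrimination_session(p))
  p2 <- session_params(n_trials = 200, laser_fraction = 0.2, seed = 12)
  expect_false(identical(simulate_discrimination_session(p),
                         simulate_discrimination_session(p2)))
})

test_that("a flat decision rule gives ~50% rightward at every frequency", {
  p <- session_params(n_trials = 3000, psych_slope = 0, lapse_low = 0,
                      lapse_high = 0, seed = 2)
  tr <- simulate_discrimination_session(p)
  pts <- psychometric_points(tr)
  # 4 sigma binomial band per frequency (family of 6 comparisons), and a
  # 3 sigma band on the pooled fraction
  tol <- 4 * sqrt(0.25 / pts$n_trials)
  expect_true(all(abs(pts$fraction_rightward - 0.5) < tol))
  pooled <- mean(valid_trials(tr)$choice == "right")
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("laser trials are an exact 20% subset at n = 1000", {
  p <- session_params(n_trials = 1000, laser_fraction = 0.2, seed = 3)
  tr <- simulate_discrimination_session(p)
  expect_identical(sum(tr$laser), 200L)
})

test_that("empirical choice fractions converge to the generating logistic", {
  p <- session_params(n_trials = 12000, seed = 4)
  tr <- simulate_discrimination_session(p)
  pts <- psychometric_points(tr)
  target <- generating_p_right(pts$frequency, p)
  expect_lt(max(abs(pts$fraction_rightward - target)), 0.035)
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(session_params(laser_fraction = 1.5), "laser_fraction")
  expect_error(session_params(lapse_low = 0.7), "lapse_low")
  expect_error(session_params(delay_range = c(0.3, 0.2)), "delay_range")
  expect_error(session_params(freq_set = c(10, 8)), "freq_set")
  expect_error(switching_params(stimuli = c(5, 4, 3)), "stimuli")
  expect_error(unit_params(baseline_rate = -2), "baseline_rate")
})

test_that("switching sessions alternate contingencies within block-length bounds", {
  p <- switching_params(n_blocks = 4, seed = 5)
  tr <- simulate_switching_session(p)
  blocks <- parse_blocks(tr)
  expect_identical(nrow(blocks), 4L)
  lens <- blocks$last_trial - blocks$first_trial + 1
  expect_true(all(lens >= 200 & lens <= 250))
  expect_true(all(blocks$contingency[-1] != blocks$contingency[-4]))
  # only the two stimuli of the current boundary appear in each block
  for (b in seq_len(4)) {
    fb <- unique(tr$frequency[tr$block_id == b])
    expected <- if (blocks$contingency[b] == "low_boundary")
      p$stimuli[1:2] else p$stimuli[2:3]
    expect_setequal(fb, expected)
  }
})

test_that("a perfect agent is 100% correct; a learning agent reverses then recovers", {
  oracle <- simulate_switching_session(
    switching_params(n_blocks = 3, learning_trials = 0, error_rate = 0, seed = 6))
  expect_true(all(oracle$correct))

  p <- switching_params(n_blocks = 4, learning_trials = 15, seed = 7)
  tr <- simulate_switching_session(p)
  blocks <- parse_blocks(tr)
  mid <- switching_stimulus(tr)
  pos <- tr$trial_id - blocks$first_trial[match(tr$block_id, blocks$block_id)] + 1
  early_mid <- tr$block_id > 1 & pos <= 15 & tr$frequency == mid
  late <- pos >= 21
  expect_lt(mean(tr$correct[early_mid]), 0.5)
  expect_gt(mean(tr$correct[late]), 0.9)
})

test_that("homogeneous unit counts are Poisson with the programmed rate", {
  tr <- simulate_discrimination_session(session_params(n_trials = 400, seed = 8))
  u <- simulate_unit(tr, unit_params(baseline_rate = 10, refractory = 0, seed = 8))
  v <- valid_trials(tr)
  counts <- count_in_window(align_spikes(u, v$t_sound_on, c(-0.1, 0.1)), c(-0.1, 0))
  expect_equal(mean(counts), 10 * 0.1, tolerance = 0.12)
  # index of dispersion consistent with Poisson
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("evoked gain produces the analytic sound response index", {
  tr <- simulate_discrimination_session(session_params(n_trials = 800, seed = 9))
  u <- simulate_unit(tr, unit_params(baseline_rate = 10, evoked_gain = 2,
                                     tuning_width = 50, refractory = 0, seed = 9))
  v <- valid_trials(tr)
  ev <- count_in_window(align_spikes(u, v$t_sound_on, c(0, 0.1)), c(0, 0.1))
  ba <- count_in_window(align_spikes(u, v$t_sound_on, c(-0.1, 0)), c(-0.1, 0))
  r <- sound_response_index(ev, ba)
  expect_lt(abs(r$index - 1 / 3), 0.05)

  supp <- simulate_unit(tr, unit_params(baseline_rate = 10, evoked_gain = 0.3,
                                        tuning_width = 50, refractory = 0, seed = 10))
  ev2 <- count_in_window(align_spikes(supp, v$t_sound_on, c(0, 0.1)), c(0, 0.1))
  ba2 <- count_in_window(align_spikes(supp, v$t_sound_on, c(-0.1, 0)), c(-0.1, 0))
  expect_lt(sound_response_index(ev2, ba2)$index, 0)
})

test_that("unit substreams are independent of each other and of behavior", {
  tr <- simulate_discrimination_session(session_params(n_trials = 100, seed = 20))
  u1 <- simulate_unit(tr, unit_params(unit_id = 1, seed = 20))
  u2 <- simulate_unit(tr, unit_params(unit_id = 2, seed = 20))
  expect_false(identical(u1$spike_times, u2$spike_times))
  expect_identical(u1$spike_times,
                   simulate_unit(tr, unit_params(unit_id = 1, seed = 20))$spike_times)
})

test_that("head trajectory encodes the programmed rotation with missing frames", {
  hp <- simulate_head_trajectory(stim_onsets = c(2, 6), rotation_per_stim = 0,
                                 noise_sd = 0, seed = 1)
  ang <- centroids_to_angle(hp)
  expect_equal(max(abs(ang$angle)), 0, tolerance = 1e-9)

  hp2 <- simulate_head_trajectory(stim_onsets = c(2, 6), rotation_per_stim = 121,
                                  missing_fraction = 0.2, seed = 2)
  expect_equal(sum(is.na(hp2$x1)) / (nrow(hp2) - 2), 0.2, tolerance = 0.01)
  truth <- attr(hp2, "ground_truth")
  expect_equal(truth[length(truth)], 242, tolerance = 1e-9)
})

test_that("session bundles round-trip through disk", {
  tr <- simulate_discrimination_session(session_params(n_trials = 50, seed = 30))
  u <- simulate_unit(tr, unit_params(unit_id = "a", seed = 30))
  hp <- simulate_head_trajectory(2, 90, seed = 30)
  dir <- withr::local_tempdir()
  write_session_bundle(list(trials = tr, units = list(u), headpose = hp,
                            meta = list(boundary = 12)), dir)
  b <- read_session_bundle(dir)
  expect_equal(b$trials$t_sound_on, tr$t_sound_on)
  expect_equal(b$units[[1]]$spike_times, u$spike_times)
  expect_identical(b$units[[1]]$hemisphere, u$hemisphere)
  expect_equal(b$meta$boundary, 12)
  expect_equal(nrow(b$headpose), nrow(hp))
})
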