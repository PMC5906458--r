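test_that("movement modulation recovers programmed ipsi/contra rate factors", {
  expect_equal(movement_modulation_index(rep(2, 20), rep(2, 20))$index, 0)
  expect_equal(movement_modulation_index(rep(3, 20), rep(0, 20))$index, 1)
  expect_true(is.na(movement_modulation_index(rep(0, 5), rep(0, 5))$index))
  expect_error(movement_modulation_index(numeric(0), 1:3), "both movement")

  # programmed ipsi 8 Hz vs contra 12 Hz in the 100 ms movement window:
  # expected index (0.8 - 1.2)/(0.8 + 1.2) = -0.2
  tr <- simulate_discrimination_session(session_params(n_trials = 600, seed = 70))
  u <- simulate_unit(tr, unit_params(baseline_rate = 10,
                                     movement_gain_ipsi = 0.8,
                                     movement_gain_contra = 1.2,
                                     hemisphere = "right", seed = 70))
  v <- valid_trials(tr)
  mc <- count_in_window(align_spikes(u, v$t_center_out, c(0.05, 0.15)),
                        c(0.05, 0.15))
  ipsi <- v$choice == "right"
  mm <- movement_modulation_index(mc[ipsi], mc[!ipsi])
  expect_lt(abs(mm$index - (-0.2)), 0.05)
  expect_true(mm$significant)
})

test_that("z-score responsiveness is null on identical bins, fires on evoked units", {
  # identical distribution in every bin: homogeneous unit
  tr <- simulate_discrimination_session(session_params(n_trials = 200, seed = 71))
  v <- valid_trials(tr)
  u0 <- simulate_unit(tr, unit_params(baseline_rate = 15, seed = 71))
  z0 <- zscore_responsiveness(align_spikes(u0, v$t_sound_on, c(-0.05, 0.1)))
  expect_identical(nrow(z0), 4L)
  expect_true(all(abs(z0$z) < 3.5))

  u1 <- simulate_unit(tr, unit_params(baseline_rate = 10, evoked_gain = 3,
                                      tuning_width = 50, seed = 72))
  r1 <- align_spikes(u1, v$t_sound_on, c(-0.05, 0.1))
  expect_true(is_responsive(zscore_responsiveness(r1)))

  expect_error(zscore_responsiveness(align_spikes(u1, numeric(0), c(-0.05, 0.1))),
               "zero trials")
})

test_that("the 4-bin criterion's family-wise false-positive rate matches simulation", {
  # analytic guide: 4 bins at |z| >= 3 give at most 4 * 2 * pnorm(-3) ~ 1.1%;
  # positive dependence between bins and count discreteness keep the realized
  # rate at or below that bound
  hits <- withr::with_seed(73, {
    vapply(1:400, function(i) {
      base <- matrix(rpois(5 * 150, 0.3), nrow = 150)  # 25 ms bins at 12 Hz
      zs <- apply(base[, 2:5], 2, function(cc)
        soundchoice:::ranksum_z(cc, base[, 1]))
      any(abs(zs) >= 3)
    }, logical(1))
  })
  expect_lt(mean(hits), 0.02)
})

test_that("choice modulation detects programmed gains and not null data", {
  expect_equal(choice_modulation(rep(2, 30), rep(2, 30))$index, 0)
  tr <- simulate_discrimination_session(session_params(n_trials = 500, seed = 74))
  v <- valid_trials(tr)
  u <- simulate_unit(tr, unit_params(baseline_rate = 15, choice_gain = 1.8,
                                     evoked_gain = 2, tuning_width = 50,
                                     hemisphere = "right", seed = 74))
  sc <- count_in_window(align_spikes(u, v$t_sound_on, c(0, 0.1)), c(0, 0.1))
  ipsi <- v$choice == "right"
  cm <- choice_modulation(sc[ipsi], sc[!ipsi])
  expect_gt(cm$index, 0)
  expect_true(cm$significant)

  u0 <- simulate_unit(tr, unit_params(baseline_rate = 15, choice_gain = 1,
                                      evoked_gain = 2, tuning_width = 50,
                                      seed = 75))
  sc0 <- count_in_window(align_spikes(u0, v$t_sound_on, c(0, 0.1)), c(0, 0.1))
  expect_lt(abs(choice_modulation(sc0[ipsi], sc0[!ipsi])$index), 0.1)
  expect_error(choice_modulation(numeric(0), 1:3), "both choices")
})

test_that("label-permuted choice data reject at the nominal rate", {
  rej <- withr::with_seed(76, {
    vapply(1:1000, function(i) {
      cc <- rpois(120, 1.5)
      lab <- sample(rep(c(TRUE, FALSE), each = 60))
      choice_modulation(cc[lab], cc[!lab])$significant
    }, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("analysis stimulus picks the stronger-responding near-boundary frequency", {
  p <- session_params(n_trials = 600, seed = 77)
  tr <- simulate_discrimination_session(p)
  fs <- sort(p$freq_set)
  near <- fs[order(abs(log(fs) - log(12)))][1:2]
  # tuned exactly to the upper near-boundary stimulus
  u <- simulate_unit(tr, unit_params(baseline_rate = 10, evoked_gain = 3,
                                     tuning_peak = max(near), tuning_width = 0.5,
                                     seed = 77))
  expect_equal(select_analysis_stimulus(u, tr, 12), max(near))
  # an untuned unit ties at ~0 and falls back to the lower frequency
  u0 <- simulate_unit(tr, unit_params(baseline_rate = 0, seed = 78))
  expect_equal(select_analysis_stimulus(u0, tr, 12), min(near))
})

test_that("population summary aggregates counts, shift tests and correlations", {
  mk <- function(idx, p) modulation_result(idx, 10, 10, p)
  res <- list(mk(0, 1), mk(0, 1), mk(0.5, 0.01), mk(NA, 0.5))
  s <- population_summary(res)
  expect_identical(s$n_total, 4L)
  expect_identical(s$n_defined, 3L)
  expect_identical(s$n_significant, 1L)
  expect_equal(s$percent_significant, fraction_percent(1, 3))

  # all-zero indices: signed-rank p = 1 by convention
  s0 <- population_summary(list(mk(0, 1), mk(0, 0.9)))
  expect_equal(s0$signed_rank_p, 1)

  # a shifted index population is detected
  shifted <- withr::with_seed(79, lapply(rnorm(500, -0.1, 0.2), mk, p = 0.5))
  expect_lt(population_summary(shifted)$signed_rank_p, 0.001)

  # perfectly monotone pairing gives Spearman r = 1
  a <- lapply(seq(0.1, 0.9, length.out = 10), mk, p = 0.5)
  b <- lapply(seq(-0.5, 0.5, length.out = 10), mk, p = 0.5)
  sp <- population_summary(a, paired_with = b)
  expect_equal(sp$spearman_r, 1)

  # independent magnitudes are uncorrelated
  ab <- withr::with_seed(80, list(a = lapply(runif(500, -1, 1), mk, p = 0.5),
                                  b = lapply(runif(500, -1, 1), mk, p = 0.5)))
  expect_lt(abs(population_summary(ab$a, ab$b)$spearman_r), 0.1)

  expect_error(population_summary(list(mk(NA, 0.5))), "no defined")
})

test_that("Fisher utility compares two detection fractions", {
  ft <- fisher_fraction_test(24, 520, 43, 520)
  expect_equal(ft$p_value,
               fisher.test(matrix(c(24, 496, 43, 477), 2))$p.value)
  expect_lt(fisher_fraction_test(5, 500, 50, 500)$p_value, 0.001)
})
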