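# Synthetic session generator ------------------------------------------------
#
# Sessions emulate a rodent auditory two-alternative choice (2AC) task: the
# animal pokes into a center port, waits through a 150-250 ms silent delay,
# hears a 100 ms chord, then reports low/high frequency at the left/right
# side port.  Units are piecewise-constant-rate Poisson processes so every
# downstream index has an exact analytic expectation.

#' Parameters for a frequency-discrimination session
#'
#' Defaults describe a single session of the fixed-boundary task: 6
#' log-spaced chord center frequencies spanning two octaves, a categorization
#' boundary at their geometric center, a uniform 150-250 ms pre-stimulus
#' delay, a 100 ms stimulus, and logistic choice behavior with small lapse
#' rates.  Optogenetic stimulation trials ("laser") are drawn as a random
#' subset and shift the rightward-choice probability additively.
#'
#' @param n_trials number of trials.
#' @param freq_set strictly increasing chord center frequencies (kHz).
#' @param boundary categorization boundary (kHz); frequencies above it are
#'   rewarded at the right port.
#' @param delay_range uniform silent-delay range in seconds (default 0.15-0.25).
#' @param stim_duration stimulus duration in seconds (default 0.1).
#' @param laser_fraction proportion of trials with optogenetic stimulation.
#' @param psych_midpoint midpoint of the generating logistic (kHz).
#' @param psych_slope slope of the logistic per natural-log kHz.
#' @param lapse_low,lapse_high asymptotic lapse probabilities, each in [0, 0.5).
#' @param laser_bias_shift additive change in rightward-choice probability on
#'   laser trials (result clipped to [0, 1]).
#' @param invalid_rate probability a trial is aborted by early withdrawal
#'   (default 0; invalid trials are excluded from all analyses).
#' @param iti_range inter-trial interval range in seconds.
#' @param seed master seed; component substreams are derived from it.
#' @return A validated list of class `session_params`.
#' @export
session_params <- function(n_trials = 500,
                           freq_set = round(exp(seq(log(6), log(24), length.out = 6)), 2),
                           boundary = 12,
                           delay_range = c(0.15, 0.25),
                           stim_duration = 0.1,
                           laser_fraction = 0,
                           psych_midpoint = 12,
                           psych_slope = 8,
                           lapse_low = 0.02,
                           lapse_high = 0.02,
                           laser_bias_shift = 0,
                           invalid_rate = 0,
                           iti_range = c(1.5, 2.5),
                           seed = 1L) {
  check_number(n_trials, "n_trials", lower = 1)
  if (length(freq_set) < 1 || any(diff(freq_set) <= 0) || any(freq_set <= 0))
    stopf("parameter `freq_set` must be strictly increasing and positive")
  check_number(boundary, "boundary", lower = 0)
  if (length(delay_range) != 2 || delay_range[1] <= 0 || delay_range[1] >= delay_range[2])
    stopf("parameter `delay_range` must satisfy 0 < low < high")
  check_number(stim_duration, "stim_duration", lower = 1e-6)
  check_number(laser_fraction, "laser_fraction", lower = 0, upper = 1)
  check_number(psych_midpoint, "psych_midpoint", lower = 1e-9)
  check_number(psych_slope, "psych_slope")
  check_number(lapse_low, "lapse_low", lower = 0, upper = 0.5 - 1e-9)
  check_number(lapse_high, "lapse_high", lower = 0, upper = 0.5 - 1e-9)
  check_number(laser_bias_shift, "laser_bias_shift", lower = -1, upper = 1)
  check_number(invalid_rate, "invalid_rate", lower = 0, upper = 1)
  structure(as.list(environment()), class = "session_params")
}

#' Parameters for a contingency-switching session
#'
#' The switching task reuses the 2AC structure but alternates the rewarded
#' action for the intermediate stimulus across blocks of 200-250 trials: in a
#' low-boundary block the animal discriminates low vs. mid (mid rewarded
#' right); in a high-boundary block, mid vs. high (mid rewarded left).  Only
#' two of the three stimuli appear in a block and no cue marks the switch.
#' The simulated agent follows the previous block's boundary for
#' `learning_trials` trials after each switch, then the current one, with a
#' stimulus-independent choice error rate.
#'
#' @param n_blocks number of blocks (>= 1).
#' @param block_length_range inclusive range of block lengths in trials.
#' @param stimuli three increasing frequencies (low, mid, high) in kHz.
#' @param initial_contingency `"low_boundary"` or `"high_boundary"`.
#' @param learning_trials trials after a switch during which the agent still
#'   applies the previous contingency.
#' @param error_rate probability a choice is flipped (lapses/exploration).
#' @param invalid_rate,delay_range,stim_duration,iti_range,seed as in
#'   [session_params()].
#' @return A validated list of class `switching_params`.
#' @export
switching_params <- function(n_blocks = 3,
                             block_length_range = c(200, 250),
                             stimuli = c(6, 12, 24),
                             initial_contingency = c("low_boundary", "high_boundary"),
                             learning_trials = 15,
                             error_rate = 0.05,
                             invalid_rate = 0,
                             delay_range = c(0.15, 0.25),
                             stim_duration = 0.1,
                             iti_range = c(1.5, 2.5),
                             seed = 1L) {
  check_number(n_blocks, "n_blocks", lower = 1)
  if (length(stimuli) != 3 || any(diff(stimuli) <= 0) || any(stimuli <= 0))
    stopf("parameter `stimuli` must be three increasing positive frequencies")
  if (length(block_length_range) != 2 ||
      block_length_range[1] < 1 || block_length_range[1] > block_length_range[2])
    stopf("parameter `block_length_range` must satisfy 1 <= low <= high")
  initial_contingency <- match.arg(initial_contingency)
  check_number(learning_trials, "learning_trials", lower = 0)
  check_number(error_rate, "error_rate", lower = 0, upper = 1)
  check_number(invalid_rate, "invalid_rate", lower = 0, upper = 1)
  structure(as.list(environment()), class = "switching_params")
}

#' Parameters for a simulated striatal unit
#'
#' A unit is a Poisson process with piecewise-constant rate: `baseline_rate`
#' everywhere, multiplied by a frequency-tuned evoked gain during the 100 ms
#' sound window, by a movement gain in the 50-150 ms window after center-port
#' exit, and by `choice_gain` during the sound window when the upcoming
#' choice is ipsilateral to the unit's hemisphere.  The evoked gain at a
#' frequency f is `1 + (evoked_gain - 1) * exp(-log2(f/peak)^2 / (2 w^2))`,
#' a Gaussian tuning profile in log2-frequency: at the preferred frequency
#' the rate is `baseline * evoked_gain` (values below 1 model suppressed
#' units); far from it the rate falls back to baseline.  An optional
#' monotone slow drift `1 + (drift_gain - 1)(1 - exp(-t/drift_tau))`
#' multiplies all rates, for testing robustness to nonstationarity.
#'
#' @param baseline_rate spontaneous rate (Hz).
#' @param tuning_peak preferred frequency (kHz).
#' @param tuning_width tuning width (octaves, sd of the log2 Gaussian).
#' @param evoked_gain multiplicative rate factor at the preferred frequency
#'   during the sound window; < 1 for suppressed units.
#' @param movement_gain_ipsi,movement_gain_contra rate factors in the
#'   post-exit movement window for ipsi/contralateral choices.
#' @param choice_gain rate factor in the sound window on ipsilateral-choice
#'   trials.
#' @param hemisphere `"left"` or `"right"` recording hemisphere; ipsilateral
#'   means the choice on the same side.
#' @param drift_gain asymptotic multiplicative drift (1 = stationary).
#' @param drift_tau drift time constant (s).
#' @param refractory absolute refractory period (s, default 0.0015): spikes
#'   closer than this to their predecessor are removed.  Set to 0 for an
#'   exact Poisson process; the default keeps simulated units within the
#'   2 ms / 2% ISI quality criterion while changing window counts by under
#'   a few percent at typical rates.
#' @param unit_id identifier used in bundle filenames.
#' @param seed substream seed for this unit.
#' @return A validated list of class `unit_params`.
#' @export
unit_params <- function(baseline_rate = 10,
                        tuning_peak = 12,
                        tuning_width = 1,
                        evoked_gain = 1,
                        movement_gain_ipsi = 1,
                        movement_gain_contra = 1,
                        choice_gain = 1,
                        hemisphere = c("right", "left"),
                        drift_gain = 1,
                        drift_tau = 600,
                        refractory = 0.0015,
                        unit_id = 1L,
                        seed = 1L) {
  check_number(baseline_rate, "baseline_rate", lower = 0)
  check_number(tuning_peak, "tuning_peak", lower = 1e-9)
  check_number(tuning_width, "tuning_width", lower = 1e-9)
  for (nm in c("evoked_gain", "movement_gain_ipsi", "movement_gain_contra",
               "choice_gain", "drift_gain"))
    check_number(get(nm), nm, lower = 0)
  check_number(drift_tau, "drift_tau", lower = 1e-9)
  check_number(refractory, "refractory", lower = 0)
  hemisphere <- match.arg(hemisphere)
  structure(as.list(environment()), class = "unit_params")
}

new_trial_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

assert_trial_table <- function(trials) {
  need <- c("trial_id", "t_center_in", "t_sound_on", "t_center_out", "t_side_in",
            "frequency", "block_id", "contingency", "choice", "correct",
            "laser", "valid")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stopf("trial table is missing column(s): %s", paste(miss, collapse = ", "))
  invisible(trials)
}

#' Valid trials of a trial table
#'
#' Aborted (early-withdrawal) trials are excluded from every analysis.
#' @param trials a trial table.
#' @return The subset of valid trials.
#' @export
valid_trials <- function(trials) {
  assert_trial_table(trials)
  trials[trials$valid, , drop = FALSE]
}

# Common timing model: center poke, silent delay, sound, withdrawal, side poke.
# Invalid trials withdraw during the sound and never reach a side port.
draw_trial_times <- function(n, delay_range, stim_duration, iti_range, invalid) {
  delay <- runif(n, delay_range[1], delay_range[2])
  hold <- stim_duration + runif(n, 0.05, 0.25)          # valid: stay past sound end
  hold[invalid] <- runif(sum(invalid), 0.01, stim_duration - 1e-3)
  travel <- runif(n, 0.2, 0.5)
  iti <- runif(n, iti_range[1], iti_range[2])
  t_center_in <- 0.5 + c(0, cumsum((delay + hold + travel + iti)[-n]))
  t_sound_on <- t_center_in + delay
  t_center_out <- t_sound_on + hold
  t_side_in <- t_center_out + travel
  t_side_in[invalid] <- NA_real_
  list(t_center_in = t_center_in, t_sound_on = t_sound_on,
       t_center_out = t_center_out, t_side_in = t_side_in)
}

#' Generating psychometric curve
#'
#' Rightward-choice probability of the generating model:
#' `lapse_low + (1 - lapse_low - lapse_high) * plogis(slope * (log f - log midpoint))`.
#'
#' @param frequency frequencies (kHz).
#' @param params a [session_params()] object.
#' @return Probabilities of a rightward choice.
#' @export
generating_p_right <- function(frequency, params) {
  params$lapse_low + (1 - params$lapse_low - params$lapse_high) *
    plogis(params$psych_slope * (log(frequency) - log(params$psych_midpoint)))
}

#' Simulate a frequency-discrimination session
#'
#' Draws one trial table under the generating logistic model described in
#' [session_params()].  Laser trials are an exact random subset of size
#' `round(laser_fraction * n_trials)` and get the additive bias shift.
#'
#' @param params a [session_params()] object.
#' @return A `trial_table` data frame (one row per trial) with event times in
#'   seconds from session start, stimulus frequency (kHz), block id,
#'   contingency label, choice, correctness, laser and validity flags.
#' @export
simulate_discrimination_session <- function(params) {
  if (!inherits(params, "session_params")) params <- do.call(session_params, params)
  n <- as.integer(params$n_trials)
  withr::with_seed(substream_seed(params$seed, "behavior"), {
    frequency <- sample(params$freq_set, n, replace = TRUE)
    laser <- rep(FALSE, n)
    n_laser <- round(params$laser_fraction * n)
    if (n_laser > 0) laser[sample.int(n, n_laser)] <- TRUE
    invalid <- runif(n) < params$invalid_rate
    p_right <- generating_p_right(frequency, params)
    p_right[laser] <- pmin(1, pmax(0, p_right[laser] + params$laser_bias_shift))
    choice <- ifelse(runif(n) < p_right, "right", "left")
    choice[invalid] <- NA_character_
    tm <- draw_trial_times(n, params$delay_range, params$stim_duration,
                           params$iti_range, invalid)
    correct <- (choice == "right") == (frequency > params$boundary)
    new_trial_table(data.frame(
      trial_id = seq_len(n),
      t_center_in = tm$t_center_in, t_sound_on = tm$t_sound_on,
      t_center_out = tm$t_center_out, t_side_in = tm$t_side_in,
      frequency = frequency, block_id = 1L, contingency = "fixed",
      choice = choice, correct = correct, laser = laser, valid = !invalid,
      stringsAsFactors = FALSE))
  })
}

# Rewarded side for a stimulus under a contingency.
rewarded_side <- function(frequency, contingency, stimuli) {
  boundary <- ifelse(contingency == "low_boundary",
                     sqrt(stimuli[1] * stimuli[2]),
                     sqrt(stimuli[2] * stimuli[3]))
  ifelse(frequency > boundary, "right", "left")
}

#' Simulate a contingency-switching session
#'
#' Blocks of 200-250 trials alternate between the low-boundary and the
#' high-boundary contingency; only the two stimuli relevant to the current
#' boundary are presented.  See [switching_params()] for the agent model.
#'
#' @param params a [switching_params()] object.
#' @return A `trial_table` with `block_id` and `contingency` filled in;
#'   `correct` is judged against the current block's contingency.
#' @export
simulate_switching_session <- function(params) {
  if (!inherits(params, "switching_params")) params <- do.call(switching_params, params)
  withr::with_seed(substream_seed(params$seed, "behavior"), {
    n_blocks <- as.integer(params$n_blocks)
    lens <- sample(seq(params$block_length_range[1], params$block_length_range[2]),
                   n_blocks, replace = TRUE)
    other <- setdiff(c("low_boundary", "high_boundary"), params$initial_contingency)
    conts <- rep(c(params$initial_contingency, other), length.out = n_blocks)
    block_id <- rep(seq_len(n_blocks), times = lens)
    contingency <- rep(conts, times = lens)
    trial_in_block <- unlist(lapply(lens, seq_len), use.names = FALSE)
    n <- length(block_id)
    s <- params$stimuli
    frequency <- ifelse(contingency == "low_boundary",
                        ifelse(runif(n) < 0.5, s[1], s[2]),
                        ifelse(runif(n) < 0.5, s[2], s[3]))
    # agent: previous contingency during the learning window (block 1 exempt)
    learning <- block_id > 1 & trial_in_block <= params$learning_trials
    prev_cont <- ifelse(contingency == "low_boundary", "high_boundary", "low_boundary")
    used_cont <- ifelse(learning, prev_cont, contingency)
    choice <- rewarded_side(frequency, used_cont, s)
    flip <- runif(n) < params$error_rate
    choice[flip] <- ifelse(choice[flip] == "right", "left", "right")
    invalid <- runif(n) < params$invalid_rate
    choice[invalid] <- NA_character_
    correct <- choice == rewarded_side(frequency, contingency, s)
    tm <- draw_trial_times(n, params$delay_range, params$stim_duration,
                           params$iti_range, invalid)
    new_trial_table(data.frame(
      trial_id = seq_len(n),
      t_center_in = tm$t_center_in, t_sound_on = tm$t_sound_on,
      t_center_out = tm$t_center_out, t_side_in = tm$t_side_in,
      frequency = frequency, block_id = block_id, contingency = contingency,
      choice = choice, correct = correct, laser = FALSE, valid = !invalid,
      stringsAsFactors = FALSE))
  })
}

#' Construct a spike train object
#'
#' @param spike_times strictly increasing, non-negative spike times (s).
#' @param unit_id identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, unit_id = 1L, hemisphere = "right") {
  spike_times <- as.numeric(spike_times)
  if (any(spike_times < 0)) stopf("spike times must be non-negative")
  if (is.unsorted(spike_times, strictly = TRUE))
    stopf("spike times must be strictly increasing")
  structure(list(unit_id = unit_id, hemisphere = hemisphere,
                 spike_times = spike_times),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (%s hemisphere), %d spikes over %.1f s\n",
              x$unit_id, x$hemisphere, length(x$spike_times),
              if (length(x$spike_times)) max(x$spike_times) else 0))
  invisible(x)
}

# Greedy dead-time: drop any spike closer than `ref` to the last kept spike.
# Vectorized by removing, per pass, the first violator of each chain.
enforce_refractory <- function(tt, ref) {
  repeat {
    bad <- which(diff(tt) < ref) + 1L
    if (!length(bad)) return(tt)
    tt <- tt[-bad[c(TRUE, diff(bad) > 1L)]]
  }
}

# Trial side relative to a hemisphere: left-hemisphere units treat left
# choices as ipsilateral.
choice_is_ipsi <- function(choice, hemisphere) {
  !is.na(choice) & choice == hemisphere
}

#' Simulate a Poisson unit for a session
#'
#' Generates a spike train by thinning a homogeneous Poisson process at the
#' maximal programmed rate.  The rate is `baseline_rate` times the drift
#' multiplier, times the tuned evoked gain (and `choice_gain` on
#' ipsilateral-choice trials) inside each valid trial's sound window
#' `[t_sound_on, t_sound_on + 0.1)`, times the movement gain inside
#' `[t_center_out + 0.05, t_center_out + 0.15)`.  Spike counts in any fixed
#' window are therefore Poisson with mean rate x duration.
#'
#' @param trials a trial table.
#' @param params a [unit_params()] object.
#' @return A [spike_train()].
#' @export
simulate_unit <- function(trials, params) {
  assert_trial_table(trials)
  if (!inherits(params, "unit_params")) params <- do.call(unit_params, params)
  if (nrow(trials) == 0L) stopf("trial table is empty")
  v <- valid_trials(trials)
  tuned_gain <- 1 + (params$evoked_gain - 1) *
    exp(-log2(v$frequency / params$tuning_peak)^2 / (2 * params$tuning_width^2))
  ipsi <- choice_is_ipsi(v$choice, params$hemisphere)
  sound_gain <- tuned_gain * ifelse(ipsi, params$choice_gain, 1)
  move_gain <- ifelse(ipsi, params$movement_gain_ipsi, params$movement_gain_contra)
  win <- rbind(
    data.frame(start = v$t_sound_on, end = v$t_sound_on + 0.1, gain = sound_gain),
    data.frame(start = v$t_center_out + 0.05, end = v$t_center_out + 0.15,
               gain = move_gain))
  win <- win[order(win$start), , drop = FALSE]
  if (any(win$start[-1] < win$end[-nrow(win)] - 1e-12))
    stopf("modulation windows overlap; trial timing too tight for the rate model")
  t_end <- max(trials$t_side_in, trials$t_center_out, na.rm = TRUE) + 1
  drift_mult <- function(t) 1 + (params$drift_gain - 1) * (1 - exp(-t / params$drift_tau))
  rmax <- params$baseline_rate * max(1, drift_mult(t_end), drift_mult(0)) *
    max(1, win$gain)
  withr::with_seed(substream_seed(params$seed, paste0("unit", params$unit_id)), {
    if (rmax <= 0) {
      tt <- numeric(0)
    } else {
      n_cand <- rpois(1, rmax * t_end)
      tt <- sort(runif(n_cand, 0, t_end))
      idx <- findInterval(tt, win$start)
      in_win <- idx > 0L & tt < win$end[pmax(idx, 1L)]
      gain <- rep(1, length(tt))
      gain[in_win] <- win$gain[idx[in_win]]
      rate <- params$baseline_rate * drift_mult(tt) * gain
      tt <- unique(tt[runif(length(tt)) < rate / rmax])
      if (params$refractory > 0 && length(tt) > 1)
        tt <- enforce_refractory(tt, params$refractory)
    }
    spike_train(tt, unit_id = params$unit_id, hemisphere = params$hemisphere)
  })
}

#' Simulate marker-based head pose during optogenetic stimulation
#'
#' Two colored head markers rotate about a fixed midpoint.  Each stimulation
#' adds `rotation_per_stim` degrees over its 1.5 s interval following a
#' smooth raised-cosine profile; the angle holds between stimulations.
#' Observed marker positions carry small angular noise, and a fraction of
#' interior frames is dropped (both centroids missing) to emulate occluded
#' markers.
#'
#' @param stim_onsets stimulation onset times (s).
#' @param rotation_per_stim rotation per stimulation (degrees; positive =
#'   counter-clockwise / left).
#' @param frame_rate camera frame rate (Hz, default 30).
#' @param missing_fraction fraction of interior frames with missing centroids.
#' @param stim_duration stimulation duration (s, default 1.5).
#' @param noise_sd angular noise per frame (degrees, default 0.5).
#' @param marker_dist distance between the two markers (arbitrary units).
#' @param seed substream seed.
#' @return A data frame of class `head_pose` with columns `frame`, `t`,
#'   `x1`, `y1` (left marker), `x2`, `y2` (right marker), missing entries as
#'   `NA`; the noise-free angle series is attached as attribute
#'   `ground_truth` and the stimulation intervals as attribute `stims`.
#' @export
simulate_head_trajectory <- function(stim_onsets, rotation_per_stim,
                                     frame_rate = 30, missing_fraction = 0,
                                     stim_duration = 1.5, noise_sd = 0.5,
                                     marker_dist = 2, seed = 1L) {
  check_number(frame_rate, "frame_rate", lower = 1e-6)
  check_number(missing_fraction, "missing_fraction", lower = 0, upper = 0.9)
  stim_onsets <- sort(as.numeric(stim_onsets))
  t_end <- if (length(stim_onsets)) max(stim_onsets) + stim_duration + 1 else 2
  t <- seq(0, t_end, by = 1 / frame_rate)
  angle <- rep(0, length(t))
  for (on in stim_onsets) {
    tau <- pmin(pmax((t - on) / stim_duration, 0), 1)
    angle <- angle + rotation_per_stim * (1 - cos(pi * tau)) / 2
  }
  withr::with_seed(substream_seed(seed, "pose"), {
    obs <- angle + rnorm(length(t), sd = noise_sd)
    th <- obs * pi / 180
    d <- marker_dist / 2
    df <- data.frame(frame = seq_along(t), t = t,
                     x1 = d * cos(th), y1 = d * sin(th),
                     x2 = -d * cos(th), y2 = -d * sin(th))
    if (missing_fraction > 0 && length(t) > 2) {
      interior <- 2:(length(t) - 1)
      drop <- sample(interior, round(missing_fraction * length(interior)))
      df[drop, c("x1", "y1", "x2", "y2")] <- NA_real_
    }
    attr(df, "ground_truth") <- angle
    attr(df, "stims") <- data.frame(onset = stim_onsets,
                                    offset = stim_onsets + stim_duration)
    class(df) <- c("head_pose", "data.frame")
    df
  })
}
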