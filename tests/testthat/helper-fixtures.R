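# Shared fixture builders: everything is generated in code at test time.

# A minimal hand-built trial table with fully controlled fields.
make_trials <- function(frequency, choice,
                        correct = NULL, boundary = 12,
                        laser = FALSE, valid = TRUE,
                        contingency = "fixed", block_id = 1L,
                        iti = 2) {
  n <- length(frequency)
  choice <- rep_len(choice, n)
  laser <- rep_len(laser, n)
  valid <- rep_len(valid, n)
  contingency <- rep_len(contingency, n)
  block_id <- rep_len(block_id, n)
  if (is.null(correct)) correct <- (choice == "right") == (frequency > boundary)
  t_center_in <- 0.5 + (seq_len(n) - 1) * iti
  t_sound_on <- t_center_in + 0.2
  t_center_out <- t_sound_on + 0.15
  t_side_in <- t_center_out + 0.3
  structure(data.frame(
    trial_id = seq_len(n), t_center_in = t_center_in, t_sound_on = t_sound_on,
    t_center_out = t_center_out, t_side_in = t_side_in,
    frequency = frequency, block_id = block_id, contingency = contingency,
    choice = choice, correct = correct, laser = laser, valid = valid,
    stringsAsFactors = FALSE),
    class = c("trial_table", "data.frame"))
}

# Spike train at exact, hand-placed times.
make_spikes <- function(times, hemisphere = "right") {
  spike_train(sort(times), unit_id = "t", hemisphere = hemisphere)
}

# Homogeneous Poisson train (no refractory) for analytic oracles.
poisson_train <- function(rate, t_end, seed = 1) {
  withr::with_seed(seed, {
    n <- rpois(1, rate * t_end)
    spike_train(sort(runif(n, 0, t_end)))
  })
}

# Brute-force window count oracle: O(n * m) scan over spikes and events.
brute_counts <- function(spikes, events, window) {
  vapply(events, function(ev)
    sum(spikes$spike_times >= ev + window[1] &
          spikes$spike_times < ev + window[2]), numeric(1))
}
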