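# Event alignment, windowed counting, unit quality, sound-response stats ----
#
# All event windows are half-open [a, b) in seconds relative to the event,
# which prevents double counting at shared boundaries.

#' Align a spike train to events
#'
#' Re-references spikes to each event, keeping relative times in the
#' half-open interval `[range[1], range[2])`.
#'
#' @param spikes a [spike_train()].
#' @param events sorted event times (s).
#' @param range relative time range (s), e.g. `c(-0.2, 0.4)`.
#' @param event_name label carried in the result.
#' @return An object of class `aligned_raster`: list with `event_name`,
#'   `range`, `trials` (one numeric vector of relative spike times per
#'   event), `n_trials`.
#' @export
align_spikes <- function(spikes, events, range, event_name = "event") {
  if (!inherits(spikes, "spike_train")) stopf("`spikes` must be a spike_train")
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2])
    stopf("parameter `range` must be a finite interval (low < high)")
  events <- as.numeric(events)
  if (is.unsorted(events)) stopf("`events` must be sorted")
  st <- spikes$spike_times
  trials <- lapply(events, function(ev) {
    lo <- findInterval(ev + range[1], st, left.open = TRUE)   # spikes < a
    hi <- findInterval(ev + range[2], st, left.open = TRUE)   # spikes < b
    if (hi > lo) st[(lo + 1):hi] - ev else numeric(0)
  })
  structure(list(event_name = event_name, range = range, trials = trials,
                 n_trials = length(events)),
            class = "aligned_raster")
}

#' @export
print.aligned_raster <- function(x, ...) {
  cat(sprintf("<aligned_raster> %d trials around '%s', window [%g, %g) s, %d spikes\n",
              x$n_trials, x$event_name, x$range[1], x$range[2],
              sum(lengths(x$trials))))
  invisible(x)
}

#' Per-trial spike counts in a window
#'
#' @param raster an [align_spikes()] result.
#' @param window half-open interval (s) contained in the raster range.
#' @return Integer counts, one per trial.
#' @export
count_in_window <- function(raster, window) {
  if (!inherits(raster, "aligned_raster")) stopf("`raster` must be an aligned_raster")
  if (length(window) != 2 || window[1] >= window[2])
    stopf("parameter `window` must be an interval (low < high)")
  if (window[1] < raster$range[1] - 1e-12 || window[2] > raster$range[2] + 1e-12)
    stopf("window [%g, %g) outside raster range [%g, %g)",
          window[1], window[2], raster$range[1], raster$range[2])
  vapply(raster$trials, function(t) sum(t >= window[1] & t < window[2]), integer(1))
}

# Convenience: per-trial counts of `spikes` in [window) around `events`.
window_counts <- function(spikes, events, window) {
  count_in_window(align_spikes(spikes, events, window), window)
}

#' Inter-spike-interval quality filter
#'
#' A sorted unit is retained when fewer than `max_fraction` of its
#' inter-spike intervals are shorter than `threshold` (refractory-period
#' violations indicating contamination).
#'
#' @param spikes a [spike_train()].
#' @param threshold ISI threshold in seconds (default 0.002).
#' @param max_fraction maximal tolerated violation fraction (default 0.02).
#' @return A list of class `isi_quality`: `fraction`, `pass`, `n_isi`.  With
#'   fewer than 2 spikes the fraction is undefined and the unit passes with
#'   a warning (no evidence of contamination).
#' @export
isi_quality <- function(spikes, threshold = 0.002, max_fraction = 0.02) {
  if (!inherits(spikes, "spike_train")) stopf("`spikes` must be a spike_train")
  isi <- diff(spikes$spike_times)
  if (length(isi) == 0L) {
    warning("fewer than 2 spikes: ISI fraction undefined, passing unit")
    return(structure(list(fraction = NA_real_, pass = TRUE, n_isi = 0L),
                     class = "isi_quality"))
  }
  frac <- mean(isi < threshold)
  structure(list(fraction = frac, pass = frac < max_fraction,
                 n_isi = length(isi)),
            class = "isi_quality")
}

#' Sound response index
#'
#' `(S - B) / (S + B)` where `S` and `B` are the across-trial mean counts in
#' the equal-duration evoked and baseline windows.  Positive values indicate
#' enhancement relative to spontaneous activity, negative values
#' suppression.  Significance from a two-sided rank-sum test on the
#' per-trial counts.
#'
#' @param evoked_counts,baseline_counts per-trial counts from equal-duration
#'   windows, one entry per trial (same trials, same order).
#' @param alpha significance level.
#' @return A [modulation_result()].
#' @export
sound_response_index <- function(evoked_counts, baseline_counts, alpha = 0.05) {
  if (length(evoked_counts) != length(baseline_counts))
    stopf("evoked and baseline counts must come from the same trials")
  if (length(evoked_counts) == 0L) stopf("no trials")
  index_from_counts(evoked_counts, baseline_counts,
                    kind = "sound_response", alpha = alpha)
}

#' Kruskal-Wallis test for frequency selectivity
#'
#' Tests whether evoked counts differ across stimulus frequencies
#' (tie-corrected H statistic against the chi-squared reference).
#'
#' @param counts per-trial evoked counts.
#' @param group stimulus frequency (or any grouping label) per trial.
#' @return A list: `statistic` (H), `df`, `p_value` (1 when every
#'   observation is identical).
#' @export
frequency_selectivity_test <- function(counts, group) {
  if (length(counts) != length(group)) stopf("counts and group lengths differ")
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) == 0))
    stopf("frequency_selectivity_test needs >= 2 non-empty groups")
  if (length(unique(counts)) == 1L)
    return(list(statistic = 0, df = nlevels(group) - 1L, p_value = 1))
  kt <- kruskal.test(counts, group)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' High- versus low-frequency selectivity index
#'
#' `(F_high - F_low) / (F_high + F_low)` comparing mean evoked counts for
#' stimuli above vs. below the categorization boundary, with a two-sided
#' rank-sum test between the two classes.
#'
#' @param counts per-trial evoked counts.
#' @param frequencies stimulus frequency per trial (kHz).
#' @param boundary categorization boundary (kHz).
#' @param alpha significance level.
#' @return A [modulation_result()] (positive = stronger response to
#'   high-frequency stimuli).
#' @export
highlow_selectivity_index <- function(counts, frequencies, boundary,
                                      alpha = 0.05) {
  if (length(counts) != length(frequencies))
    stopf("counts and frequencies lengths differ")
  high <- frequencies > boundary
  if (!any(high) || all(high))
    stopf("both sides of the boundary must be represented")
  index_from_counts(counts[high], counts[!high],
                    kind = "highlow_selectivity", alpha = alpha)
}
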