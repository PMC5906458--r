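# Movement-direction and choice modulation -----------------------------------

#' Movement-direction modulation index
#'
#' `(I - C) / (I + C)` where `I` and `C` are the mean counts in the 50-150 ms
#' post-exit window for choices ipsilateral and contralateral to the
#' recording hemisphere.  Positive values mean stronger ipsilateral firing.
#'
#' @param counts_ipsi,counts_contra per-trial counts for the two movement
#'   directions.
#' @param alpha significance level.
#' @return A [modulation_result()].
#' @export
movement_modulation_index <- function(counts_ipsi, counts_contra, alpha = 0.05) {
  if (length(counts_ipsi) == 0L || length(counts_contra) == 0L)
    stopf("both movement directions must be represented")
  index_from_counts(counts_ipsi, counts_contra, kind = "movement", alpha = alpha)
}

#' Binned z-score responsiveness criterion
#'
#' Spike counts are taken in non-overlapping 25 ms bins.  Each of the four
#' response bins covering 0-100 ms after sound onset is compared with the
#' single baseline bin 25-50 ms before onset by a Wilcoxon rank-sum test,
#' summarized as the tie-corrected standardized rank-sum statistic (z).  The
#' unit is responsive when any response-bin z falls outside
#' `(-z_threshold, z_threshold)`.  No correction across the four bins is
#' applied; the induced family-wise rate is a property of the criterion.
#'
#' @param raster an [align_spikes()] raster around sound onset covering at
#'   least `[-0.05, 0.1)` s.
#' @param bin_width bin width in seconds (default 0.025).
#' @param response_window response period (default `c(0, 0.1)`).
#' @param baseline_bin baseline bin (default `c(-0.05, -0.025)`).
#' @param z_threshold responsiveness threshold (default 3).
#' @return A data frame of class `zscore_profile` (`bin_start`, `bin_end`,
#'   `z`), with attributes `responsive` (logical) and `z_threshold`.
#' @export
zscore_responsiveness <- function(raster, bin_width = 0.025,
                                  response_window = c(0, 0.1),
                                  baseline_bin = c(-0.05, -0.025),
                                  z_threshold = 3) {
  if (!inherits(raster, "aligned_raster")) stopf("`raster` must be an aligned_raster")
  if (raster$n_trials == 0L) stopf("raster has zero trials")
  base <- count_in_window(raster, baseline_bin)
  starts <- seq(response_window[1], response_window[2] - bin_width / 2, by = bin_width)
  prof <- do.call(rbind, lapply(starts, function(s) {
    z <- ranksum_z(count_in_window(raster, c(s, s + bin_width)), base)
    data.frame(bin_start = s, bin_end = s + bin_width, z = z)
  }))
  attr(prof, "responsive") <- any(abs(prof$z) >= z_threshold)
  attr(prof, "z_threshold") <- z_threshold
  class(prof) <- c("zscore_profile", "data.frame")
  prof
}

#' Is a z-score profile responsive?
#'
#' @param profile a [zscore_responsiveness()] result.
#' @return Logical flag.
#' @export
is_responsive <- function(profile) {
  isTRUE(attr(profile, "responsive"))
}

#' Choice modulation of sound-evoked activity
#'
#' `(I - C)/(I + C)` on sound-window counts split by the upcoming choice
#' (ipsilateral vs. contralateral to the recording hemisphere), for the
#' analysis stimulus near the categorization boundary.  Intended for units
#' that pass [zscore_responsiveness()] for that stimulus.
#'
#' @param counts_ipsi,counts_contra per-trial sound-window counts by choice.
#' @param alpha significance level.
#' @return A [modulation_result()].
#' @export
choice_modulation <- function(counts_ipsi, counts_contra, alpha = 0.05) {
  if (length(counts_ipsi) == 0L || length(counts_contra) == 0L)
    stopf("both choices must be represented")
  index_from_counts(counts_ipsi, counts_contra, kind = "choice", alpha = alpha)
}

#' Choice-related activity before leaving the center port
#'
#' Same contract as [choice_modulation()], applied to counts from the 100 ms
#' window ending at center-port exit, restricted to boundary-stimulus trials.
#'
#' @inheritParams choice_modulation
#' @return A [modulation_result()].
#' @export
pre_exit_choice_activity <- function(counts_ipsi, counts_contra, alpha = 0.05) {
  if (length(counts_ipsi) == 0L || length(counts_contra) == 0L)
    stopf("both choices must be represented")
  index_from_counts(counts_ipsi, counts_contra, kind = "pre_exit_choice",
                    alpha = alpha)
}

#' Select the analysis stimulus near the boundary
#'
#' Of the two frequencies nearest the categorization boundary (log distance),
#' returns the one eliciting the largest absolute sound response index; ties
#' are broken toward the lower frequency.
#'
#' @param spikes a [spike_train()].
#' @param trials a trial table.
#' @param boundary categorization boundary (kHz).
#' @param sound_window,baseline_window windows (s) relative to sound onset.
#' @return The selected frequency (kHz).
#' @export
select_analysis_stimulus <- function(spikes, trials, boundary,
                                     sound_window = c(0, 0.1),
                                     baseline_window = c(-0.1, 0)) {
  v <- valid_trials(trials)
  freqs <- sort(unique(v$frequency))
  if (length(freqs) < 2) stopf("need >= 2 distinct frequencies")
  near <- freqs[order(abs(log(freqs) - log(boundary)))][1:2]
  near <- sort(near)
  idx <- vapply(near, function(f) {
    ev <- v$t_sound_on[v$frequency == f]
    r <- sound_response_index(window_counts(spikes, ev, sound_window),
                              window_counts(spikes, ev, baseline_window))
    if (is.na(r$index)) 0 else abs(r$index)
  }, numeric(1))
  # strict '>' keeps the lower frequency on ties
  if (idx[2] > idx[1]) near[2] else near[1]
}

#' Population summary of modulation results
#'
#' Aggregates a list of [modulation_result()]s: counts of defined and
#' significant indices, a one-sample Wilcoxon signed-rank test of the
#' defined indices against zero, and (optionally) a Spearman rank
#' correlation with a second, paired set of results.
#'
#' @param results list of [modulation_result()]s.
#' @param paired_with optional second list, same length and unit order, for
#'   the Spearman correlation between index vectors.
#' @return A list of class `population_summary`: `n_total`, `n_defined`,
#'   `n_significant`, `fraction_significant`, `percent_significant`,
#'   `median_index`, `signed_rank_p`, and (when paired) `spearman_r`,
#'   `spearman_p`, `n_pairs`.
#' @export
population_summary <- function(results, paired_with = NULL) {
  idx <- vapply(results, function(r) r$index, numeric(1))
  sig <- vapply(results, function(r) r$significant, logical(1))
  defined <- !is.na(idx)
  if (!any(defined)) stopf("no defined indices in `results`")
  out <- list(
    n_total = length(results),
    n_defined = sum(defined),
    n_significant = sum(sig[defined]),
    fraction_significant = sum(sig[defined]) / sum(defined),
    percent_significant = fraction_percent(sum(sig[defined]), sum(defined)),
    median_index = median(idx[defined]),
    signed_rank_p = signedrank_p(idx[defined]))
  if (!is.null(paired_with)) {
    idx2 <- vapply(paired_with, function(r) r$index, numeric(1))
    keep <- defined & !is.na(idx2)
    if (sum(keep) < 3) stopf("too few paired defined indices for correlation")
    ct <- suppressWarnings(cor.test(idx[keep], idx2[keep], method = "spearman"))
    out$spearman_r <- unname(ct$estimate)
    out$spearman_p <- ct$p.value
    out$n_pairs <- sum(keep)
  }
  structure(out, class = "population_summary")
}

#' Fisher's exact test for two detection fractions
#'
#' Utility for comparing two counts of significant units out of their
#' denominators (e.g. choice- vs. sound-selective fractions under matched
#' trial counts).
#'
#' @param k1,n1 significant count and denominator of the first fraction.
#' @param k2,n2 same for the second.
#' @return A list: `p_value`, `odds_ratio`.
#' @export
fisher_fraction_test <- function(k1, n1, k2, n2) {
  ft <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
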