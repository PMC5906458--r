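# Contingency-switching analysis ---------------------------------------------

#' Parse contingency blocks
#'
#' Maximal runs of constant contingency partition the session into blocks.
#'
#' @param trials a trial table with a `contingency` column.
#' @return A data frame of class `block_structure`: `block_id`,
#'   `first_trial`, `last_trial`, `contingency`, `n_valid`, `accuracy`
#'   (over valid trials of the block).
#' @export
parse_blocks <- function(trials) {
  assert_trial_table(trials)
  if (any(is.na(trials$contingency)))
    stopf("`contingency` column contains missing values")
  if (nrow(trials) == 0L) stopf("trial table is empty")
  run <- cumsum(c(TRUE, trials$contingency[-1] != trials$contingency[-nrow(trials)]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(trials)), run), function(i) {
    b <- trials[i, ]
    v <- b[b$valid, ]
    data.frame(block_id = b$block_id[1],
               first_trial = b$trial_id[1], last_trial = b$trial_id[nrow(b)],
               contingency = b$contingency[1], n_valid = nrow(v),
               accuracy = if (nrow(v)) mean(v$correct) else NA_real_)
  }))
  rownames(out) <- NULL
  class(out) <- c("block_structure", "data.frame")
  out
}

#' The switching (shared) stimulus
#'
#' The frequency presented under both contingencies — the stimulus whose
#' rewarded action moves with the boundary.
#'
#' @param trials a switching-session trial table.
#' @return The shared frequency (kHz).
#' @export
switching_stimulus <- function(trials) {
  assert_trial_table(trials)
  by_cont <- split(trials$frequency, trials$contingency)
  if (length(by_cont) < 2) stopf("session has a single contingency")
  shared <- Reduce(intersect, lapply(by_cont, unique))
  if (length(shared) != 1)
    stopf("expected exactly one stimulus shared across contingencies, found %d",
          length(shared))
  shared
}

#' Stable-performance trial filter for switching sessions
#'
#' Sessions below `min_accuracy` (fraction correct over valid trials) are
#' rejected outright.  Within retained sessions, the first
#' `exclude_after_switch` trials of every post-switch block (counting all
#' trials after the switch, valid or not) are dropped, as are invalid and —
#' by default — incorrect trials.  A `trial_in_block` column records each
#' trial's original position within its block, which makes the filter
#' idempotent.
#'
#' @param trials a switching-session trial table.
#' @param min_accuracy session inclusion threshold (default 0.6).
#' @param exclude_after_switch trials dropped after each switch (default 20).
#' @param correct_only drop incorrect trials (default TRUE).
#' @return The filtered trial table; attribute `session_rejected` is TRUE
#'   (and the table empty) when the session fails the accuracy criterion.
#' @export
switching_trial_filter <- function(trials, min_accuracy = 0.6,
                                   exclude_after_switch = 20,
                                   correct_only = TRUE) {
  assert_trial_table(trials)
  v_acc <- mean(trials$correct[trials$valid])
  if (is.na(v_acc) || v_acc < min_accuracy) {
    out <- trials[0, ]
    attr(out, "session_rejected") <- TRUE
    return(out)
  }
  if (!"trial_in_block" %in% names(trials)) {
    blocks <- parse_blocks(trials)
    first_of <- blocks$first_trial[match(trials$block_id, blocks$block_id)]
    trials$trial_in_block <- trials$trial_id - first_of + 1L
    post_switch <- trials$block_id != blocks$block_id[1]
  } else {
    post_switch <- trials$block_id != min(trials$block_id)
  }
  keep <- trials$valid &
    !(post_switch & trials$trial_in_block <= exclude_after_switch)
  if (correct_only) keep <- keep & trials$correct
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "session_rejected") <- FALSE
  out
}

#' Contingency modulation with the multi-switch consistency rule
#'
#' The overall index `(I - C)/(I + C)` compares mean sound-window counts on
#' switching-stimulus trials between the contingency in which the correct
#' choice is ipsilateral to the recording hemisphere (`I`) and the other
#' contingency (`C`), with a two-sided rank-sum p-value.  To exclude slow
#' nonstationary drift, each switch between adjacent blocks is also tested:
#' a switch shows the effect when the rank-sum between the two blocks has
#' p < `alpha` and the ipsi-minus-contra difference has the same sign as the
#' overall index.  The unit counts as contingency-modulated only when the
#' overall test is significant and at least `min_switches` switches show the
#' effect.
#'
#' @param counts per-trial counts (filtered switching-stimulus trials).
#' @param contingency,block_id per-trial labels matching `counts`.
#' @param hemisphere recording hemisphere; for a right-hemisphere unit the
#'   ipsilateral contingency is the low-boundary block (mid stimulus rewarded
#'   right).
#' @param alpha significance level.
#' @param min_switches switches required to confirm the effect (default 2).
#' @param kind result label.
#' @return A list of class `switching_modulation`: `overall` (a
#'   [modulation_result()]), `switches` (per-switch data frame with blocks,
#'   p, direction agreement, flag), `n_switch_effects`, `modulated`.
#' @export
switching_modulation <- function(counts, contingency, block_id,
                                 hemisphere = "right", alpha = 0.05,
                                 min_switches = 2, kind = "switching") {
  if (length(counts) != length(contingency) || length(counts) != length(block_id))
    stopf("counts, contingency and block_id must have equal length")
  blocks <- sort(unique(block_id))
  if (length(blocks) < 2)
    stopf("switching_modulation needs >= 2 blocks")
  ipsi_cont <- if (hemisphere == "right") "low_boundary" else "high_boundary"
  ipsi <- contingency == ipsi_cont
  if (!any(ipsi) || all(ipsi)) stopf("both contingencies must be represented")
  overall <- index_from_counts(counts[ipsi], counts[!ipsi],
                               kind = kind, alpha = alpha)
  switches <- do.call(rbind, lapply(seq_along(blocks)[-1], function(j) {
    a <- block_id == blocks[j - 1]; b <- block_id == blocks[j]
    ia <- ipsi[a][1]
    ci <- if (ia) counts[a] else counts[b]
    cc <- if (ia) counts[b] else counts[a]
    p <- ranksum_p(ci, cc)
    di <- mean(ci) - mean(cc)
    same_dir <- !is.na(overall$index) && overall$index != 0 && di != 0 &&
      sign(di) == sign(overall$index)
    data.frame(switch = j - 1L, block_before = blocks[j - 1],
               block_after = blocks[j], p_value = p,
               same_direction = same_dir,
               effect = !is.na(p) && p < alpha && same_dir)
  }))
  n_eff <- sum(switches$effect)
  structure(list(overall = overall, switches = switches,
                 n_switch_effects = n_eff,
                 modulated = overall$significant && n_eff >= min_switches),
            class = "switching_modulation")
}

#' @export
print.switching_modulation <- function(x, ...) {
  print(x$overall)
  cat(sprintf("  switch effects: %d/%d; contingency-modulated: %s\n",
              x$n_switch_effects, nrow(x$switches), x$modulated))
  invisible(x)
}

#' Pre-exit activity across contingencies
#'
#' [switching_modulation()] applied to counts from the 100 ms window before
#' center-port exit on switching-stimulus trials, with the same filters and
#' multi-switch rule.
#'
#' @inheritParams switching_modulation
#' @return A `switching_modulation` object.
#' @export
pre_exit_switching_activity <- function(counts, contingency, block_id,
                                        hemisphere = "right", alpha = 0.05,
                                        min_switches = 2) {
  switching_modulation(counts, contingency, block_id, hemisphere = hemisphere,
                       alpha = alpha, min_switches = min_switches,
                       kind = "pre_exit_switching")
}
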