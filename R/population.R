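# Synthetic populations with programmed response-class fractions -------------

#' Simulate a recorded population with known class labels
#'
#' Builds one or more discrimination sessions and a population of units with
#' programmed class memberships: a `frac_responsive` subset carries a sound
#' response (a share of them suppressed rather than enhanced), a
#' `frac_movement` subset carries a movement-direction gain (random
#' preferred direction), and a `frac_choice` subset — drawn from within the
#' responsive class, since choice effects are measured on sound-evoked
#' activity — carries a choice gain.  Class labels are returned so detection
#' rates can be scored against ground truth.
#'
#' @param n_units number of units.
#' @param n_sessions number of sessions the units are spread across.
#' @param n_trials trials per session.
#' @param frac_responsive,frac_movement,frac_choice programmed class
#'   fractions of all units (choice units are a subset of responsive ones,
#'   so `frac_choice <= frac_responsive` is required).
#' @param frac_suppressed share of responsive units that are suppressed.
#' @param baseline_range uniform range of baseline rates (Hz).
#' @param evoked_gain,suppressed_gain,movement_gain,choice_gain effect sizes
#'   given to members of each class.
#' @param seed master seed.
#' @return A list: `bundles` (one per session, each with `trials`, `units`,
#'   `meta`), `truth` (data frame: session, unit_id, responsive, movement,
#'   choice labels).
#' @export
simulate_population <- function(n_units = 520, n_sessions = 5, n_trials = 600,
                                frac_responsive = 0.45, frac_movement = 0.38,
                                frac_choice = 0.12, frac_suppressed = 0.25,
                                baseline_range = c(8, 16),
                                evoked_gain = 2.5, suppressed_gain = 0.35,
                                movement_gain = 2, choice_gain = 2,
                                seed = 1L) {
  if (frac_choice > frac_responsive)
    stopf("frac_choice must not exceed frac_responsive (choice effects ride on evoked activity)")
  n_resp <- round(frac_responsive * n_units)
  n_move <- round(frac_movement * n_units)
  n_choice <- round(frac_choice * n_units)
  labels <- withr::with_seed(substream_seed(seed, "classes"), {
    responsive <- logical(n_units); responsive[sample.int(n_units, n_resp)] <- TRUE
    movement <- logical(n_units); movement[sample.int(n_units, n_move)] <- TRUE
    choice <- logical(n_units)
    choice[sample(which(responsive), n_choice)] <- TRUE
    suppressed <- logical(n_units)
    suppressed[sample(which(responsive), round(frac_suppressed * n_resp))] <- TRUE
    data.frame(unit = seq_len(n_units), responsive = responsive,
               movement = movement, choice = choice, suppressed = suppressed,
               baseline = runif(n_units, baseline_range[1], baseline_range[2]),
               move_pref_ipsi = runif(n_units) < 0.5,
               hemisphere = ifelse(runif(n_units) < 0.5, "left", "right"))
  })
  session_of <- rep(seq_len(n_sessions), length.out = n_units)
  bundles <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    p <- session_params(n_trials = n_trials,
                        seed = substream_seed(seed, paste0("session", s)))
    tr <- simulate_discrimination_session(p)
    ids <- which(session_of == s)
    units <- lapply(ids, function(i) {
      li <- labels[i, ]
      simulate_unit(tr, unit_params(
        baseline_rate = li$baseline,
        evoked_gain = if (!li$responsive) 1
                      else if (li$suppressed) suppressed_gain else evoked_gain,
        tuning_width = 3,               # broad: drives all task frequencies
        movement_gain_ipsi = if (li$movement && li$move_pref_ipsi) movement_gain else 1,
        movement_gain_contra = if (li$movement && !li$move_pref_ipsi) movement_gain else 1,
        choice_gain = if (li$choice) choice_gain else 1,
        hemisphere = li$hemisphere,
        unit_id = i,
        seed = substream_seed(seed, paste0("unit", i))))
    })
    bundles[[s]] <- list(trials = tr, units = units,
                         meta = list(boundary = p$boundary))
  }
  truth <- data.frame(session = session_of, unit_id = labels$unit,
                      responsive = labels$responsive,
                      movement = labels$movement, choice = labels$choice,
                      suppressed = labels$suppressed)
  list(bundles = bundles, truth = truth)
}
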