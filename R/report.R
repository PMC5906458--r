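# Population-level orchestration and reporting -------------------------------

#' Percentage of a count pair, rounded half-up to one decimal
#'
#' Fractions are stored as exact integer pairs; percentages are display
#' only.  Rounding is half-up at one decimal, computed in integer
#' arithmetic so no floating-point representation issue can flip a digit.
#'
#' @param k numerator count(s), `0 <= k <= n`.
#' @param n denominator count(s), `> 0`.
#' @return `100 * k / n` rounded half-up to one decimal.
#' @export
fraction_percent <- function(k, n) {
  if (length(k) != length(n) && length(k) != 1 && length(n) != 1)
    stopf("k and n lengths are incompatible")
  if (any(n <= 0)) stopf("denominator must be positive")
  if (any(k < 0) || any(k > n)) stopf("need 0 <= k <= n")
  if (any(k != floor(k)) || any(n != floor(n))) stopf("counts must be integers")
  floor((2000 * k + n) / (2 * n)) / 10
}

format_fraction <- function(k, n) {
  sprintf("%.1f%% (%d/%d)", fraction_percent(k, n), as.integer(k), as.integer(n))
}

#' Pipeline configuration
#'
#' Analysis windows are in seconds and half-open; windows named `*_window`
#' relative to sound onset or center-port exit as noted.
#'
#' @param sound_window evoked window relative to sound onset (default 0-100 ms).
#' @param baseline_window spontaneous window relative to sound onset
#'   (default -100-0 ms).
#' @param movement_window window relative to center-port exit (default
#'   50-150 ms).
#' @param pre_exit_window window relative to center-port exit (default
#'   -100-0 ms).
#' @param bin_width,z_threshold binned responsiveness criterion settings
#'   (default 25 ms bins, |z| >= 3).
#' @param alpha significance level for all unit-level tests.
#' @param switch_exclude trials dropped after each contingency switch.
#' @param min_session_accuracy switching-session inclusion threshold.
#' @param min_switches switches required by the contingency-modulation rule.
#' @param lapse_bounds psychometric lapse constraint.
#' @param boundary default categorization boundary (kHz) when a bundle does
#'   not carry one in its manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sound_window = c(0, 0.1),
                            baseline_window = c(-0.1, 0),
                            movement_window = c(0.05, 0.15),
                            pre_exit_window = c(-0.1, 0),
                            bin_width = 0.025,
                            z_threshold = 3,
                            alpha = 0.05,
                            switch_exclude = 20,
                            min_session_accuracy = 0.6,
                            min_switches = 2,
                            lapse_bounds = c(0, 0.3),
                            boundary = 12) {
  for (w in list(sound_window, baseline_window, movement_window, pre_exit_window))
    if (length(w) != 2 || w[1] >= w[2]) stopf("analysis windows must be ordered")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(z_threshold, "z_threshold", lower = 0)
  structure(as.list(environment())[setdiff(ls(), "w")], class = "pipeline_config")
}

# Analyze one unit of a fixed-boundary discrimination session.
analyze_discrimination_unit <- function(u, trials, boundary, cfg) {
  v <- valid_trials(trials)
  res <- list(unit_id = u$unit_id, hemisphere = u$hemisphere)
  q <- isi_quality(u)
  res$isi_fraction <- q$fraction
  res$included <- q$pass
  if (!q$pass) return(res)

  evoked <- window_counts(u, v$t_sound_on, cfg$sound_window)
  base <- window_counts(u, v$t_sound_on, cfg$baseline_window)
  sr <- sound_response_index(evoked, base, alpha = cfg$alpha)
  res$sound_index <- sr$index; res$sound_p <- sr$p_value
  res$sound_responsive <- sr$significant

  res$kw_p <- frequency_selectivity_test(evoked, v$frequency)$p_value
  res$frequency_selective <- res$sound_responsive & res$kw_p < cfg$alpha

  hl <- highlow_selectivity_index(evoked, v$frequency, boundary, alpha = cfg$alpha)
  res$highlow_index <- hl$index; res$highlow_p <- hl$p_value
  res$highlow_selective <- hl$significant

  chosen <- !is.na(v$choice)
  ipsi <- choice_is_ipsi(v$choice, u$hemisphere)
  mv_counts <- window_counts(u, v$t_center_out, cfg$movement_window)
  mm <- movement_modulation_index(mv_counts[chosen & ipsi],
                                  mv_counts[chosen & !ipsi], alpha = cfg$alpha)
  res$movement_index <- mm$index; res$movement_p <- mm$p_value
  res$movement_selective <- mm$significant

  fa <- select_analysis_stimulus(u, trials, boundary,
                                 sound_window = cfg$sound_window,
                                 baseline_window = cfg$baseline_window)
  res$analysis_stimulus <- fa
  bt <- v[v$frequency == fa & !is.na(v$choice), ]
  ras <- align_spikes(u, bt$t_sound_on, c(-0.05, cfg$sound_window[2]))
  zp <- zscore_responsiveness(ras, bin_width = cfg$bin_width,
                              response_window = cfg$sound_window,
                              z_threshold = cfg$z_threshold)
  res$z_responsive <- is_responsive(zp)
  b_ipsi <- choice_is_ipsi(bt$choice, u$hemisphere)
  if (res$z_responsive && any(b_ipsi) && !all(b_ipsi)) {
    sc <- window_counts(u, bt$t_sound_on, cfg$sound_window)
    cm <- choice_modulation(sc[b_ipsi], sc[!b_ipsi], alpha = cfg$alpha)
    res$choice_tested <- TRUE
    res$choice_index <- cm$index; res$choice_p <- cm$p_value
    res$choice_modulated <- cm$significant
  } else {
    res$choice_tested <- FALSE
  }
  if (any(b_ipsi) && !all(b_ipsi)) {
    pc <- window_counts(u, bt$t_center_out, cfg$pre_exit_window)
    pe <- pre_exit_choice_activity(pc[b_ipsi], pc[!b_ipsi], alpha = cfg$alpha)
    res$pre_exit_index <- pe$index; res$pre_exit_p <- pe$p_value
    res$pre_exit_modulated <- pe$significant
  }
  res
}

# Analyze one unit of a switching session (trials must already have passed
# the session accuracy criterion; `filtered` is the stable-performance set).
analyze_switching_unit <- function(u, trials, filtered, cfg) {
  res <- list(unit_id = u$unit_id, hemisphere = u$hemisphere)
  q <- isi_quality(u)
  res$isi_fraction <- q$fraction
  res$included <- q$pass
  if (!q$pass) return(res)
  mid <- switching_stimulus(trials)
  res$analysis_stimulus <- mid
  v <- valid_trials(trials)
  mt_all <- v[v$frequency == mid, ]
  ras <- align_spikes(u, mt_all$t_sound_on, c(-0.05, cfg$sound_window[2]))
  zp <- zscore_responsiveness(ras, bin_width = cfg$bin_width,
                              response_window = cfg$sound_window,
                              z_threshold = cfg$z_threshold)
  res$z_responsive <- is_responsive(zp)
  mt <- filtered[filtered$frequency == mid, ]
  if (length(unique(mt$block_id)) < 2) return(res)
  sc <- window_counts(u, mt$t_sound_on, cfg$sound_window)
  if (res$z_responsive) {
    sw <- switching_modulation(sc, mt$contingency, mt$block_id,
                               hemisphere = u$hemisphere, alpha = cfg$alpha,
                               min_switches = cfg$min_switches)
    res$switching_tested <- TRUE
    res$switching_index <- sw$overall$index
    res$switching_p <- sw$overall$p_value
    res$n_switch_effects <- sw$n_switch_effects
    res$switching_modulated <- sw$modulated
  } else {
    res$switching_tested <- FALSE
  }
  pc <- window_counts(u, mt$t_center_out, cfg$pre_exit_window)
  pe <- pre_exit_switching_activity(pc, mt$contingency, mt$block_id,
                                    hemisphere = u$hemisphere, alpha = cfg$alpha,
                                    min_switches = cfg$min_switches)
  res$pre_exit_index <- pe$overall$index
  res$pre_exit_p <- pe$overall$p_value
  res$pre_exit_modulated <- pe$modulated
  res
}

unit_rows <- function(res_list, cols) {
  do.call(rbind, lapply(res_list, function(r) {
    row <- lapply(cols, function(cn) if (is.null(r[[cn]])) NA else r[[cn]])
    names(row) <- cols
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
}

pop_entry <- function(k, n) list(k = as.integer(k), n = as.integer(n),
                                 percent = if (n > 0) fraction_percent(k, n) else NA_real_)

#' Run the full analysis pipeline over session bundles
#'
#' Applies the unit-quality filter, the sound-response / frequency
#' selectivity / movement / choice analyses (fixed-boundary sessions) or the
#' contingency-switching analysis (switching sessions) to every unit of
#' every bundle, and aggregates population fractions.  Every percentage is
#' reported together with its exact `(k, n)` pair, and denominator chains
#' are conserved (frequency-selective units are a subset of sound-responsive
#' units, which are a subset of included units).  The run is deterministic:
#' no randomness is used in any analysis.
#'
#' @param bundles list of session bundles (each a list with `trials`,
#'   `units`, optional `meta$boundary`), e.g. from [read_session_bundle()].
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `units` (per-unit table),
#'   `population` (named list of `(k, n, percent)` entries), `log`
#'   (character vector of filter decisions), `config`.
#' @export
run_pipeline <- function(bundles, config = pipeline_config()) {
  if (length(bundles) == 0L) stopf("no session bundles given")
  log <- character(0)
  disc <- list(); swit <- list()
  for (si in seq_along(bundles)) {
    b <- bundles[[si]]
    assert_trial_table(b$trials)
    if (length(b$units) == 0L) stopf("bundle %d contains no units", si)
    is_switching <- length(unique(b$trials$contingency)) > 1
    if (is_switching) {
      filtered <- switching_trial_filter(
        b$trials, min_accuracy = config$min_session_accuracy,
        exclude_after_switch = config$switch_exclude)
      if (isTRUE(attr(filtered, "session_rejected"))) {
        log <- c(log, sprintf("session %d: rejected (accuracy < %g)",
                              si, config$min_session_accuracy))
        next
      }
      for (u in b$units) {
        r <- analyze_switching_unit(u, b$trials, filtered, config)
        r$session <- si
        if (!r$included)
          log <- c(log, sprintf("session %d unit %s: excluded by ISI filter (%.3f)",
                                si, r$unit_id, r$isi_fraction))
        swit[[length(swit) + 1L]] <- r
      }
    } else {
      boundary <- b$meta$boundary %||% config$boundary
      for (u in b$units) {
        r <- analyze_discrimination_unit(u, b$trials, boundary, config)
        r$session <- si
        if (!r$included)
          log <- c(log, sprintf("session %d unit %s: excluded by ISI filter (%.3f)",
                                si, r$unit_id, r$isi_fraction))
        disc[[length(disc) + 1L]] <- r
      }
    }
  }
  population <- list()
  units_disc <- NULL; units_swit <- NULL
  if (length(disc)) {
    cols <- c("session", "unit_id", "hemisphere", "isi_fraction", "included",
              "sound_index", "sound_p", "sound_responsive", "kw_p",
              "frequency_selective", "highlow_index", "highlow_p",
              "highlow_selective", "movement_index", "movement_p",
              "movement_selective", "analysis_stimulus", "z_responsive",
              "choice_tested", "choice_index", "choice_p", "choice_modulated",
              "pre_exit_index", "pre_exit_p", "pre_exit_modulated")
    units_disc <- unit_rows(disc, cols)
    ud <- units_disc[units_disc$included, ]
    n_all <- nrow(ud)
    population$sound_responsive <- pop_entry(sum(ud$sound_responsive), n_all)
    population$frequency_selective <-
      pop_entry(sum(ud$frequency_selective, na.rm = TRUE),
                sum(ud$sound_responsive))
    population$highlow_selective_all <-
      pop_entry(sum(ud$highlow_selective & ud$sound_responsive), n_all)
    population$highlow_selective_responsive <-
      pop_entry(sum(ud$highlow_selective & ud$sound_responsive),
                sum(ud$sound_responsive))
    population$movement_selective <- pop_entry(sum(ud$movement_selective), n_all)
    population$frequency_and_movement <-
      pop_entry(sum(ud$highlow_selective & ud$sound_responsive &
                      ud$movement_selective), n_all)
    tested <- !is.na(ud$choice_tested) & ud$choice_tested
    population$choice_modulated <-
      pop_entry(sum(ud$choice_modulated[tested]), sum(tested))
    population$pre_exit_choice <-
      pop_entry(sum(ud$pre_exit_modulated, na.rm = TRUE), n_all)
  }
  if (length(swit)) {
    cols <- c("session", "unit_id", "hemisphere", "isi_fraction", "included",
              "analysis_stimulus", "z_responsive", "switching_tested",
              "switching_index", "switching_p", "n_switch_effects",
              "switching_modulated", "pre_exit_index", "pre_exit_p",
              "pre_exit_modulated")
    units_swit <- unit_rows(swit, cols)
    us <- units_swit[units_swit$included, ]
    tested <- !is.na(us$switching_tested) & us$switching_tested
    population$switching_modulated <-
      pop_entry(sum(us$switching_modulated[tested]), sum(tested))
    population$pre_exit_switching <-
      pop_entry(sum(us$pre_exit_modulated, na.rm = TRUE), nrow(us))
  }
  structure(list(units = units_disc, units_switching = units_swit,
                 population = population, log = log, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$population)) {
    e <- x$population[[nm]]
    cat(sprintf("  %-30s %s\n", nm, format_fraction(e$k, e$n)))
  }
  if (length(x$log)) cat(sprintf("  (%d filter decisions logged)\n", length(x$log)))
  invisible(x)
}

#' Write a pipeline result to disk
#'
#' Emits `units.csv` (and `units_switching.csv` when present),
#' `population.json` with exact count pairs, and a plain-text `report.md`.
#' Output is byte-identical across reruns on the same inputs.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$units))
    write.csv(result$units, file.path(dir, "units.csv"), row.names = FALSE)
  if (!is.null(result$units_switching))
    write.csv(result$units_switching, file.path(dir, "units_switching.csv"),
              row.names = FALSE)
  jsonlite::write_json(result$population, file.path(dir, "population.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c("# Population summary", "",
             vapply(names(result$population), function(nm)
               sprintf("- %s: %s", nm,
                       format_fraction(result$population[[nm]]$k,
                                       result$population[[nm]]$n)),
               character(1)),
             "", "## Filter log", "",
             if (length(result$log)) paste("-", result$log) else "- none")
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
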