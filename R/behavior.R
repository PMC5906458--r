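# Behavioral analyses --------------------------------------------------------

#' Psychometric summary points
#'
#' Fraction of rightward choices per stimulus frequency with exact
#' Clopper-Pearson 95% binomial confidence intervals, computed over valid
#' trials of the requested subset.
#'
#' @param trials a trial table.
#' @param subset `"all"`, `"laser"` or `"control"` trials.
#' @param conf_level confidence level for the binomial CI.
#' @return A data frame of class `psychometric_points` with one row per
#'   distinct frequency: `frequency`, `n_trials`, `n_rightward`,
#'   `fraction_rightward`, `ci_low`, `ci_high`.  Empty subsets give a
#'   zero-row result.
#' @export
psychometric_points <- function(trials, subset = c("all", "laser", "control"),
                                conf_level = 0.95) {
  subset <- match.arg(subset)
  v <- valid_trials(trials)
  v <- switch(subset, all = v, laser = v[v$laser, ], control = v[!v$laser, ])
  out <- if (nrow(v) == 0L) {
    data.frame(frequency = numeric(0), n_trials = integer(0),
               n_rightward = integer(0), fraction_rightward = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0))
  } else {
    freqs <- sort(unique(v$frequency))
    rows <- lapply(freqs, function(f) {
      ff <- v[v$frequency == f, ]
      n <- nrow(ff); k <- sum(ff$choice == "right")
      ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
      data.frame(frequency = f, n_trials = n, n_rightward = k,
                 fraction_rightward = k / n, ci_low = ci[1], ci_high = ci[2])
    })
    do.call(rbind, rows)
  }
  class(out) <- c("psychometric_points", "data.frame")
  out
}

# Negative binomial log-likelihood of the 4-parameter logistic sigmoid
# p(right | f) = lapse_low + (1 - lapse_low - lapse_high) * plogis(beta (log f - alpha)).
psy_nll <- function(par, logf, k, n) {
  p <- par[3] + (1 - par[3] - par[4]) * plogis(par[2] * (logf - par[1]))
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Constrained maximum-likelihood psychometric fit
#'
#' Fits the 4-parameter logistic sigmoid (midpoint `alpha` on the natural-log
#' frequency axis, slope `beta`, lower/upper lapse rates bounded by
#' `lapse_bounds`) by maximizing the binomial likelihood of the per-frequency
#' rightward counts.  A deterministic multi-start grid over (alpha, beta)
#' followed by box-constrained local refinement makes the fit reproducible;
#' ties in likelihood are broken toward the lowest midpoint.
#'
#' @param points a [psychometric_points()] table (or any data frame with
#'   `frequency`, `n_trials`, `n_rightward`).
#' @param lapse_bounds interval constraining both lapse rates (default
#'   `c(0, 0.3)`).
#' @return A list of class `psychometric_fit`: `alpha` (log-kHz midpoint),
#'   `midpoint` (kHz), `beta` (slope per log-kHz), `lapse_low`, `lapse_high`,
#'   `loglik`, `converged`, `on_boundary` (TRUE when a lapse or the slope sits
#'   on a constraint).
#' @export
fit_logistic_psychometric <- function(points, lapse_bounds = c(0, 0.3)) {
  stopifnot(all(c("frequency", "n_trials", "n_rightward") %in% names(points)))
  pts <- points[points$n_trials > 0, ]
  if (length(unique(pts$frequency)) < 4)
    stopf("psychometric fit needs >= 4 distinct frequencies with trials")
  if (length(lapse_bounds) != 2 || lapse_bounds[1] < 0 || lapse_bounds[2] > 0.5 ||
      lapse_bounds[1] >= lapse_bounds[2])
    stopf("parameter `lapse_bounds` must be an interval inside [0, 0.5]")
  logf <- log(pts$frequency); k <- pts$n_rightward; n <- pts$n_trials
  span <- diff(range(logf))
  lower <- c(min(logf) - span, -200, lapse_bounds[1], lapse_bounds[1])
  upper <- c(max(logf) + span, 200, lapse_bounds[2], lapse_bounds[2])
  lap0 <- mean(lapse_bounds) / 4
  starts <- expand.grid(
    alpha = seq(min(logf), max(logf), length.out = 7),
    beta = c(-30, -10, -3, 3, 10, 30))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(starts$alpha[i], starts$beta[i], lap0, lap0), psy_nll,
            logf = logf, k = k, n = n, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best)) stopf("psychometric fit failed from every start")
  par <- best$par
  tol <- 1e-5
  on_boundary <- any(abs(par[3:4] - lapse_bounds[1]) < tol |
                       abs(par[3:4] - lapse_bounds[2]) < tol) ||
    abs(abs(par[2]) - 200) < 1e-3
  structure(list(alpha = par[1], midpoint = exp(par[1]), beta = par[2],
                 lapse_low = par[3], lapse_high = par[4],
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 on_boundary = on_boundary),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> midpoint %.2f kHz (alpha %.3f), slope %.2f, lapses (%.3f, %.3f)\n",
    x$midpoint, x$alpha, x$beta, x$lapse_low, x$lapse_high))
  cat(sprintf("  logLik %.2f, converged: %s, on boundary: %s\n",
              x$loglik, x$converged, x$on_boundary))
  invisible(x)
}

#' Predicted rightward-choice probability from a fit
#'
#' @param fit a [fit_logistic_psychometric()] result.
#' @param frequency frequencies (kHz).
#' @return Predicted probabilities.
#' @export
predict_psychometric <- function(fit, frequency) {
  fit$lapse_low + (1 - fit$lapse_low - fit$lapse_high) *
    plogis(fit$beta * (log(frequency) - fit$alpha))
}

#' Optogenetic choice bias of a session
#'
#' Bias is the difference between the fraction of rightward choices on
#' stimulation (laser) trials and on control trials, over valid trials.
#'
#' @param trials a trial table containing both laser and control trials.
#' @return A list of class `bias_result`: `fraction_right_stim`,
#'   `fraction_right_control`, `bias`, `n_stim`, `n_control`.
#' @export
stimulation_bias <- function(trials) {
  v <- valid_trials(trials)
  stim <- v[v$laser, ]; ctrl <- v[!v$laser, ]
  if (nrow(stim) == 0L || nrow(ctrl) == 0L)
    stopf("stimulation_bias needs both laser and control trials")
  fs <- mean(stim$choice == "right"); fc <- mean(ctrl$choice == "right")
  structure(list(fraction_right_stim = fs, fraction_right_control = fc,
                 bias = fs - fc, n_stim = nrow(stim), n_control = nrow(ctrl)),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "<bias_result> rightward: %.3f (laser, n=%d) - %.3f (control, n=%d) = %+.3f\n",
    x$fraction_right_stim, x$n_stim, x$fraction_right_control, x$n_control,
    x$bias))
  invisible(x)
}

#' Switching-task performance curves
#'
#' @param trials a switching-session trial table.
#' @param window moving-average window in valid trials.
#' @return A list of class `switching_performance`: `trial` (per valid trial:
#'   `trial_id`, `block_id`, trailing `moving_accuracy`), `blocks` (per block:
#'   contingency, n valid, accuracy), `by_stimulus` (block x frequency
#'   accuracy), `session_accuracy`.
#' @export
switching_performance <- function(trials, window = 40) {
  check_number(window, "window", lower = 1)
  v <- valid_trials(trials)
  if (nrow(v) == 0L) stopf("no valid trials")
  correct <- as.numeric(v$correct)
  csum <- cumsum(correct)
  i <- seq_along(correct)
  lo <- pmax(i - window + 1, 1)
  mov <- (csum - c(0, csum)[lo]) / (i - lo + 1)
  blocks <- do.call(rbind, lapply(split(v, v$block_id), function(b)
    data.frame(block_id = b$block_id[1], contingency = b$contingency[1],
               n_valid = nrow(b), accuracy = mean(b$correct))))
  by_stim <- do.call(rbind, lapply(
    split(v, list(v$block_id, v$frequency), drop = TRUE), function(b)
      data.frame(block_id = b$block_id[1], frequency = b$frequency[1],
                 n = nrow(b), accuracy = mean(b$correct))))
  by_stim <- by_stim[order(by_stim$block_id, by_stim$frequency), ]
  rownames(blocks) <- rownames(by_stim) <- NULL
  structure(list(
    trial = data.frame(trial_id = v$trial_id, block_id = v$block_id,
                       moving_accuracy = mov),
    blocks = blocks, by_stimulus = by_stim,
    session_accuracy = mean(correct)),
    class = "switching_performance")
}

#' Trials to criterion after each contingency switch
#'
#' Counts, for every switch, how many presentations of the switching
#' (shared) stimulus occur until the criterion is met.  The default
#' criterion is `n_consecutive` consecutive correct responses on that
#' stimulus; the reported value is the index (among switching-stimulus
#' trials, valid only) of the trial completing the run.
#'
#' @param trials a switching-session trial table.
#' @param n_consecutive run length required (default 4).
#' @return A data frame with one row per switch: `switch` (index), `block_id`
#'   of the post-switch block, `n_to_criterion` (`NA` when never reached).
#' @export
trials_to_criterion <- function(trials, n_consecutive = 4) {
  check_number(n_consecutive, "n_consecutive", lower = 1)
  v <- valid_trials(trials)
  blocks <- parse_blocks(trials)
  if (nrow(blocks) < 2) stopf("trials_to_criterion needs at least one switch")
  mid <- switching_stimulus(trials)
  out <- lapply(seq_len(nrow(blocks))[-1], function(b) {
    bt <- v[v$block_id == blocks$block_id[b] & v$frequency == mid, ]
    hit <- NA_integer_
    if (nrow(bt) >= n_consecutive) {
      run <- 0L
      for (j in seq_len(nrow(bt))) {
        run <- if (isTRUE(bt$correct[j])) run + 1L else 0L
        if (run >= n_consecutive) { hit <- j; break }
      }
    }
    data.frame(switch = b - 1L, block_id = blocks$block_id[b],
               n_to_criterion = hit)
  })
  do.call(rbind, out)
}
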