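# Head-angle quantification from marker centroids ----------------------------
#
# Input starts at per-frame centroids of two colored head markers; no image
# processing happens here.  The reference axis is the image x-axis — only
# angle changes are reported, so the reference is arbitrary.

wrap_diff <- function(d) ((d + 180) %% 360) - 180

#' Head angle from marker centroids
#'
#' The head angle is the orientation of the vector from the right marker
#' `(x2, y2)` to the left marker `(x1, y1)`; positive angles are
#' counter-clockwise (left) rotations.  Angles are unwrapped across frames
#' with both centroids present, so the series is continuous (no +-180
#' degree jumps) and can exceed a full turn.  Frames with a missing
#' centroid get `NA`.
#'
#' @param series a head-pose frame table with columns `frame`, `t`, `x1`,
#'   `y1`, `x2`, `y2` (see [simulate_head_trajectory()]).
#' @return A data frame (`frame`, `t`, `angle`) with the unwrapped angle in
#'   degrees.
#' @export
centroids_to_angle <- function(series) {
  need <- c("frame", "t", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(series)))
    stopf("head-pose series must have columns %s", paste(need, collapse = ", "))
  ok <- stats::complete.cases(series[, c("x1", "y1", "x2", "y2")])
  if (!any(ok)) stopf("no frame has both centroids")
  raw <- atan2(series$y1 - series$y2, series$x1 - series$x2) * 180 / pi
  angle <- rep(NA_real_, nrow(series))
  kn <- which(ok)
  unwrapped <- raw[kn[1]] + c(0, cumsum(wrap_diff(diff(raw[kn]))))
  angle[kn] <- unwrapped
  data.frame(frame = series$frame, t = series$t, angle = angle)
}

#' Fill gaps in an angle series by linear interpolation
#'
#' Missing frames are estimated linearly in the unwrapped angle; known
#' frames are left untouched and leading/trailing gaps are held at the
#' nearest known value.
#'
#' @param angles a data frame (`frame`, `t`, `angle`) as returned by
#'   [centroids_to_angle()].
#' @return The same data frame with every `angle` filled.
#' @export
interpolate_angles <- function(angles) {
  known <- !is.na(angles$angle)
  if (sum(known) < 2) stopf("interpolation needs >= 2 known frames")
  if (all(known)) return(angles)
  filled <- approx(angles$t[known], angles$angle[known],
                   xout = angles$t, rule = 2)$y
  angles$angle <- filled
  angles
}

angle_at <- function(angles, t) {
  if (t < min(angles$t) - 1e-9 || t > max(angles$t) + 1e-9)
    stopf("time %g s outside the tracked interval [%g, %g]",
          t, min(angles$t), max(angles$t))
  approx(angles$t, angles$angle, xout = t, rule = 2)$y
}

#' Head-angle change over stimulation intervals
#'
#' For each interval, the angle at the end of the stimulation minus the
#' angle at its beginning, on the unwrapped (and, if needed, interpolated)
#' series.  Rotations beyond 90 degrees are flagged, as whole-body rotations
#' typically follow head rotations of that size.
#'
#' @param angles an angle series (`frame`, `t`, `angle`), gaps allowed.
#' @param intervals a data frame with columns `onset` and `offset` (s), or a
#'   single `c(onset, offset)` pair.
#' @return A data frame: `onset`, `offset`, `delta_angle` (degrees),
#'   `body_rotation` (|delta| > 90).
#' @export
trial_angle_change <- function(angles, intervals) {
  if (is.numeric(intervals) && length(intervals) == 2)
    intervals <- data.frame(onset = intervals[1], offset = intervals[2])
  if (!all(c("onset", "offset") %in% names(intervals)))
    stopf("`intervals` needs columns onset and offset")
  if (any(is.na(angles$angle))) angles <- interpolate_angles(angles)
  delta <- vapply(seq_len(nrow(intervals)), function(i) {
    angle_at(angles, intervals$offset[i]) - angle_at(angles, intervals$onset[i])
  }, numeric(1))
  data.frame(onset = intervals$onset, offset = intervals$offset,
             delta_angle = delta, body_rotation = abs(delta) > 90)
}

#' Compare rotation magnitudes across stimulation sites
#'
#' Per-group mean and standard deviation (n-1 denominator) of per-trial
#' angle changes, plus a two-sided rank-sum test between the two sites
#' within each hemisphere (or overall when no hemisphere labels are given).
#'
#' @param delta per-trial angle changes (degrees).
#' @param site site label per trial (e.g. `"anterior"`, `"posterior"`;
#'   exactly two levels are compared).
#' @param hemisphere optional hemisphere label per trial.
#' @return A list of class `site_comparison`: `summary` (per group: n, mean,
#'   sd, `flagged` when n < 2 leaves the SD undefined) and `tests` (one
#'   rank-sum p per hemisphere).
#' @export
site_comparison <- function(delta, site, hemisphere = NULL) {
  site <- factor(site)
  if (nlevels(site) < 2) stopf("site_comparison needs >= 2 groups")
  hemi <- if (is.null(hemisphere)) factor(rep("all", length(delta)))
          else factor(hemisphere)
  grp <- interaction(site, hemi, drop = TRUE, sep = "/")
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    x <- delta[grp == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2) sd(x) else NA_real_,
               flagged = length(x) < 2)
  }))
  tests <- do.call(rbind, lapply(levels(hemi), function(h) {
    x <- delta[hemi == h & site == levels(site)[1]]
    y <- delta[hemi == h & site == levels(site)[2]]
    data.frame(hemisphere = h,
               comparison = paste(levels(site)[1:2], collapse = " vs "),
               p_value = if (length(x) && length(y)) ranksum_p(x, y) else NA_real_)
  }))
  structure(list(summary = summ, tests = tests), class = "site_comparison")
}
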