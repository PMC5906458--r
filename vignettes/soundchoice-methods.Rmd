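---
title: "Models and methods behind soundchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soundchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

soundchoice analyzes rodent auditory two-alternative choice (2AC)
experiments: a mouse pokes into a center port, waits through a short silent
delay, hears a 100 ms chord, and reports whether its center frequency lies
below or above a categorization boundary by choosing the left or right
reward port. The package covers the behavioral read-outs (psychometric
curves, optogenetic choice bias, switching-task performance), event-aligned
spike-train statistics for simultaneously recorded striatal units
(modulation indices, a binned z-score responsiveness criterion,
contingency-switching analysis), and head-rotation quantification from
overhead video markers. Because such data sets are rarely deposited, the
package ships a synthetic-session generator with fully known ground truth;
every analysis is validated by recovering what the generator programmed.

```{r setup}
library(soundchoice)
```

## The synthetic session model

`simulate_discrimination_session()` draws trials under the task's timing
contract: a uniform 150–250 ms silent delay between center poke and sound
onset, a 100 ms stimulus, and withdrawal after the sound on valid trials.
Stimuli are sampled uniformly from 6 (by default) log-spaced chord center
frequencies spanning two octaves (6–24 kHz), with the categorization
boundary at their geometric center (12 kHz). Choices follow a
four-parameter logistic in log frequency,

$$p(\mathrm{right} \mid f) \;=\; \lambda_L + (1 - \lambda_L - \lambda_H)\,
\sigma\!\big(\beta(\log f - \alpha)\big),$$

with midpoint $\alpha$ (log-kHz), slope $\beta$, and lapse rates
$\lambda_L, \lambda_H$ bounding the asymptotes away from 0 and 1.
Optogenetic ("laser") trials are an exact random subset — 20% is the
fraction used in the stimulation experiments the generator emulates — and
shift the rightward probability additively by `laser_bias_shift`, clipped
to $[0, 1]$. The clipping matters when interpreting recovery: an additive
shift programmed near a saturated part of the curve is partly absorbed by
the clip, so bias-recovery checks are run in a regime where neither arm
saturates. Early withdrawals (invalid trials) are generated at a
configurable rate, default 0, and are excluded from every analysis.

The switching task alternates blocks of 200–250 trials between a
low-boundary contingency (stimuli low/mid, mid rewarded right) and a
high-boundary contingency (mid/high, mid rewarded left); only the two
stimuli relevant to the current boundary appear in a block, and no cue
marks a switch. The simulated agent applies the *previous* block's boundary
for `learning_trials` trials after each switch (default 15, matching
animals that need fewer than 20 switching-stimulus trials to re-learn), and
otherwise the current one, with a stimulus-independent error rate (default
5%, the lapse level of a well-trained animal). A consequence worth noting:
during the learning window the agent is wrong on essentially every
switching-stimulus trial but still correct on the other stimulus, so
overall accuracy sits near 50% while switching-stimulus accuracy collapses
— the signature seen in per-stimulus performance curves.

### Units as piecewise-constant-rate Poisson processes

`simulate_unit()` models a unit as a Poisson process whose rate is
`baseline_rate` everywhere except in defined trial windows, where it is
multiplied by programmed gains:

* a frequency-tuned evoked gain during the sound window
  $[t_\mathrm{on}, t_\mathrm{on} + 100\,\mathrm{ms})$:
  $g(f) = 1 + (g_e - 1)\exp(-\log_2^2(f/f_0)/2w^2)$, a Gaussian profile in
  octaves. At the preferred frequency the rate is $g_e \times$ baseline
  ($g_e < 1$ gives suppressed units); far away it falls back to baseline.
  The Gaussian-in-log-frequency shape matches the log-spaced stimulus
  design; striatal tuning shapes are not otherwise constrained by data,
  and nothing downstream depends on the shape beyond "tuned vs. broad".
* `choice_gain` in the same sound window on trials whose upcoming choice is
  ipsilateral to the unit's hemisphere — choice modulation is a rate gain
  conditioned on upcoming choice, not a separate latent process, which is
  sufficient to test detection;
* `movement_gain_ipsi` / `movement_gain_contra` in the window 50–150 ms
  after center-port exit.

This piecewise-constant construction is chosen because it yields exact
analytic oracles: counts in any window are Poisson with mean
rate × duration, so e.g. an evoked gain of 2 gives a sound response index
of exactly $(2-1)/(2+1) = 1/3$ in expectation, and the tests assert these
values. An optional monotone drift multiplier
$1 + (g_d - 1)(1 - e^{-t/\tau})$ models slow nonstationarity for testing
the switching analysis's drift resistance.

One deliberate departure from a pure Poisson process: spikes closer than
1.5 ms to their predecessor are removed (absolute refractory period,
configurable, 0 disables it). Without it, any unit above ~10 Hz would fail
the 2 ms / 2% ISI contamination filter *by construction*, which would make
the quality criterion meaningless on synthetic data. The dead time shortens
window counts by under ~3% at typical rates; the analytic-oracle tests that
need exact Poisson statistics set `refractory = 0`.

All randomness flows from one master seed through named substreams
(behavior, each unit, pose), so any component can be regenerated
independently and a fixed seed reproduces a bundle byte for byte.

### What the generator does not emulate

Real striatal recordings have bursting and non-Poisson interval statistics,
rate co-fluctuations across simultaneously recorded units, behavioral
history effects (win-stay/lose-switch, motivation drift), and
stimulus-correlated movement artifacts. Passing recovery tests on this
generator therefore demonstrates that the *analysis chain* is correct and
its detection thresholds behave as designed — not that the effect sizes
chosen here are what tissue produces.

## Behavioral analyses

`psychometric_points()` tabulates rightward fractions per frequency with
exact Clopper–Pearson 95% intervals (chosen over Wald/Wilson because it is
parameter-free and exact at the small per-frequency counts of single
sessions). `fit_logistic_psychometric()` maximizes the binomial likelihood
of the four-parameter sigmoid under box constraints (lapses default to
$[0, 0.3]$ — generous for trained mice, tight enough to keep the slope
identifiable). The optimizer is a deterministic grid of 42 starts over
$(\alpha, \beta)$ — midpoints across the tested range, slopes
$\pm\{3, 10, 30\}$ — each refined by `L-BFGS-B`, with ties broken toward
the lowest midpoint. This removes any seed dependence from the fit; the
recovery tests require the fitted likelihood to beat the generating
parameters' likelihood on every fixture, so optimizer regressions cannot
hide inside tolerance bands. Boundary solutions (a lapse pinned at a bound,
as happens for degenerate all-one-side data) are flagged, not silently
returned.

`stimulation_bias()` is the plain difference in rightward fractions,
laser minus control — antisymmetric under swapping the labels, and
recovered against the programmed shift in a non-saturating regime.
Session-level biases are aggregated by simple averaging, not hierarchical
modeling.

`trials_to_criterion()` defaults to "first trial completing 4 consecutive
correct switching-stimulus responses", counted over valid
switching-stimulus trials after each switch. The criterion is configurable;
the oracle agent reaches it at exactly 4.

## Spike-train statistics

All windows are half-open $[a, b)$ relative to their event, so a spike on a
shared boundary is counted exactly once; stated ranges like "0–100 ms"
follow this convention throughout. Alignment and window counts are verified
against a brute-force $O(nm)$ scan on random fixtures.

Three indices share one form, $(A - B)/(A + B)$ on across-trial mean
counts: the sound response index (evoked 0–100 ms vs. baseline −100–0 ms,
pooled over all frequencies), the high/low selectivity index (evoked counts
split at the categorization boundary), and the movement/choice modulation
index (ipsilateral vs. contralateral trials; left-hemisphere units treat
left choices as ipsilateral). The index is undefined (NA) when both means
are zero; such silent units are excluded from population fractions rather
than coerced to 0. Significance uses two-sided Wilcoxon rank-sum tests on
the per-trial counts — exact where `stats::wilcox.test` supports it, the
tie- and continuity-corrected normal approximation otherwise. The
evoked-vs-baseline comparison is implemented as a two-sample test on the
per-trial counts (the paired and pooled readings of "comparing evoked to
baseline" differ; the two-sample one is used and stated here). Frequency
selectivity among sound-responsive units uses the tie-corrected
Kruskal–Wallis H test, with $p = 1$ by convention when every observation is
identical.

The responsiveness criterion used to gate choice and switching analyses
bins activity into 25 ms bins, compares each of the four response bins
(0–100 ms) to the single baseline bin (−50 to −25 ms) by rank-sum, and
calls a unit responsive when any bin's tie-corrected standardized rank-sum
statistic (z, no continuity correction) falls outside $(-3, 3)$.
Deliberately, no multiple-testing correction is applied across the four
bins — the criterion is the union rule itself; its family-wise false-positive
rate (≈1% at |z|≥3, below the naive 4 × two-sided bound because the bins
share one baseline and counts are discrete) is quantified by simulation in
the test suite, not corrected away.

For choice analyses, the analysis stimulus is chosen per unit as whichever
of the two frequencies nearest the boundary elicits the larger absolute
sound response index, ties toward the lower frequency — a deterministic
restatement of "the near-boundary stimulus with the largest evoked
response".

## Switching analysis

Blocks are maximal runs of constant contingency. The stable-performance
filter (i) rejects sessions below 60% correct — applied per session, the
plainest reading; a per-block variant would only tighten it — (ii) drops
the first 20 trials after each switch, counting *all* trials, not just
switching-stimulus ones, and (iii) keeps only correct, valid trials. The
filter stores each trial's original position within its block, which makes
it idempotent even after rows are removed.

`switching_modulation()` computes the contingency index on filtered
switching-stimulus counts and applies a two-part rule: the pooled rank-sum
must be significant, *and* the effect must be observed at ≥ 2 switches —
operationalized as: the rank-sum between the two blocks adjacent to a
switch has $p < 0.05$ with the ipsi-minus-contra sign matching the overall
index. "Observed at a switch" is not otherwise defined anywhere we could
follow, so this definition is the package's own and both pieces are
configurable. Its purpose is specificity against nonstationarity: a unit
whose rate merely drifts monotonically produces adjacent-block differences
whose contingency-referenced signs alternate, so it can satisfy the pooled
test but rarely assembles two same-signed significant switches. The test
suite quantifies this with saturating-drift and step-change units (< 10%
flagged) against programmed contingency-coupled units (> 90% detected).

## Head tracking

The head angle is the orientation of the right→left marker-centroid vector
against the image x-axis (positive = counter-clockwise = leftward). Only
angle *changes* are reported, so the reference axis is arbitrary. Angles
are unwrapped across observed frames before any interpolation —
interpolating wrapped angles across the ±180° cut is simply wrong — under
the assumption that the head turns less than 180° between consecutive
observed frames (comfortably true at the generator's default 30 Hz, a free
parameter since the recording rate is not otherwise pinned down). Missing
frames are filled linearly in unwrapped angle, with edge gaps held at the
nearest observed value. Per-trial rotation is the angle difference across
each 1.5 s stimulation interval; |Δ| > 90° raises a body-rotation flag
(rotations that large recruit the body), which is reported but not
tracked further.

## Population reporting

`run_pipeline()` chains the unit-quality ISI filter (< 2% of intervals
under 2 ms), the sound-response test, frequency selectivity, high/low
selectivity, movement and choice modulation, and — for switching sessions —
the contingency analysis, and aggregates fractions. Every percentage is
stored as its exact integer pair $(k, n)$ and formatted with
`fraction_percent()`, which rounds half-up at one decimal using integer
arithmetic only. Round-half-even would format the same values identically
on all pairs exercised here; half-up is used because it is the convention
the reported fractions follow. Denominator chains are conserved by
construction: frequency-selective units ⊆ sound-responsive units ⊆ included
units, and every tested subset reports its own denominator next to the
percentage. The pipeline is fully deterministic — analyses use no random
numbers — so re-running on the same bundles reproduces outputs byte for
byte.

## Problem sizes and numerical choices

The validation suite works at "desk scale": populations of 520 units across
5 sessions of 600 trials (matching the recorded population size the
fraction chain refers to), 2000-unit null batteries for test size, and
40–80 unit batteries for switching specificity. These sizes give binomial
standard errors comfortably inside the tolerances being asserted
(e.g. ±2 points on a 5% rejection rate at n = 2000) while keeping a full
run in minutes on a laptop. Other numerical conventions: likelihood
clipping at $10^{-9}$ in the psychometric fit; rank-sum z with tie
correction and zero variance mapped to $z = 0$; `NA` indices propagate to
"counted separately", never to 0.

## Known limitations

* The generator's effect-size defaults are plausible but not fitted to
  tissue; detection-rate recoveries validate thresholds, not biology.
* The psychometric fit is per session; no hierarchical pooling.
* The choice/switching gate inherits the z-criterion's moderate power at
  ~100 trials per stimulus, so detected choice fractions sit slightly
  below programmed ones at realistic session lengths (visible, and
  accounted for, in the recovery tolerances).
* Ipsi/contra assignment trusts the hemisphere metadata; no lateralization
  check is performed on the data itself.
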