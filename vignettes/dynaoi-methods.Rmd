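---
title: "Motion tracking and anticipatory looking with dynamic AOIs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion tracking and anticipatory looking with dynamic AOIs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaoi)
```

## The problem this package addresses

When an animal watches a repetitive dynamic scene — here, two players
throwing an object back and forth on a screen — two questions can be asked
of its raw gaze stream. First, *motion tracking*: how much of the variance
in horizontal gaze position is explained by the horizontal position of the
moving object? Second, *anticipatory looking*: does gaze arrive at the
object's destination (the catcher) before the object does, and does that
anticipation grow with repeated exposure? `dynaoi` implements the full
chain from raw gaze samples to mixed-model inference for both questions,
plus a seeded simulator so every stage can be exercised and validated with
known ground truth.

All analyses consume raw samples. No fixation or saccade event detection
is applied anywhere: the tracking regression and the first-look detector
operate directly on the time-stamped sample stream, so results do not
depend on an event-parsing algorithm's settings.

## Stimulus model

A timeline (`build_timeline()`) describes one of two designs:

* **exp1** — ten throws alternating between the two players over 16 s at
  60 fps. The catcher is additionally "frozen" (a boolean covariate; the
  object still arrives) on throws 2, 5, 7 and 10.
* **exp2** — the same base video, but frozen for 1,000 ms while the object
  is in mid-air and then rewound to the thrower, twice in a row at throw 4
  and twice at throw 9. Each completed rewind returns the object to a
  player and is treated as a catch-type event, giving 10 forward + 4
  backward events.

Throw kinematics are reconstructed, not copied from a video file: each
throw occupies a 1,600 ms cycle (hold at the thrower, 650 ms linear
flight between the player centres, hold at the catcher), which yields the
printed 16 s for ten throws and matches the ±650 ms interest-period
half-width being "roughly the flight time". For exp2, a freeze at 50% of
the flight plus a same-speed rewind adds 2 × (325 + 1,000 + 325) ms per
freeze-rewind pair; the printed 24 s total additionally requires a short
handling pause after each rewind before the throw is replayed, which we
set to 350 ms (4 × 350 ms closes the 1.4 s gap exactly). These are the
package's own reconstruction choices; all of them are configurable in
`timeline_config()`.

Every event's *contact time* is the start of the last full video frame
before the object reaches the catcher, consistent with latencies being
measured "relative to the frame before contact" at 60 fps.

The pixel-to-degree scale derives from the horizontal extent only
(48.2° across 1,024 px at 50 cm). The printed vertical extent is not
consistent with square pixels, and every analysed signal is horizontal,
so the horizontal scale governs `visual_angle_deg()`. With this geometry
the 52 px object subtends 2.6°, a 90 px fixation target 4.5°, and 50/32 px
calibration targets 2.5°/1.6°, reproducing the printed apparatus values.

Player AOIs default to the outer 25% of the video width on each side
(their exact published extent is only shown graphically); the signed
gaze distance of the anticipation analysis is measured from the AOI edge
facing the screen centre, positive inside the catcher area.

## Motion tracking

`fit_tracking()` regresses horizontal gaze on the horizontal object
position by OLS, pairing each gaze sample with the AOI track linearly
interpolated to that sample's timestamp — the full-rate gaze stream stays
the response variable; the coarser AOI track (one keyframe every
~55–61 ms) is never used to down-sample gaze. r² equals the squared
Pearson correlation of the pairs, and a window with a constant target
position (one lying entirely inside a freeze) is reported as undefined,
never as 0. Invalid samples and samples outside the video rectangle are
dropped pairwise. For exp2, `fit_tracking_periods()` fits the five longer
analysis periods (before, first freeze-rewind pair, between, last pair,
after) separately.

## Anticipatory looking

For each catch-type event, an interest period spans the contact time
± 650 ms (half-open `[start, end)`; entry exactly at the window start
counts). The first look at the catcher is the first run of consecutive
valid samples with signed distance ≥ 0 spanning at least `min_dwell_ms`
(default 25 ms). The dwell guard exists because the pipeline is
sample-based: a single 1 ms noise excursion across the AOI boundary
should not count as a look. Setting `min_dwell_ms = 0` gives the literal
first-sample rule; whether the original analysis used any such guard is
not recoverable, so both behaviours are supported and the guard is a
configuration value, not a claim.

Two exclusion rules shape the model dataset (`apply_exclusions()`): the
first event is dropped for every subject, and an observation is excluded
as `not_looked_away` when gaze never left the catcher rectangle between
the previous event's contact time (video onset for event 2) and the
current window's start — absence of any valid sample over that span
triggers the same status, a deliberately conservative reading. With 11
subjects and events 2–10 this machinery yields 99 candidate events; with
9 subjects and events 2–14, 117.

Subject-level inclusion (`filter_subjects()`) requires at least 70% of
valid samples inside the video area. The original rule was phrased in
terms of fixations, but since this pipeline applies no event detection,
the fraction of valid raw samples is the operative criterion; a
fixation-based variant could classify borderline subjects differently.

## Mixed models

`fit_lmm()` fits the latency models with `lme4`: fixed effects as
specified, a per-subject random intercept, and a per-subject random slope
for every fixed-effect design column with all random-effect correlations
omitted (each random term enters as its own `(0 + x | subject)` block).
Numeric covariates are z-standardized beforehand; condition factors use
explicit reference levels (catcher movement: `frozen`; object movement:
`backward`). For the period-level model, observed latencies are averaged
per subject × analysis period, and the period number is z-standardized
within movement condition.

Estimates, standard errors and Wald 95% CIs come from the REML fit.
Every reported test is a likelihood-ratio comparison of ML refits: each
fixed term against the model without it, and the full model against the
intercept-only null, in both cases keeping the random structure fixed —
the null models retain all random slopes, which resolves an ambiguity in
the usual description of full-null comparisons in the conservative
direction. Wald CIs were chosen because the CI method behind published
tables of this kind is typically unstated; a profile or bootstrap CI
could be substituted without affecting any test.

Model stability (`stability_loso()`) refits once per left-out subject
and reports the min/max of each fixed estimate; non-convergent refits
are excluded and counted. Collinearity (`vif_fixed()`) is assessed as
`1/(1 − R²)` per design column on the fixed-effects-only design, the
standard VIF on the random-effects-free model. With ~10 subjects,
singular random-effect fits are expected occasionally; they are flagged
on the result (`$singular`) rather than auto-simplified, so the user
sees exactly what was fitted.

## The simulator and what it does (not) show

`simulate_recording()` generates gaze as the target track delayed by a
per-subject pursuit lag plus Gaussian jitter. Around each event, pursuit
saturates just outside the catcher AOI until the subject's scheduled
look, which enters the AOI boundary exactly at the planted time and ramps
to the player centre over `saccade_duration_ms`. This makes the planted
latency recoverable to within one sample interval by construction, which
is what the recovery tests rely on. Defaults:

* pursuit lag 120 ± 40 ms and jitter 30 px — placeholders chosen so that
  whole-video r² lands within the plausible published range for this
  paradigm; they are not claims about dog oculomotor control.
* planted latency: −38 ms at the mean event number, −30 ms per event,
  subject SDs 60 ms (intercept) and 10 ms (slope), residual 120 ms,
  backward events +140 ms — all anchored to the published summary
  statistics of the paradigm the package implements.
* looks occur with probability 0.65 per event, matching the observed-look
  rates (≈61/99 and ≈72/117) of the original datasets.
* blinks: Poisson starts at 0.2/s, 150 ms each; off-video excursions
  0.05/s, 300 ms.

Even-indexed subjects are emitted in mirrored orientation to exercise the
`normalize_orientation()` step; a mirrored twin yields exactly the
latencies of its unmirrored counterpart after normalization.

Two caveats on realism. First, the simulator does not model attentional
disengagement — a simulated subject never stops tracking for seconds at a
time, which real animals do; simulated whole-video r² therefore
concentrates near the top of the real range, and passing recovery tests
demonstrate correctness of the estimators, not that real data will be as
clean. Second, saccades are simple linear ramps with no main-sequence
kinematics; latency extraction only depends on AOI entry time, so this
does not affect what the tests validate.

## Numerical and scale choices

* Coordinates: origin top-left, x rightward, pixels; times in ms from
  video onset; all windows half-open `[start, end)`.
* Interpolation: the AOI track is piecewise linear; `position_at()` is
  exact at keyframes. Freeze-rewind edits splice exact nodes at all edit
  boundaries, so held positions are exactly constant and the edited track
  is continuous (bounded by the flight speed × sample spacing).
* Degenerate inputs are errors or flagged results, never silent zeros:
  constant covariates, windows without usable samples, single-subject
  model data, rank-deficient VIF designs.
* Validation problem sizes: the oracle suites use 200 random tracking
  windows, 1,000 randomized latency traces, and 100 + 200 simulated
  cohorts of 11 subjects at a 250 Hz sampling rate. The reduced rate
  (4 ms sample spacing instead of 1 ms) only coarsens latency
  quantization, which is negligible against the ~120 ms residual SD, and
  keeps the recovery study compact; all defaults remain 1,000 Hz.

## Known limitations

* The exp2 segment layout between rewind and replay is a reconstruction;
  only its total duration is constrained by the published design.
* The attention criterion is sample-based, not fixation-based (above).
* Whether "looked away" required leaving the player rectangle or the
  whole screen region is unstated; the package uses the rectangle.
* No vertical-channel or 2-D tracking metrics, no pursuit gain/lag
  estimation, no pupil measures: the analysis chain is deliberately
  limited to the horizontal signals it was designed around.
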