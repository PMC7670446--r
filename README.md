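# dynaoi

Dynamic area-of-interest gaze analysis for motion tracking and
anticipatory looking.

`dynaoi` is for researchers analysing eye-tracking recordings of subjects
(originally: pet dogs) watching a repetitive dynamic scene — two players
throwing an object back and forth on a screen. It implements the complete
analysis chain on **raw gaze samples**, with no fixation/saccade event
detection anywhere:

* **Stimulus timelines** — throw schedules, freeze and rewind edits,
  player rectangles, and a piecewise-linear dynamic AOI track for the
  moving object, plus pixel-to-visual-angle conversion
  (`2·atan(extent_cm / 2d)` with the cm/px scale derived from the
  horizontal screen extent).
* **Motion tracking** — per-subject OLS regression of horizontal gaze on
  the interpolated horizontal target position; the tracking *r²* is the
  proportion of gaze variance explained by the object's motion.
* **Anticipatory looking** — signed horizontal gaze distance from the
  catcher AOI boundary within ±650 ms interest periods around each
  catch event; the *first-look latency* is the first sustained AOI entry
  minus the contact time (negative = gaze arrived before the object).
* **Inclusion and exclusion rules** — subjects need ≥ 70% of valid
  samples on the video; the first event is dropped; looks that are mere
  continuations of the previous look are excluded.
* **Mixed models** — `lme4` fits with per-subject random intercepts and
  uncorrelated random slopes for every fixed term, z-standardized
  covariates, likelihood-ratio tests per term and against the
  intercept-only null, leave-one-subject-out stability ranges, and
  variance inflation factors on the fixed-effects design.
* **A seeded gaze simulator** — lagged smooth pursuit with jitter,
  blinks, off-video excursions, mirrored-orientation subjects, and a
  planted anticipation trend with known ground truth, used by the
  package's parameter-recovery tests.

## Worked example

Simulate an 11-subject cohort on the 16-s ten-throw design, run the whole
pipeline, and inspect the results:

```r
library(dynaoi)

geom <- viewing_geometry()        # 50 cm, 1024x768 px, 48.2 deg wide
visual_angle_deg(52, geom)        # the 52 px object subtends 2.6 deg

tl <- build_timeline("exp1")
#> <stimulus_timeline> exp1: 16000 ms at 60 fps, 10 catch-type events
#> (10 forward, 0 backward), 0 edits

res <- run_pipeline(run_config("exp1", "simulate", seed = 42,
                               n_subjects = 11, out_dir = "demo_run"))

res$r2_summary      # tracking r2: median 0.87 (range 0.82-0.92)
res$latency_summary # median -46 ms (range -349 to 284), 62/99 observed
print(res$models$lmm01)
#> <lmm_result> latency_ms ~ movement + throw_z | 62 obs, 11 subjects [singular fit]
#>             term estimate    se ci_lower ci_upper   chisq df         p
#> 1    (Intercept)   -10.71 25.99   -61.64    40.23      NA NA        NA
#> 2 movementmoving   -24.53 30.27   -83.86    34.79  0.6552  1 0.4182611
#> 3        throw_z   -83.23 18.74  -119.96   -46.51 10.8417  1 0.0009924
#>   stability_min stability_max
#> 1        -29.87        0.1145
#> 2        -34.13       -9.5923
#> 3        -98.85      -72.4111
#> Full-null comparison: chisq = 11.53, df = 2, p = 0.003
```

Reading the model table: the simulator plants a latency trend of
−30 ms per throw, and the `throw_z` estimate of −83 ms per standard
deviation of throw number (sd(2:10) ≈ 2.74) recovers it — subjects look
at the catcher earlier on later throws. The movement covariate (whether
the catcher was frozen) has no planted effect and tests non-significant.
The `[singular fit]` flag reports that one random-effect variance was
estimated at zero, expected with 11 subjects; the stability columns show
the estimate range when each subject is left out in turn.

The candidate-event count of 99 is the design's bookkeeping check:
11 subjects × throws 2–10. The 24-s design (`build_timeline("exp2")`)
yields 14 catch-type events (10 forward + 4 rewound) and 117 candidates
for 9 subjects, and additionally fits period-level models with movement
direction (reference: backward) and within-condition period number.

`run_pipeline()` writes a full report bundle (exclusions, tracking,
observations, model tables, run log) as delimited text; identical seeds
produce byte-identical bundles. A thin command-line wrapper lives at
`inst/scripts/dynaoi-run.R`.

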