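---
title: "Simulating eye-movement threshold perimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating eye-movement threshold perimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeperim)
```

## The procedure being modelled

Standard automated perimetry (SAP) maps differential light sensitivity (DLS)
across the visual field: small luminance increments are flashed at fixed
retinal locations and the observer presses a button when one is seen. An
eye-movement perimeter replaces both the chin rest and the button. A remote
eye tracker reports gaze at 50 Hz; each stimulus is drawn on a desktop
monitor *relative to wherever the observer is currently fixating*, so that it
lands at the intended retinal location without requiring steady central
fixation; and the response is the reflexive saccade toward the target.
`gazeperim` implements that procedure end to end as a simulation: no
hardware, with synthetic observers standing in for human participants. It is
aimed at researchers who want to study the algorithmic properties of such a
test — threshold-estimation accuracy, termination behaviour, catch-trial
error accounting, test–retest repeatability — without a lab.

## The decibel scale

Sensitivity is reported as attenuation of the display's largest increment:

$$\mathrm{DLS}_{dB} = 10\,\log_{10}(\Delta L_{max} / \Delta L_{jnd}),$$

with background 10 cd/m², $\Delta L_{max} = 225$ cd/m², giving a working
domain of 0–34 dB (higher = more sensitive). A clinical comparator (HFA)
uses the same formula against its own, much brighter, 3183.1 cd/m² pedestal,
so its values must be passed through `hfa_to_native_db()` before comparison:
converted to linear units, re-expressed against 225 cd/m², and any negative
result rounded up to 0 (an increment brighter than anything the panel can
display). The two scales coincide nowhere except through this map; the
crossover (HFA dB that maps exactly to 0) is $10\log_{10}(3183.1/225)
\approx 11.51$ dB.

The printed minimum increment of 0.08 cd/m² corresponds to 34.49 dB, just
past the last integer grid value; we treat the integer grid $\{0,\dots,34\}$
as authoritative and leave intensities continuous (no 10-bit panel
quantisation — the dB grid already discretises presentations).

## Test grid and growth pattern

The grid is the standard 54-point 24-2 lattice (odd multiples of 3°, 6°
spacing, nasal extension pair at 27°) minus the four-point top and bottom
rows (`|y| > 15°`), which remote trackers cannot cover reliably: 46
locations, of which two — (15°, ±3°) in right-eye format, the projection of
the optic nerve head — are blind-spot validity checks and 44 carry the
measurement. Left-eye grids are the x-mirror; results are pooled in
right-eye format.

Testing proceeds in growth-pattern stages: the four quadrant seeds at
(±9°, ±9°) run first, and each later stage contains untested points within
one lattice step (6° Chebyshev) of an earlier stage, so every new location
can borrow information from a measured neighbour. The published figure that
defines the original grouping is not machine-readable, so the default here
is a breadth-first reconstruction with the same seeds and adjacency rule;
the grouping is config-overridable (set the `group` column of the grid).
Blind-spot points sit outside the pattern and are scheduled throughout the
session.

## Tangent-screen geometry

The display (59.7 × 33.6 cm, 2560 × 1440 px, ~60 cm viewing distance,
52.9° × 31.3°) is flat, so visual angle is not proportional to pixels. We
use a per-axis tangent construction with the eye on the normal through the
screen centre: a pixel at physical offset $c$ from centre subtends
$\theta = \arctan(c/d)$, and a field offset is placed by inverting this at
the current fixation angle. Head translation is folded into the effective
fixation position; the projection convention itself is a modelling choice
(the arithmetic of the screen-extent figures above is what anchors it).

Because of the tangent mapping, a stimulus of fixed retinal size (Goldmann
III, 0.43° diameter) must be drawn physically larger towards the screen
edge and at greater viewing distance; `stimulus_footprint()` applies that
warp and, by construction, holds the subtended angle within 0.5% over the
50–70 cm working range. Placements are validated before presentation: the
footprint must lie on-screen, outside prohibited zones (defaulting to the
two bottom screen corners, where display and tracking quality degrade), and
inside the tracker's ±27° × ±15° trackable box. A failed placement triggers
a refixation trial — an attention-grabbing recentering event — never a
silent skip. Gaussian edge blur of the physical stimulus is recorded as a
configuration field (`blur_sigma_deg`) but not rendered; this package has no
renderer.

## ZEST thresholding

Each location maintains a posterior over the integer dB domain. The
likelihood of a hit at stimulus $s$ given threshold $t$ is a cumulative
Gaussian $\Phi((t - s)/\sigma)$ with fixed slope $\sigma = 1.25$ dB
(optional guess/lapse rates default to 0). The prior is bimodal — a healthy
component centred on the location's normative value (SD 2 dB) mixed with a
broad abnormal component (mean 5, SD 8, weight 0.2) so damaged locations are
reached quickly; the exact constants follow the usual construction for this
prior but are conventions, exposed in `prior_spec()`. Stimuli are placed at
the posterior mean snapped to the grid (ties toward the brighter value), the
final estimate is the continuous posterior mean, and termination is dynamic:
posterior SD ≤ 1.5 dB.

Two guard rails surround the dynamic criterion. A presentation cap (default
20) bounds pathological locations. And a minimum of 4 presentations is
required before the dynamic criterion is consulted: with a slope-1.25
likelihood and an informative prior, one or two consistent responses can
collapse the posterior SD below 1.5 dB while the mean is still far from the
true threshold, which would end locations after ~2 trials and give sessions
of only ~100 trials; the floor restores the ~200-trial regime a full test
of this design is documented to take, and materially reduces worst-case
pointwise error. Whether the floor should be 3, 4 or 5 is not sharply
determined; 4 was fixed once from that trial-count arithmetic.

When a stage opens, each new location's prior is recentred: its healthy-mean
becomes the normative value shifted by the mean deviation
(estimate − normative) of completed 6°-neighbours. Blind-spot locations use
the same machinery with a prior centred near 0 dB.

Note the interpretation of the termination rule: posterior SD ≤ 1.5 dB is a
statement about the posterior's spread, *not* a guarantee that every
individual estimate lies within 1.5 dB of truth. Across 44 locations the
worst single error in a session is routinely 2–3 dB even for a noiseless
observer; what holds (and what the tests assert) is the SD bound itself,
a mean absolute error within the termination spread, and the absence of
systematic bias.

## Saccadic response classification

A presentation is a hit if at least $N$ valid gaze samples land within a
$D° \times D°$ box centred on the target within $R$ seconds of onset.
Counting is cumulative (the printed rule requires only that the samples
"fell within", not that they be consecutive), the box is closed on its
boundary, and invalid tracker samples are skipped, never interpolated.
$N, D, R$ vary with eccentricity — peripheral saccades are slower and less
accurate — and only one anchor triple is published: (9°, 9°) →
$N = 6, D = 2.77, R = 1.62$. The default model is therefore an explicit
placeholder, affine in eccentricity about that anchor
($D$ and $R$ growing 6%/° and 4%/° respectively, $N$ constant), with every
coefficient in the configuration so the true functional forms can be
substituted when known.

## The synthetic observer

The generator stands in for a cohort of young, normally sighted adults.
True thresholds follow a parametric hill of vision,
$\mathrm{clamp}(\text{peak} - \text{slope}\cdot\text{eccentricity} +
\text{observer offset} + \text{pointwise noise},\ 0,\ 34)$, with defaults
peak 23 dB, slope 0.25 dB/°, 1 dB between-observer SD and 1 dB pointwise
SD — a calibration chosen so cohort mean sensitivity lands in the
high-teens regime typical of such cohorts on this scale, not a measured
value. Blind-spot locations are truly blind: a hard flag, not merely a 0 dB
threshold, so nothing displayable is ever detected there and their response
rate equals the false-positive rate (a 0 dB threshold alone would still
imply 50% detection of a 0 dB stimulus, which is not how an absolute
scotoma behaves). Simulated field defects (config polygons with a dB depth,
e.g. arcuate shapes) can be subtracted for patient-mode experiments.

Responses follow an error-adjusted frequency-of-seeing curve
$p = fp + (1 - fp - fn)\,\Phi((t - s)/\sigma_{fos})$, with defaults
$fp = 0.028$, $fn = 0.073$ (the error-rate regime reported for this kind of
test) and $\sigma_{fos} = 1.25$ so that, by default, the observer exactly
matches the ZEST likelihood and recovery properties are well-posed;
mismatch is one configuration change away. Behaviour on top of detection:
saccade latency ~ N(0.3 s, 0.05 s), per-saccade landing error (SD 0.5°),
50 Hz sampling with 2% dropout, viewing-distance random walk (SD 0.5
cm/trial, clamped to the tracker's 50–70 cm focal range). Unseen trials
hold fixation, except that with probability $fp$ an erroneous saccade goes
to a random trackable location.

What the generator does *not* emulate: physiological tracker noise spectra,
blink/pupil artefacts beyond random dropout, smooth pursuit, saccade
kinematics (streams jump from fixation to target at latency), fatigue and
learning effects, and media opacities. Passing tests therefore demonstrate
algorithmic correctness and statistical behaviour under a clean oculomotor
model — not robustness to every failure mode of real eye tracking.

## Session orchestration

`run_session()` draws trials uniformly at random from the active set
(current stage + unterminated blind spots). Each trial: a fixation-stability
gate (modelled as a per-trial instability probability, default 0.03), then
gaze-contingent placement with up to 3 refixation retries, presentation,
gaze-stream synthesis, classification, and a ZEST update *from the
classified outcome* — the estimator sees exactly what the classifier
delivers, misclassifications included. Catch trials are inserted with
probability 0.07 per trial (blank or maximal-luminance, 50/50, at test-trial
locations); they are tallied for the false-positive/false-negative
estimates and never touch a ZEST state. A location whose placement fails
repeatedly (default 10 abandoned attempts) is flagged `unmeasured` and the
session continues. Everything is reproducible bit-for-bit under the session
seed. Time is counted in trials, not minutes: wall-clock duration of the
physical test is hardware- and human-bound and deliberately out of scope.

```{r session}
obs <- sample_observer(seed = 42)
res <- run_session(obs, session_config(), seed = 42)
res
```

## Analysis layer

* `mean_sensitivity()`: mean of the 44 test locations (blind spots
  excluded).
* `bland_altman()`: test–retest agreement; the 95% coefficient of
  repeatability is defined as $1.96 \times$ sample SD of paired
  differences, and the limits of agreement as mean ± CoR₉₅.
* `bca_bootstrap_ci()`: bias-corrected and accelerated percentile
  bootstrap (default 20,000 resamples), hand-implemented: $z_0$ from the
  bootstrap CDF at the point estimate, acceleration from jackknife
  skewness; degenerate bootstrap distributions fall back to the plain
  percentile interval with a warning. Plain-vector input is sorted
  internally so the interval is exactly permutation-invariant.
* `cor_difference_test()`: the published description of the
  repeatability-difference test is only "a nonparametric bootstrap, similar
  in principle to a Mann–Whitney U test"; we reconstruct it as within-
  observer device-label exchange (each observer's run-pair swapped between
  devices with probability ½ under the null), two-sided, with +1
  smoothing so $p \in (0, 1]$. The resampling scheme is isolated in one
  function and replaceable.
* `pointwise_comparison()`: per-location paired t-tests at
  Bonferroni-corrected α (default 0.01 over the locations tested).
* `normative_table()`: per-location mean and 2.5th/97.5th percentiles,
  linear interpolation between order statistics (stated in the output
  metadata, since percentile conventions differ).
* `min_detectable_difference()`: central-t paired-design sensitivity,
  $(t_{1-\alpha/2,\,n-1} + t_{\mathrm{power},\,n-1})\,sd/\sqrt{n}$; power
  defaults to 0.80, which is the conventional assumption and reproduces
  the 0.55 dB figure for $n = 64$, $sd = 1.548$.

```{r analysis}
round(min_detectable_difference(64, 1.548, alpha = 0.05, power = 0.80), 2)
```

## Numerical choices and degenerate inputs

Ties in stimulus placement round toward the brighter (lower-dB) value. The
posterior is renormalised after every update and an all-zero posterior is
an error, not a silent reset. Estimates are clamped to the domain. An empty
gaze stream classifies as a miss with a `no_data` diagnostic. Error-rate
estimates with a zero denominator are `NA` (undefined), never 0. Config
files may be empty (all defaults); unknown keys are errors that name the
key.

## Problem sizes used by the test suite

The shipped tests run a single full session (~250 trials) for the
termination checks, 500 fast-path sessions for the recovery/bias check
(direct latent responses, isolating the thresholding layer; the gaze loop
is exercised end-to-end by its own tests), 40 full-gaze sessions for
catch-trial error-rate recovery, 1,000 null replicates at 2,000 resamples
for the repeatability-test type-I check, and 100 replications at 2,000
resamples for BCa coverage. These sizes are the package's own choices for a
suite that completes in a few minutes on one core; all of them scale up by
changing one constant.

## Known limitations

The growth-pattern grouping and the classifier's eccentricity model are
faithful-in-spirit reconstructions anchored to the published constants, not
the original supplementary formulas. The blind-spot prior constants and the
bimodal-prior mixture constants are conventions. The simulator's
repeatability (CoR₉₅ of MS ≈ 1 dB under defaults) sits below the ~2 dB
reported for human cohorts, as expected for an observer model without
fatigue, criterion drift or tracker failure; cohort-level human numbers are
sanity bands here, not reproduction targets.
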