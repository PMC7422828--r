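# gazeperim

Hardware-free simulation and analysis of **eye-movement threshold
perimetry**: visual field testing in which the observer responds to a
luminance increment not with a button press, but by looking at it, while a
remote eye tracker both places each stimulus relative to the current point
of fixation and scores the saccadic response.

The package is for vision scientists and methodologists who want to study
the *algorithmic* behaviour of such a test — threshold estimation accuracy,
termination, catch-trial error accounting, test–retest repeatability —
without hardware or participants. Everything runs against simulated
observers that generate synthetic 50 Hz gaze streams.

## What it implements

* **Decibel scale** — differential light sensitivity as attenuation,
  `DLS = 10 log10(ΔL_max / ΔL_jnd)` against a 225 cd/m² maximum increment
  on a 10 cd/m² background (0–34 dB working range), plus rescaling of
  clinical HFA values from their 3183.1 cd/m² pedestal onto the same scale
  (negative rescaled values clamp to 0).
* **Modified 24-2 grid** — the standard lattice minus its top and bottom
  rows: 46 locations = 44 test points + 2 blind-spot validity points at
  (15°, ±3°) in right-eye format; quadrant-seeded growth pattern; eye
  mirroring; generic subregion aggregation.
* **Tangent-screen geometry** — per-axis tangent projection between
  visual-field degrees and screen pixels (59.7 × 33.6 cm, 2560 × 1440 px,
  52.9° × 31.3° at 60 cm), gaze-relative placement, eccentricity warping
  that holds the Goldmann III stimulus at 0.43° on the retina, prohibited
  zones, placement validation.
* **ZEST** — Bayesian thresholding on the integer dB domain: bimodal prior,
  cumulative-Gaussian likelihood with fixed slope σ = 1.25 dB,
  posterior-mean stimulus placement, neighbour-seeded priors, dynamic
  termination at posterior SD ≤ 1.5 dB (with a presentation floor and cap).
* **Saccadic classifier** — hit iff ≥ N valid gaze samples fall in a
  D° × D° box around the target within R s of onset; N, D, R vary with
  eccentricity, anchored at (9°, 9°) → N = 6, D = 2.77, R = 1.62.
* **Simulated observers** — hill-of-vision thresholds, error-adjusted
  frequency-of-seeing responses `p = fp + (1 − fp − fn)·Φ((t − s)/σ)`,
  truly blind blind-spots, saccade latency and landing error, tracker
  dropout, viewing-distance drift, optional polygonal field defects.
* **Session runner** — growth-pattern scheduling, gaze-contingent
  placement with refixation trials, interleaved blank/suprathreshold catch
  trials (never entering threshold estimates), full reproducibility under a
  seed.
* **Analysis layer** — mean sensitivity (MS), Bland–Altman repeatability
  (CoR₉₅ = 1.96 × SD of paired differences), BCa bootstrap confidence
  intervals, a permutation bootstrap test for CoR differences between
  devices, Bonferroni-corrected pointwise comparisons, normative percentile
  tables, and paired-design minimum detectable difference.

## Worked example

```r
library(gazeperim)

obs <- sample_observer(seed = 42)          # one synthetic normal observer
res <- run_session(obs, session_config(), seed = 42)
res
#> Simulated perimetric test (right eye)
#>   mean sensitivity: 19.49 dB over 44 test locations
#>   trials: 183 test, 11 blank catch, 6 supra catch, 193 refixation
#>   catch-trial error rates: fp = 0, fn = 0
```

The mean sensitivity (19.49 dB) is the average of the 44 test-point
estimates; the two blind-spot points are excluded. Trial counts separate
real presentations from blank/suprathreshold catch probes (used only to
estimate false-positive and false-negative response rates — here 0/11 and
0/6) and from refixation events, where the target could not be validly
placed relative to the current fixation and gaze was recentred first.

Test–retest repeatability over a small cohort:

```r
cohort <- sample_cohort(6, seed = 1)
ms1 <- sapply(1:6, function(i) mean_sensitivity(run_session(cohort[[i]], session_config(), seed = 2 * i)))
ms2 <- sapply(1:6, function(i) mean_sensitivity(run_session(cohort[[i]], session_config(), seed = 2 * i + 1)))
bland_altman(ms1, ms2)
#> Bland-Altman repeatability (n = 6 pairs)
#>   mean difference: -0.258 dB
#>   CoR95: +/-0.954 dB
#>   95% limits of agreement: [-1.212, 0.697] dB
```

CoR₉₅ is the half-width of the limits of agreement: 95% of repeat tests on
the same observer are expected to differ by less than ~0.95 dB here.

Rescaling HFA decibels onto the package's scale, and the sensitivity of a
64-pair design:

```r
round(hfa_to_native_db(c(0, 20, 30)), 2)
#> [1]  0.00  8.49 18.49
round(min_detectable_difference(64, 1.548), 2)
#> [1] 0.55
```

## Command line

A thin CLI over the same functions lives in `inst/cli/gazeperim.R`:

```sh
Rscript inst/cli/gazeperim.R simulate --seed 1 --n-observers 4 --out out/
Rscript inst/cli/gazeperim.R analyze  --results out/ --out report/ --paired
Rscript inst/cli/gazeperim.R compare  --device-a a/ --device-b b/ --out cmp.json
Rscript inst/cli/gazeperim.R fixtures --seed 1 --out fixtures/
```

Outputs are CSV (pointwise results, trial logs, gaze logs) and JSON
(summaries with a provenance block: config hash, seed, package version).

## Further reading

The methods vignette (`vignettes/eye-movement-perimetry.Rmd`) documents the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic observers do and do not emulate, numerical conventions,
and known limitations.
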