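---
title: "Methods: trial-based analysis of shadow-evoked escape responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based analysis of shadow-evoked escape responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what the package computes

A single fly walks freely in a shallow linear tunnel (52 mm x 5 mm by
default) while a camera under the arena tracks its centroid at 100
frames/s. At pseudorandom intervals a passing overhead shadow — a
predator-mimicking stimulus — sweeps the arena for 2 s; a session contains
40 such trials separated by approximately exponentially distributed
inter-trial intervals with mean 52.2 s (floor 15 s), so the fly cannot
anticipate the next stimulus. Because the tunnel is too shallow for flight,
the behavioral repertoire reduces to four walking responses: freezing
(*stop*), *slow down*, *speed up* (running escape), and *no reaction*.

`shadowtrial` turns centroid tables plus a stimulus schedule into:

1. stimulus-aligned speed and acceleration traces (`compute_speed_series()`,
   `extract_trials()`);
2. a four-way threshold classification per trial with stop-duration
   measurement (`classify_trials()`, `measure_stop_duration()`);
3. an exploratory PCA + Ward-clustering view of the same trials
   (`fit_response_pca()`, `cluster_trials()`);
4. speed-conditioned response-probability curves and a speed-matched
   Monte-Carlo "virtual fly" null model (`build_curve()`,
   `simulate_virtual_cohort()`, `test_prediction()`);
5. the group-level statistics used for genotype and age comparisons
   (`compare_groups()`, `dispersion_permutation_test()`,
   `age_trend_analysis()`).

A synthetic-trajectory generator (`generate_fly_session()`,
`generate_cohort()`) with full ground truth validates every stage.

## Kinematics

Per-frame speed is the Euclidean centroid displacement between consecutive
frames divided by the frame interval, averaged onto a fixed 10 ms grid.
Each trial is the window from 0.2 s before to 1.0 s after shadow onset
(120 bins); the pre-stimulus window is half-open, `[-0.2, 0)` s, so the
onset bin belongs to the post-window. The baseline `v_pre` is the mean
speed over the pre-window, and normalized speed is `speed - v_pre`, which
makes normalization idempotent and gives the pre-window exactly zero mean.

Short tracking dropouts (up to 3 frames) are linearly interpolated — they
are tracker noise, and differencing across them would fabricate speed
spikes. Longer gaps invalidate every overlapping trial: kinematics across
them are meaningless. Invalid trials are labeled unscored and excluded from
profiles, but never silently dropped from the count of attempted trials.

Acceleration is the central finite difference of binned speed (a scalar;
its sign distinguishes speeding up from slowing down). A version smoothed
with a centered 100 ms moving average (window shrinking at the trace edges
so the full 1 s post-window stays scored) is stored alongside the
10 ms-resolution version in every trial trace.

### At which time scale the 200 mm/s² threshold must act

A reaction counts as robust only if |acceleration| reaches 200 mm/s² in the
post-window. A basic scale argument fixes the resolution at which this
threshold can be applied. Any acceleration estimate averaged over a window
of length $T$ is bounded by $\Delta v / T$, where $\Delta v$ is the net
speed change inside the window. For a *complete stop* the available
$\Delta v$ is at most `v_pre`, so a 100 ms average can never exceed
`v_pre / 0.1 s`: a fly stopping dead from 12 mm/s peaks at 120 mm/s² on
that scale, and no stop from below 20 mm/s could ever pass a 200 mm/s²
criterion. Since freezing responses are in fact concentrated at ordinary
walking speeds (roughly 5–13 mm/s), the threshold is applied to the
acceleration at its native 10 ms resolution (`accel_source = "raw"`, the
default), where an abrupt stop from `v_pre` registers up to
`v_pre / 0.02 s`. The 100 ms-smoothed trace remains available for
characterization and via `accel_source = "smoothed"`.

The same bound shapes what speed-dependent responses are *detectable at
all*: a stop from below 4 mm/s cannot reach 200 mm/s² even at 10 ms
resolution ($\Delta v / 0.02 < 200$). The generator's default response
curve therefore places zero stop/slow probability below 4 mm/s — which
also matches the behavioral observation that running and no-reaction
dominate at low speeds.

## The classifier

For each valid trial, with threshold 200 mm/s² and stationarity floor
`v_zero`:

- no crossing of the threshold in `(0, 1]` s → **no reaction**;
- first crossing positive → **speed up** (possible from rest);
- first crossing negative and `v_pre > v_zero`: **stop** if speed reaches
  `v_zero` before the first subsequent positive crossing (or window end),
  otherwise **slow down**;
- first crossing negative with `v_pre <= v_zero` → remapped to
  **no reaction**: a stationary fly cannot meaningfully decelerate, so such
  crossings are noise.

Every valid trial receives exactly one label. `v_zero = 0.5 mm/s` is the
operational meaning of "zero speed" under centroid noise — exact zeros are
unattainable from real tracking — and is the single most sensitive
constant in the pipeline; it is configurable and shared consistently by
the classifier, the stop-duration estimator and the stationary speed bin.

**Stop duration** is measured in the full-session speed series, not the
1 s window, because freezes frequently outlast the window: from the first
post-onset bin at or below `v_zero` to the first later bin above `v_zero`
sustained for at least 50 ms (so single noisy bins do not end a stop),
capped at the next trial onset with a right-censoring flag.

## Exploratory response typing

PCA is fit to the normalized post-stimulus speed traces (100 bins,
mean-centered) and the first three components are retained; agglomerative
clustering (Ward linkage on Euclidean distances, cut at k = 4 by default)
groups trials into response archetypes. Linkage, metric and k are
conventions chosen for compact clusters matching the four types, not
results; the clustering is a qualitative cross-check of the threshold
classifier. Note an intrinsic limit: normalization removes absolute speed,
so a stop from 5 mm/s and a slow-down from 12 mm/s can produce similar
normalized traces — cluster boundaries therefore blur exactly where the
threshold rules discriminate, which is why the thresholds, not the
clusters, define the group comparisons.

## Speed conditioning and the virtual-fly null

`build_curve()` bins `v_pre` (default: a dedicated stationary bin
`[0, v_zero)`, 2 mm/s bins to 20 mm/s, one overflow bin) and tabulates
label frequencies per bin — the *outer model*. The stationary bin can
carry no stop/slow mass by the classifier's preconditions. Empty bins are
flagged, never imputed.

`simulate_virtual_cohort()` is the *inner model*: each of `n_virtual`
(default 3000) virtual flies draws a speed by resampling the genotype's
empirical `v_pre` values with replacement (no parametric fit) and then a
label from the curve at that speed. `test_prediction()` compares observed
and virtual label counts with a Pearson chi-square (df = labels − 1). If
the virtual counts match the observations, the genotype's response
distribution is explained by its baseline speed alone; a significant
result implicates behavioral differences beyond speed.

Two chi-square forms are provided. The default (`"expected"`) scales the
virtual proportions to the observed total and treats them as the
expectation. Two opposing finite-sample effects act on it: treating an
estimated expectation as exact inflates the statistic (the virtual cohort
is finite), while speed-matching the virtual flies to the very trials
being tested positively correlates observed and expected counts, deflating
it. At the default `n_virtual = 3000` these nearly cancel, and the
package's calibration tests (1000-replicate self-consistency simulations,
where the tested genotype truly follows the pooled curve) verify a
rejection rate within [0.03, 0.07] at nominal 0.05. The `"sample"` option
is a 2 x k homogeneity test treating both vectors as samples; under speed
matching it is conservative.

## Group statistics

- `compare_groups()`: two-sided Mann-Whitney U (exact enumeration for
  small tie-free samples via `stats::wilcox.test`, tie-corrected normal
  approximation otherwise). The single-number percent change is computed
  on group *means* of per-fly values by default (`basis = "median"`
  available): published single-percentage effects rarely state their
  basis, and this choice is the main reproduction risk when matching them.
- `dispersion_permutation_test()`: statistic `|log(var_A / var_B)|` after
  centering each group at its median, so location shifts do not masquerade
  as dispersion differences; the statistic is scale-free. The p-value uses
  random relabeling with the add-one correction
  `(1 + #{permuted >= observed}) / (n_perm + 1)`, which keeps it valid at
  any permutation count.
- `age_trend_analysis()`: two-way ANOVA (genotype x age group, with
  interaction) on per-fly response proportions — reasonably robust to
  non-normality — cross-checked by per-genotype Kruskal-Wallis tests, with
  Mann-Whitney post-hocs restricted to adjacent age pairs. Post-hoc p
  values are reported uncorrected and the result object carries the note
  to interpret them at p = 0.01, since no straightforward multiplicity
  correction applies to this family.

## The synthetic-data generator

The generator is the ground-truth instrument for the whole pipeline, so
its design choices matter:

- **Locomotion**: a two-state (walk/pause) semi-Markov process with
  exponential bout durations; the long-run stationary fraction is
  `pause_probability` (default 0.25, walk-bout mean 3 s). Walking speed is
  drawn per bout from a log-normal (median 9 mm/s, sdlog 0.35) with a
  small AR(1) within-bout fluctuation (SD 0.3 mm/s, 0.2 s correlation
  time). This is the simplest model reproducing the bimodal
  (zero-vs-moving) speed structure the classifier assumes.
- **Voluntary vs evoked transitions**: spontaneous bout edges ramp at
  60 mm/s², below threshold, so they are never scored as reactions;
  response motifs ramp at 800 mm/s² (well above it). Spontaneous
  transitions are deferred out of a guard window around each onset
  (−0.25 s to +1.5 s) so every trial has a well-defined pre-stimulus state
  and an uncontaminated response window — without the guard, a voluntary
  pause landing inside the post-window would be indistinguishable from an
  evoked stop for *any* classifier, making ground-truth labels ill-defined.
- **Tunnel confinement**: the fly runs along the tunnel axis and reverses
  at the ends via constant-speed semicircular U-turns (radius 1.5 mm, as
  the 5 mm width allows). A mirror-reflection at a wall would compress one
  frame's displacement and produce a single-bin speed dip that the
  10 ms-resolution acceleration scores as a spurious 200+ mm/s² event;
  arc turns keep centroid speed continuous through the reversal.
- **Tracking noise**: AR(1)-correlated Gaussian centroid jitter per
  coordinate, marginal SD 0.05 mm, correlation time 10 s. The correlation
  is essential, not cosmetic: white per-frame noise of SD $\sigma$ adds a
  phantom speed floor of roughly $\sigma\sqrt{2}\sqrt{\pi/2}/\Delta t$
  (about 9 mm/s at 0.05 mm and 100 frames/s) to a stationary fly, which
  contradicts the plainly observable zero-speed pauses in real tracking.
  Deterministic blob-centroid error is in fact dominated by slowly varying
  segmentation bias (posture, illumination), which the AR(1) model
  captures; under it a stationary fly reads ≈ 0.3 mm/s, safely below
  `v_zero`.
- **Responses**: at each onset the generator measures true `v_pre`, draws
  a label from the genotype's response curve at that speed, and injects
  the motif after a drawn latency (default 80 ± 10 ms): decelerate to zero
  and hold for a log-normal stop duration (median 0.5 s, clipped to
  [0.25, 3] s); decelerate to `max(1.5, 0.25 v)` mm/s; accelerate by
  `max(8, 0.8 v)` mm/s; or nothing. Recovery motifs rejoin the ongoing
  baseline at the gentle 60 mm/s² rate.

What the generator does **not** emulate: realistic gait and body
orientation, heading-dependent responses, jumping or flight (physically
excluded by the tunnel), multi-fly interactions, habituation or
sensitization across trials, and non-Gaussian tracker artifacts (identity
swaps, reflections). Passing tests on synthetic data therefore validate
the *computational* pipeline — alignment, thresholds, probability
estimation, statistics — not the biological realism of any particular
constant.

## Numerical conventions

- Bin grids are fixed and anchored at session start; identical input gives
  identical traces.
- The moving-average window shrinks symmetrically at the edges rather than
  padding, keeping the full post-window scored.
- Degenerate statistical inputs are handled explicitly: all-tied samples
  give p = 1 with a warning; zero variance in both dispersion groups gives
  p = 1; constant ANOVA responses give F = 0, p = 1 with a warning rather
  than 0/0.
- All randomness flows through explicit seeds; cohort generation spawns
  per-fly child seeds deterministically (`derive_seed()`), and every seed
  is recorded in the cohort manifest.

## Problem sizes used by the validation suite

The test suite works at sizes chosen to make binomial/Monte-Carlo error
small relative to the margins being asserted: 10,000 simulated schedules
for the inter-trial-interval mean; cohorts of 10 flies x 40 trials
(noise-free and default-jitter) for label and stop-duration recovery;
10,000 randomized traces for the exhaustiveness/stationarity properties;
1000 replicates for the chi-square and permutation type-I calibrations
(at 500 observed trials and 3000 virtual flies per replicate); 200
replicates for dispersion power at a tenfold variance ratio; and cohorts
of 20 flies per genotype for end-to-end planted-effect recovery.

## Known limitations

- `v_zero` and the 200 mm/s² threshold are operational constants; group
  comparisons are meaningful under a fixed configuration, and sensitivity
  to `v_zero` should be checked when porting to a different tracker.
- Stop durations are right-censored at the next onset; their group
  comparisons treat censored values as observed durations (censoring is
  flagged so survival-style analyses can be applied externally).
- The percent-change basis (means of per-fly values) is a convention;
  median-based changes can differ appreciably for skewed metrics such as
  stop duration.
- Clustering results depend on linkage/metric conventions and are
  intentionally not used for quantitative group claims.
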