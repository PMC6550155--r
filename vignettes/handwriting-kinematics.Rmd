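---
title: "Handwriting kinematics and dysgraphia screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting kinematics and dysgraphia screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphokin)
```

## The problem and the data model

Human handwriting scales score the written *product*; a digitizer tablet
additionally records the *process*: for every sample, time, pen position,
normalized pressure, the two pen inclination angles (tilt-x along the
written line, tilt-y below it, each in [−60°, 60°]), and whether the pen
tip touched the surface. `graphokin` models such a recording as a
time-ordered data frame (`recording()`) with strictly increasing
timestamps. Hover samples are kept in the stream — the in-air time ratio
and word segmentation need them — and a *stroke* is a maximal contiguous
run of on-surface samples.

Two conventions are enforced at the boundary and nowhere else: pressure is
already normalized to [0, 1] (cross-device calibration is an acquisition
concern), and x grows along the writing direction while y grows downward
(a `flip_y` switch at load covers bottom-up devices). Irregular sampling
is tolerated: every time computation uses actual timestamps; the nominal
sampling rate only builds spectral frequency axes.

## The spectral engine

All frequency-domain features share one pipeline (`mean_power_spectrum()`):

1. split the signal into consecutive, non-overlapping packets of
   `packet_size` samples (default 600) and discard the remainder;
2. remove each packet's mean (a rectangular window; a Hann option exists
   but is off by default, staying closest to the plain description of the
   procedure);
3. take `|DFT|²` at the non-negative frequencies;
4. average across packets and normalize the averaged power to unit sum.

Discarding the remainder keeps every packet on an identical frequency
axis so averaging is well defined. Unit-sum normalization makes spectra
comparable across writers of different amplitude — all spectral features
are therefore invariant to signal rescaling, which the tests verify.

Three summaries reduce a spectrum:

* **bandwidth** — the width of the central interval holding `coverage`
  (default 90 %) of total power, with symmetric 5 % tails. Quantiles are
  discrete: the q-quantile is the smallest bin frequency at which
  cumulative power reaches q. Other readings of a "90 % range" exist
  (smallest covering interval, [0, 90th percentile]); the symmetric-tails
  rule was chosen because it is the standard definition of a central
  coverage interval and reduces to 0 for a single-bin spectrum.
* **median** — the 50 % quantile under the same rule.
* **distance to mean** — the Euclidean (L2) distance between two
  normalized power vectors on a shared axis. No resampling is attempted
  on mismatched axes; a mismatch is a contract error.

The reference for distance features (`cohort_reference()`) is the
element-wise mean of the training cohort's spectra, re-normalized.
Computing it from training recordings only is a hard rule: the evaluation
protocol rebuilds it per split (see below).

For short recordings the configured packet may not fit the derived
series. Rather than dropping the whole spectral family, the packet
shrinks to the largest power of two that fits, never below 128 samples;
recordings too short even for that get `NA` for the family. When a cohort
is processed together, one packet size per family is chosen from the
shortest usable series so that all writers share one axis and distances
remain defined.

## The tremor signal

Within each stroke, consecutive windows of 10 on-surface points yield 9
local difference vectors $d_i$ and their mean $g$, the window's "global"
direction. The emitted value per local vector is $|d_i \times g|$ (the
magnitude of the z-component of the cross product): zero for collinear
motion, large when the pen deviates sharply from its local direction of
travel. Windows never straddle stroke boundaries — a pen lift would
fabricate one giant vector — and remainder points at stroke ends are
skipped. The series is bilinear in its inputs, hence translation- and
rotation-invariant and exactly linear in the amplitude of an injected
perpendicular perturbation; the tests exploit all three properties.

One property worth stating plainly: the windowed construction imprints
deterministic structure at the window rate (sampling rate/10 = 20 Hz) and
its mixing products, and the magnitude operation rectifies oscillations,
so the spectral *median* of this signal does not track an injected tremor
frequency. The spectrum still responds strongly to tremor — its
*bandwidth* grows with tremor amplitude, broadband fraction and injected
frequency — which is what the downstream features rely on.

## Static features

* **Space between words** — words are strokes merged unless separated by
  a pen-up interval > 0.15 s *and* a horizontal bounding-box gap > 40
  device units (both must hold, so i-dots and accents stay attached).
  Gaps between consecutive words on a line are pooled; the feature is the
  natural log of the mean gap ("logged" read as a log transform of the
  feature, not as "recorded"), plus the raw population SD of gaps as a
  spacing-irregularity measure.
* **Density** — mean on-surface sample count over the non-empty cells of
  a 300-unit square grid anchored at the trace bounding box ("300-pixel
  cells" read as side length, not area; configurable).
* **Moment** — per line, barycenters of consecutive 300-point bins; mean
  |Δy| between consecutive barycenters, weighted across lines by their
  number of barycenter pairs. A horizontal baseline scores 0.
* **Size** — mean bounding-box area of consecutive 300-point bins.
* **Tremor bandwidth / median / distance** — the spectral summaries of
  the tremor signal at the raw sampling rate, packet size 600.

Line segmentation is the artifact's own: a new line starts when a
stroke's left edge retreats by more than half the running line width
while its vertical centroid drops by more than the running median stroke
height. Features are extracted over the whole recording (no restriction
to the first sentences of a copy task).

## Kinematic, pressure and tilt features

A shared engine smooths the raw channel with a moving average (n = 10),
keeps every 10th point (20 Hz effective at a 200-Hz tablet), and
differences consecutive retained points. A measurement is kept only when
the pen stayed on the surface for every raw sample it spans. Speed is
`‖Δ(x,y)‖/Δt`; channel change speed is `|Δc|/Δt` in 1/s (pressure) or
deg/s (tilt). The change-speed formula is deliberately value-over-time —
the only reading whose units (deg/s) match how these features are used —
and unsigned, since the features describe variability, not direction.
Tilt features use on-surface samples only: hover tilt is unreliable
across devices.

Each derived series is summarized by mean, max and **population** SD (a
deliberate, documented choice applied uniformly), an OLS slope of value
against time (the "evolution over time" features, including those of the
tilt-change series), Gaussian-smoothed strict local extrema per second,
and the three spectral summaries at the effective rate. `peak_sigma` is
specified in seconds (default 0.25 s) rather than samples so results
survive resampling; 0.25 s suppresses sensor noise while preserving
writing saccades. Extrema counts are normalized by on-surface writing
time for every series, including speed, for consistency. Acceleration is
the finite-difference |Δv|/Δt of the speed series.

The assembled vector (`feature_names()`) has 52 named entries: 8 static,
12 kinematic, 10 pressure, 22 tilt. Published feature banks of this kind
quote between 51 and 53 items depending on counting conventions; this
package documents exactly the 52 it computes. Missing
features are `NA`, never imputed.

## Evaluation protocol

`evaluate_cohort()` runs k = 25 independent stratified shuffle-splits:
70 % of each class trains a 100-tree Random Forest, the held-out 30 % is
scored at a 0.5 vote threshold, and per-repeat F1, sensitivity,
specificity and FPR are reported with means and SDs. Repeated
shuffle-splits (rather than disjoint folds) are the only protocol under
which "a 70/30 split" and "k = 25 validation with a mean and SD of F1"
are simultaneously coherent; a plain stratified k-fold mode is available
via `cv_config(mode = "kfold")`. No class weighting or resampling is
applied to the 242/56-style imbalance, mirroring common practice of
reporting F1 instead. Forest hyperparameters beyond tree count are the
`randomForest` defaults (unlimited depth, √p features per split).

Rows with missing required features are excluded *before* splitting, with
a logged count — exclusion is part of the protocol, not of any one split.
Per repeat, the cohort reference spectra are rebuilt from that repeat's
training rows only and the five distance features are recomputed from the
stored per-recording spectra, so test-set information never enters the
reference; the tests verify the recomputation against hand-built subset
references. Gini importances are normalized to sum to one within each
repeat, then averaged; whether to refit on all data instead was an open
choice, and per-repeat training forests were kept because they match the
reported mean ± SD structure. Everything is driven by one integer seed
(splits and forests draw from deterministic per-repeat streams), so
reports are bit-stable.

`robustness_curve()` truncates every recording to each requested
duration, re-extracts (packet sizes shrink as described), and re-runs the
protocol — the "how many seconds of writing are enough" curve.

## The simulator

`generate_trace()` is a test harness, not a model of children's motor
control. Letters are sinusoidal loops advanced left to right at a speed
modulated by a piecewise-constant multiplicative saccade process; words
are separated by in-air hovers realizing a target gap width and in-air
fraction; lines end with a carriage-return hover. Tremor is a narrowband
sinusoid plus smoothed broadband noise scaled by an amplitude; pressure
and tilt are clipped sinusoid-plus-noise processes. Every generated
recording passes `validate_recording()`, and every knob moves its matched
feature monotonically (verified by sweep tests).

`default_profiles()` encodes the documented TD/D contrasts: relative to
TD, the D profile has stronger and more broadband tremor, a more saccadic
and slower speed process, smaller and more variable word gaps, more
in-air time, slower tilt-y change, and broadband tilt-x jitter. With the
default per-writer spread (10 % lognormal jitter), the manipulated axes
separate by roughly 2 pooled SD or more — deliberately clean, so
classification tests are stable at desk scale; `effect = 0.25` gives a
~0.5-SD "hard" preset. Per-writer random streams derive from the cohort
seed within each group separately, so growing one group never perturbs
the other's writers.

What the simulator does *not* emulate: real letterforms and languages,
age- or grade-dependent maturation, fatigue drift, digitizer quantization
and frame drops, or correlated multi-channel pathology. Passing tests on
simulated cohorts therefore demonstrates that the pipeline measures what
it claims and that the protocol separates groups whose traces differ in
the documented directions — not that any particular clinical accuracy
would be attained on real children.

## Numerical choices and degenerate inputs

* Constant (zero-power) signals are rejected by the spectral engine
  rather than silently normalized.
* A truncation that leaves fewer than two samples is an error; truncation
  is idempotent.
* Strict inequalities define local extrema; heavier Gaussian smoothing
  can only merge extrema (tested as a monotone property).
* Discrete quantiles use a 1e−12 cumulative-sum guard against
  floating-point shortfall at bin boundaries.
* Word/line thresholds, grid and bin sizes, packet sizes and the peak
  sigma are all surfaced in `static_config()` / `dynamics_config()` /
  `spectral_config()` and round-trip through the YAML config
  (`run_config()`, `write_config()`, `read_config()`).

## Problem sizes used by the test-suite

The acceptance-style tests run the full protocol on a simulated
242 TD / 56 D cohort of 300-s recordings (the reference population
shape), direction-recovery checks on 40 + 40 writers, and plumbing tests
on smaller, shorter cohorts; the whole suite completes in a few minutes
on one CPU. These sizes are the package's own validation choices and can
be scaled up freely via `cohort_spec()`.

## Known limitations

* The tremor-spectrum median is dominated by window-rate structure (see
  above); bandwidth and distance carry the discriminative load.
* Line segmentation assumes left-to-right writing with carriage returns;
  boustrophedon or vertical scripts would need a different segmenter.
* The simulator's group contrasts are axis-aligned and independent across
  writers; real cohorts correlate features in ways the Random Forest may
  exploit differently.
* With the clearly-separable default profiles the synthetic evaluation
  saturates (F1 ≈ 1); use the hard preset to study protocol variance.
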