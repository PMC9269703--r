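---
title: "Methods: movement complexity and classification for instrumented trunk bending tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement complexity and classification for instrumented trunk bending tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bendr)
```

## The measurement and the data model

The package analyses a repetitive trunk bending-and-return (b&r) test:
standing participants bend forward to touch a target, return upright, and
repeat continuously for 70 s. Three inertial measurement units record the
movement at 100 Hz — SENS1 over the twelfth thoracic vertebra, SENS2 over
the second sacral vertebra, SENS3 on the lateral thigh — each with a
triaxial accelerometer (`Acc X/Y/Z`, g) and gyroscope (`Gyr X/Y/Z`,
deg/s). For SENS1 and SENS2, `Gyr Y` is the sagittal (flexion) axis;
SENS3 is mounted rotated, so its `-Gyr Z` plays that role.

A `br_recording` is a wide tibble (one row per sample, one column per
channel) with subject, group and sampling-rate metadata. Text I/O is
plain delimited files with a column map, because sensor deposits differ
only in column naming; full `%.17g` precision makes write/read round
trips bit-exact. The first 10 s are treated as warm-up and discarded;
with the 70 s cap this leaves the N = 6000-sample analysis window all
entropy computations assume. Recordings shorter than 70 s are rejected
rather than padded, mirroring the protocol's exclusion of aborted tests.

Two derived channel families are available: angular acceleration
(`AccA`), by central differences with one-sided stencils at the ends
(length-preserving, no invented samples), and drift-corrected angle
(`AngC`), by cumulative trapezoidal integration followed by subtraction
of the least-squares line fitted over the whole analysis window. The
drift line depends on the window by construction, so derived angles are
computed after trimming in the pipeline; angular acceleration commutes
with trimming except within the two-sample stencil at the edges.

## Sample Entropy

`sample_entropy()` implements SampEn(m, r, N) = −ln(A/B): B counts
pairs of length-m template vectors whose Chebyshev distance is ≤ r, A
the same for length-(m+1) vectors, with self-matches excluded and both
template sets containing N − m vectors. Defaults m = 2 and r = 0.2·SD
follow the standard parameterization for kinematic series. Conventions
the literature leaves open are fixed and exposed as options: template
count `"n-m"` vs `"n-m-1"`, and `<=` vs `<` for the tolerance. The SD
uses the n−1 denominator; since r tracks the SD of the series itself,
SampEn is exactly invariant under affine transforms, so the choice of
units (g vs m/s², deg vs rad) cannot affect results — asserted in tests.

Degenerate cases are defined, not avoided: a constant series has r = 0
and all templates still match (distance 0 ≤ 0), giving SampEn exactly 0;
when no (m+1)-pair matches, the result is flagged undefined and
propagates as a missing value rather than as 0 or infinity, which would
silently bias group statistics. The O(N²) pair count is compiled (Rcpp)
with early abandoning; a deliberately naive pure-R double-loop oracle
(`sample_entropy_bruteforce()`) restates the definition and the test
suite requires exact integer agreement of A and B between the two on
hundreds of random series.

One numerical fact worth knowing: a *perfect* sinusoid at the task's
cycle frequency, sampled at 100 Hz with m = 2 and r = 0.2·SD, has SampEn
≈ 0.11, not 0 — near the extrema, templates lie within the tolerance of
time-reversed copies and diverge on extension. "Nearly periodic" series
therefore bottom out around 0.1 at these parameters; values below 0.05
are unreachable for smooth 0.7 Hz signals.

The complexity factors condense the lumbo-pelvic-hip coordination into
two numbers: LCF = SampEn(Gyr Y SENS1 − Gyr Y SENS2) (lumbar flexion
complexity) and HCF = SampEn(−Gyr Z SENS3 − Gyr Y SENS2) (hip flexion
complexity), each with r taken from the difference series' own SD.

## Cycle segmentation

Cycles are found on Acc Z of SENS1, whose gravity projection dips once
per cycle at deep flexion: (1) smooth with a 25-sample (0.25 s) rolling
centered mean — the window shrinks symmetrically at the edges, no
padding; (2) threshold at the global minimum plus 40% of the global
amplitude of the *smoothed* series; (3) keep contiguous runs strictly
below the threshold, which protects against shallow local minima above
it; (4) one minimum per run (argmin, earliest on ties).

The successive deep-flexion minima delimit the cycles: k minima give
k − 1 cycles, matching both the observed cycle rate (~42 per 60 s at a
1.43 s period) and the bookkeeping of the cycle dataset. The mid-cycle
markers — the average position of two consecutive minima, rounded to the
nearest sample with .5 ties toward the earlier sample — correspond to
the upright instants and are returned alongside (`midpoints` attribute).
We chose minima as the cycle delimiters because the amplitude-gated
minimum is the sharply defined event; the midpoint markers inherit
whatever jitter both neighbouring minima carry. Samples before the first
minimum and after the last are partial cycles and are discarded. Because
the threshold is amplitude-relative, segmentation is invariant to adding
a constant and to positive rescaling.

Every channel is then cut with the same limits and each cycle resampled
to exactly 450 points by linear interpolation over its own duration
(`itime` = normalized within-cycle time). 450 is kept as a fixed default
rather than recomputed per dataset, so cycle datasets from different
cohorts align; it is overridable. Cycles shorter than 2 samples are
skipped with a warning. `mean_cycle()` summarizes a channel as pointwise
mean and SD across cycles (SD defined as 0 for a single cycle).

## Features and group statistics

Seven describers per channel — max, min, mean, median, Q1, Q3, SD, with
quartiles by linear interpolation between order statistics (the common
default in mainstream numeric stacks) — yield 6 channels × 3 sensors ×
7 = 126 raw features per participant (whole-sequence mode) or per cycle
(cycle mode). Derived channels are excluded from the default feature set
(the reported analyses reference only recorded channels) but can be
switched in. SampEn-per-channel (18 features) and the two complexity
factors are separate feature sets so their added value can be assessed
against the raw describers.

Group comparison follows the test-selection protocol used for the
entropy outcomes: Shapiro-Wilk on each group; if both pass at α = 0.05,
a pooled-variance two-sample t-test with mean/SD/SEM descriptives,
otherwise Mann-Whitney with median/quartiles. Tests are two-sided.
Because the study design matched each patient to a healthy subject, the
between-group difference block is computed from per-matched-pair
differences; from the difference SD, `difference_metrics()` returns
SEM = SD/√N, the 95% CI half-width 1.96·SEM, and the minimal detectable
change MDC = 1.96·√2·SEM. The 1.96 normal quantile (not a t quantile) is
used because that is the convention of the reliability literature these
quantities come from; MDC/CI = √2 identically.

## The classifier benchmark

Seven algorithms are benchmarked: brute-force KNN, linear SVM, RBF SVM,
decision tree, random forest, AdaBoost and Gaussian naive Bayes. Their
hyperparameter grids and default selections are the study's
(`default_classifier_specs()`); `grid_search()` re-selects by
cross-validated accuracy with ties broken toward the first-listed
candidate, run once on the full table (a nested per-fold search is
trivially possible by calling it inside a loop, but a single selection
is what a single set of chosen values implies). SVMs come from libsvm
(e1071), trees from rpart, forests from ranger (which exposes the
maximum-depth hyperparameter the grid requires). KNN (with distance
weighting and class-probability votes), Gaussian naive Bayes (with the
variance-smoothing ratio) and AdaBoost (discrete SAMME over depth-1
stumps) are implemented in the package, since no installed library
exposes those exact hyperparameters. Two mapping notes: rpart has no
random-split strategy, so both split-strategy candidates use exhaustive
best-split search, and its maximum depth caps at 30, so the depth-100
candidate fits at 30 (unconstraining at these sample sizes).

The evaluation protocol is 5-fold stratified cross-validation repeated
100 times: each repetition reshuffles rows with a repetition-specific
seed derived from the base seed, per-feature standardization is fitted
on the training folds only and applied to the held-out fold, accuracy
and AUC are pooled over the repetition's held-out predictions, and means
± SDs are taken over repetitions. AUC uses the rank (Mann-Whitney)
formula on class probabilities where available and decision values for
SVMs. The whole benchmark is bit-reproducible given the protocol seed.
The fold count is configurable (5 is the conventional choice at n = 40);
so is the grouping: `rowwise` treats every row as independent — the
apparent historical protocol for cycle-level rows — while `subjectwise`
keeps all cycles of a subject in the same fold. Row-wise splitting of
cycle data lets a classifier memorize subjects (a test demonstrates
near-perfect "accuracy" on label-free data that way), so subject-wise
splitting is what we recommend for cycle mode; both remain available
because comparability with published cycle-level numbers requires the
row-wise option.

Sequential feature selection (`sfs_rank()`) wraps the same CV accuracy:
forward selection greedily adds the best feature; backward elimination
drops the least harmful feature until one survives, ranking features by
survival. One run per algorithm × repetition (7 × 100 = 700 runs at the
defaults) tallies each feature's first- and second-place finishes;
first-place counts sum to the number of runs by construction. Within a
run, all candidate subsets share one fold assignment so comparisons are
paired.

## The synthetic cohort generator

`generate_subject()` simulates the b&r signal family the analysis
assumes, with analytic ground truth. The trunk angle is a train of
smooth excursions (a difference of raised cosines peaking at deep
flexion mid-cycle, with a second-harmonic skew that places peak velocity
early in flexion), with period jitter (mean 1.43 s, SD 0.15 s — about 42
cycles per 60 s window) and small (4% CV) excursion jitter: the
excursion is anchored by the physical target, so its variability is much
smaller than the timing's. The pelvis and thigh see scaled (0.55, 0.30),
slightly lagged (60, 100 ms) copies of the movement; gyroscopes record
the angular velocities, accelerometers gravity projections of the angles
(so Acc Z of SENS1 dips once per cycle), plus structured noise.

Complexity is controlled by noise *colour*, not level: all perturbations
are variance mixtures of white noise and an AR(1) process (φ = 0.95),
and the white fraction is the group's complexity weight (healthy 0.8,
patients 0.25, each with 0.1 between-subject SD so that within-group
entropy varies between subjects, as observed cohorts do). Noise SDs scale with the subject's movement amplitude so
the noise-to-signal ratio is group-independent — otherwise the smaller
patient amplitudes would raise their relative noise and *increase* their
entropy, inverting the intended contrast. The flexion-axis gyroscope
channels share a common-mode noise component (trunk micro-adjustments
seen coherently by all sensors) that partially cancels in the
sensor-difference series, keeping LCF/HCF in the empirically plausible
0.1–0.7 band. Group presets: healthy peak flexion velocity 190 ± 25
deg/s between subjects, patients 140 ± 25 — encoding the lower and less
complex patient movement. A 5 s amplitude ramp emulates the warm-up and
is removed by trimming.

What the generator does *not* emulate: sensor-fusion artefacts,
magnetometer channels, gravity/linear-acceleration mixing during fast
movement, fatigue drift within the minute, and any biomechanical
coupling beyond fixed ratios and lags. Passing the pipeline's tests on
synthetic cohorts therefore demonstrates that the chain of operations is
correct and well-calibrated under the assumed signal family, not that
the clinical effect sizes are reproduced on real recordings; real-data
runs require the original deposit, which the text reader accepts
directly.

## Numerical choices and problem sizes

Rounding of cycle-limit midpoints: nearest sample, .5 toward the earlier
sample. Argmin ties in a below-threshold run: earliest sample. Grid and
SFS ties: first-listed candidate. Scaling of constant features: SD
treated as 1 to avoid division by zero. Undefined SampEn: missing value;
rows with missing features are dropped (with a warning) before
classification. All randomness flows from one base seed; repetition r
uses seed + r, and per-subject generator seeds derive from the cohort
seed, so every result in the package is exactly reproducible.

The shipped tests and the acceptance script run the full study geometry
where it matters — N = 6000 samples, n = 20 + 20 subjects, 5-fold CV
with 100 repetitions, 700 SFS runs (on a compact 10-feature planted
fixture) — and reduced sizes (fewer repetitions, shorter recordings)
for unit-level checks; each test states its sizes inline.

## Known limitations

Backward SFS on the full 126-feature table is quadratic in features per
run and is practical for ranking studies, not for the 700-run tally at
full width; the planted-feature analyses use compact tables. The
Mann-Whitney branch reports an asymptotic p-value (exact enumeration
adds nothing at n = 20 with ties possible). The generator's group
contrast is encoded in amplitude and noise colour only; features outside
the flexion axis carry weaker, incidental contrast. Accelerometer units
are carried as metadata and never converted; mixed-unit cohorts are the
caller's responsibility.
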