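# bendr

Movement-complexity and classification analysis of instrumented trunk
**b**ending-and-**r**eturn tests.

Chronic low back pain (CLBP) changes *how* people move, not just how
far or how fast: patients tend toward slower, more stereotyped trunk
movements. `bendr` implements a complete analysis pipeline for a simple
clinical test that probes this — one minute of continuous trunk
bending (flexion to touch a target) and return to standing, recorded by
three inertial measurement units at 100 Hz: SENS1 at T12, SENS2 at S2,
SENS3 on the lateral thigh, each with a triaxial accelerometer
(Acc X/Y/Z) and gyroscope (Gyr X/Y/Z). It is aimed at movement
scientists and clinician-researchers working with wearable-sensor
kinematics.

The pipeline covers:

* **Preprocessing** — delimited-text readers with a column map,
  warm-up trimming to the 10–70 s analysis window (N = 6000 samples),
  derived angular acceleration and drift-corrected angle channels.
* **Movement complexity** — Sample Entropy
  SampEn(m, r, N) = −ln(A/B) with m = 2, r = 0.2·SD, where B counts
  length-m template pairs within Chebyshev tolerance r and A the same
  for length-(m+1); plus the lumbar and hip flexion complexity factors
  LCF = SampEn(Gyr Y SENS1 − Gyr Y SENS2) and
  HCF = SampEn(−Gyr Z SENS3 − Gyr Y SENS2). Lower SampEn = more
  stereotyped movement.
* **Cycle segmentation** — smoothed Acc Z of SENS1, an
  amplitude-relative 40% threshold, one deep-flexion minimum per
  below-threshold run; cycles between successive minima, each
  length-normalized to 450 points.
* **Group statistics** — Shapiro-gated t / Mann–Whitney comparisons and
  the reliability quantities SEM = SD/√N, CI = 1.96·SEM,
  MDC = 1.96·√2·SEM of matched between-group differences.
* **Classification** — a benchmark of seven classifiers (brute-force
  KNN, linear SVM, RBF SVM, decision tree, random forest, AdaBoost,
  Gaussian naive Bayes) with grid-search hyperparameters, repeated
  stratified cross-validation (5-fold × 100 repetitions, train-only
  scaling) reporting accuracy and AUC as mean ± SD, and forward /
  backward sequential feature selection with first/second-place
  tallies.
* **Synthetic cohorts** — a generator of 3-sensor recordings with
  ground-truth cycle times and tunable group contrasts, so every stage
  is testable end to end without any data download.

## Worked example

Simulate a labelled cohort (10 healthy NLBP + 10 CLBP), trim the
warm-up, compare entropy outcomes between groups, and benchmark a
classifier on the 126 raw kinematic features:

```r
library(bendr)

cohort <- generate_cohort(n = 10, seed = 42) |> trim_cohort()

entropy <- purrr::map2_dfr(cohort$recording, cohort$subject_id,
  function(rec, sid) {
    cf <- complexity_factors(rec)
    tibble::tibble(subject_id = sid, group = attr(rec, "group"),
                   `SampEn Gyr Y SENS2` = sample_entropy(rec$SENS2_Gyr_Y)$value,
                   LCF = cf$value[1], HCF = cf$value[2])
  })
entropy_group_table(entropy)
#> # A tibble: 3 × 8
#>   outcome            test       p_value diff_mean diff_sd     sem     ci    mdc
#>   <chr>              <chr>        <dbl>     <dbl>   <dbl>   <dbl>  <dbl>  <dbl>
#> 1 SampEn Gyr Y SENS2 t     0.0000000448    0.101   0.0344 0.0109  0.0213 0.0302
#> 2 LCF                t     0.0000000977    0.0761  0.0256 0.00809 0.0159 0.0224
#> 3 HCF                t     0.0000000905    0.202   0.0727 0.0230  0.0451 0.0637
```

The pelvis flexion-axis entropy and both complexity factors are lower
in the patient group (positive NLBP − CLBP differences, t-test
p ≪ 0.05): simulated patients move more regularly. The `sem`/`ci`/`mdc`
columns say how large a difference must be before it exceeds
measurement noise at this sample size.

```r
features <- build_feature_table(cohort)
features
#> <br_features> 20 rows x 126 features (whole-sequence mode)

bm <- evaluate_classifiers(
  features,
  specs = default_classifier_specs()["GaussianNB"],
  protocol = eval_protocol(folds = 5, repetitions = 25, seed = 1))
dplyr::select(tidy(bm), algorithm, accuracy, auc)
#> # A tibble: 1 × 3
#>   algorithm  accuracy    auc
#>   <chr>      <chr>       <chr>
#> 1 GaussianNB 0.85 ± 0.04 0.94 ± 0.03
```

Gaussian naive Bayes separates the groups well above chance from the
raw describers (accuracy 0.85 ± 0.04 over 25 shuffled 5-fold CV
repetitions). `autoplot()` methods display benchmark tables, SFS
tallies and mean ± SD normalized cycles; `run_pipeline(run_config(...))`
executes every stage and writes a delimited-text report bundle, and
`inst/scripts/br_pipeline.R` wraps it for shell use. The methods
vignette (`vignettes/bendr-methods.Rmd`) documents the models,
conventions and the synthetic signal family in detail.

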