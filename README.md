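# actikoa

Can a week of wrist-worn accelerometry reveal knee osteoarthritis (KOA)
years before it is diagnosed? `actikoa` implements that case-control
analysis end to end for researchers in digital biomarkers and
musculoskeletal epidemiology: each participant is a 24-value diurnal
profile of hourly mean acceleration plus month, sex, age and weight, and
three binary tasks are evaluated — healthy vs KOA, prodromal vs diagnosed
KOA, and healthy vs a diagnosis within 5 years. Because the motivating
cohort data are access-controlled, the package includes a seeded
synthetic-cohort generator with the same statistical structure, so the
whole pipeline runs, and is tested, without any data download.

## What is inside

* **Synthetic cohorts** — `synthetic_config()`, `generate_population()`:
  a diurnal template with nocturnal plateau and 10:00 peak, seasonal
  modulation `1 + a·cos(2π(month − 7)/12)`, BMI-linked activity, ICD-10
  coded cases with pre-/post-recording diagnosis offsets, and a
  multiplicative daytime (hours 9–16) case attenuation δ.
  `calibrate_attenuation()` picks δ for a target separability through the
  closed form `AUC = Φ(d/√2)`, `d = δ·μ_day/σ_day`.
* **Cohort construction** — `filter_valid()` (complete profiles, hourly
  values ≤ 1000, BMI ≥ 29), `classify_status()` (healthy / diagnosed /
  prodromal with a within-5-years flag), `matched_undersample()`
  (sex-stratified, binned density-ratio weights on age and BMI),
  `build_scenario()` for the three tasks.
* **Classifier** — `model_config()`, `train_fold()`, `predict()`: a 1D
  CNN (16/32 filters, batch norm, ReLU, global average pooling) fused
  with month/sex embeddings and an age/weight projector, trained with
  Adam (30 epochs, batch 64, learning rate 0.001). Implemented in
  vectorized base R with hand-derived backpropagation, verified by
  finite-difference gradient checks in the test suite.
* **Evaluation** — `stratified_kfold()`, `compute_metrics()` (accuracy,
  macro F1, macro sensitivity, macro AUC, confusion matrices),
  `chi_squared_confusion()`, `proportion_z_test()`, `cross_validate()`.
* **Pipeline** — `run_config()`, `run_pipeline()`, `make_report()`, and
  the staged drivers in `analysis/` (simulate → build scenarios →
  cross-validate → report) writing under `results/`.

## Worked example

Simulate a cohort whose case effect is calibrated to a daytime-mean AUC
of 0.672, build the healthy-vs-KOA scenario, and cross-validate:

```r
library(actikoa)

cfg <- synthetic_config(
  n_participants = 12000,
  daytime_attenuation = calibrate_attenuation(0.672, synthetic_config()),
  seed = 1)
cohort <- generate_population(cfg)
kept <- filter_valid(cohort)$kept          # 10020 of 12000 pass
scen1 <- build_scenario(kept, scenario = 1, seed = 2)
scen1
#> scenario_dataset (scenario 1): 1253 vs 1253 records
cv <- cross_validate(scen1, model_config(), k = 5, seed = 3)
cv
#> cross-validation over 5 folds
#>   accuracy           0.574 +/- 0.012
#>   f1_macro           0.572 +/- 0.011
#>   sensitivity_macro  0.574 +/- 0.012
#>   auc_macro          0.604 +/- 0.016
#>   chi-squared (best fold) 14.22, p = 0.000162
#>   proportion z (pooled)   7.39, p = 1.46e-13
round(normalize_confusion(cv$folds[[cv$best_fold]]$confusion), 3)
#>     predicted
#> true     0     1
#>    0 0.628 0.372
#>    1 0.460 0.540
```

Reading the output: the classifier separates cases from controls well
above chance (pooled proportion z test p ≈ 1e-13), with a mean
cross-validated AUC of 0.60 at this cohort size; with exactly balanced
classes, accuracy equals macro sensitivity. At the full ~7000-record
scale of the `analysis/` and acceptance runs, the cross-validated AUC
moves into the 0.62–0.67 band of the calibrated design value. Scenario 2
(prodromal vs diagnosed) stays near 0.5 by design: prodromal and
diagnosed cases share one attenuation, encoding the interpretation that
movement changes precede diagnostic coding (see the methods vignette,
`vignettes/diurnal-koa-classification.Rmd`).

The staged analysis is run from the repository root with

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_build_scenarios.R
Rscript analysis/03_crossvalidate.R
Rscript analysis/04_report.R
```

which writes datasets, per-fold metric tables, significance tests and a
plain-text report under `results/`.

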