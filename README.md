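# manugrip

Detecting insincere (deliberately submaximal) grip effort from the hand's
load-distribution pattern.

## The problem

Grip-force measurements drive treatment and compensation decisions, yet a
patient can feign weakness by gripping at, say, half strength, and no single
force number reveals it. Cylinder manugraphy measures not just the total
grip force but *where* the hand applies it: the force component
perpendicular to a sensor-covered cylinder is recorded per sensor and
aggregated into seven anatomical areas — thumb (I), index (II), middle
(III), ring (IV) and little finger (V), thenar (TH) and hypothenar (HY)
eminences — each expressed as a percent contribution to the total load.
Under submaximal effort this compositional pattern shifts, which opens two
ways to classify an individual test as sincere or insincere:

* **Conventional threshold method.** For a bimanual test, compute the
  absolute percentage-point difference of each corresponding area between
  the two hands and count the exceedances
  `N = #{ a : |p_a^left − p_a^right| > 3 }`. A pair is called insincere
  when `N ≥ c`; the operating point `c ∈ {0,…,8}` is chosen on the ROC
  curve by Youden's `J = sensitivity + specificity − 1`, with ties broken
  toward specificity.
* **Machine-learning harness.** Per-record features (age, sex, handedness,
  total force, six area percents, the variance of the seven percents, the
  log of the total contact load) feed four classifier families — random
  forest, linear-kernel SVM, gradient boosting and XGBoost — trained with
  stratified 80/20 splitting, five-fold cross-validated grid search, and
  evaluated on the held-out part.

Both routes are scored the same way: sensitivity (detecting submaximal
effort is the positive class), specificity, accuracy with an exact
Clopper–Pearson 95% CI, and AUC with a DeLong 95% CI.

Because no public manugraphy dataset exists, the package ships a
synthetic-cohort simulator that replicates the reference study design — 54
subjects (25 male, 52 right-handed), two sessions, three trials per hand,
one hand maximal and one submaximal (½–¾ strength) per session — yielding
324 maximal and 324 submaximal records, with an effort-dependent Dirichlet
shift of the 7-area composition. It also renders plausible sensor grids
(2 sensors/cm², 120–200 activated sensors per grip) from any load record.

The package is aimed at hand-function researchers and methodologists who
want to stress-test sincerity classifiers end to end before touching
clinical data.

## Worked example

```r
library(manugrip)

trials <- simulate_study(study_design(seed = 42))   # 648 records
pairs  <- build_pairs(trials)                       # 324 insincere + 162 sincere
thr    <- threshold_report(pairs)
print(thr$roc)
#> Exceedance-count ROC (>3 pp rule) on 324 insincere / 162 sincere pairs
#> AUC 0.7181; chosen cutoff 1 areas (sens 0.7068, spec 0.6790)

feats <- build_features(trials)
split <- split_data(feats, train_fraction = 0.8, seed = 42)
fit   <- train_model(split$train, "xgb", seed = 42)
print(evaluate_model(fit, split$validation))
#> Method: extreme_gradient_boosting  (n = 65 positive / 65 negative)
#>   Sensitivity     0.9385
#>   Specificity     0.9538
#>   Accuracy        0.9462  (95% CI 0.8922-0.9781, Clopper-Pearson)
#>   AUC             0.9851  (95% CI 0.9703-0.9999, DeLong)
```

Read: the conventional exceedance-count rule separates sincere from
insincere pairs only moderately (AUC 0.72) — individual load patterns vary
too much for a fixed threshold — while the ML model, which sees each
record's full pattern plus covariates, detects 94% of submaximal trials
while misclassifying under 5% of maximal ones on held-out data. The
ordering (ML well above thresholds) is the package's central qualitative
result; the absolute numbers describe the synthetic cohort, not any
clinical population.

`run_experiment(run_config(seed = 1))` runs the whole pipeline — simulate,
threshold analysis, all four ML algorithms, comparison table — and writes
`trials.csv`, `pairs.csv`, `cutoff_roc.csv`, `ml_metrics.csv`,
`comparison.csv/.txt` and a run manifest. The same pipeline is available
from the shell via `exec/manugrip` (subcommands `simulate`, `threshold`,
`ml`, `compare`; see `--help`).

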