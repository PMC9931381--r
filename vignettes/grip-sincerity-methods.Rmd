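---
title: "Methods: grip-sincerity classification from load-distribution patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grip-sincerity classification from load-distribution patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manugrip)
```

## The measurement model

Cylinder manugraphy records the force component perpendicular to a
sensor-covered cylinder, sensor by sensor (7 mm² sensors at 2 per cm²).
The contact image is segmented into seven anatomical areas — thumb (I),
four fingers (II–V), thenar (TH), hypothenar (HY) — and each area's share
of the total load is expressed in percentage points, so every record is a
7-part composition summing to 100 plus a total force in newtons.
`aggregate_map()` performs the segmentation sum; the mask is an input,
since area boundaries come from anatomical landmarks, not from the force
image itself. Percent values are always percentage points, never
fractions: the clinical ">3%" significance rule and all bimanual
comparisons are stated on that scale.

## The synthetic cohort

No manugraphy dataset is publicly deposited, so everything downstream is
exercised on simulated data with the reference design: 54 subjects (25
male, 29 female; 52 right-handed), ages 19–53, two sessions, three trials
per hand per session, one hand maximal and the other submaximal per
session, the submaximal hand swapping between sessions — 648 records, 324
per class.

Generator structure, per subject:

* **Strength** — sex-specific normals (male 400 ± 60 N, female 280 ± 50 N,
  truncated at 100 N). These are configuration values chosen to give a
  plausible spread of total cylinder loads in a healthy adult cohort; they
  are not estimates from any dataset.
* **Baseline composition** — a Dirichlet draw centred on the population
  mean composition (default I 20, II 12, III 16, IV 13, V 8, TH 16, HY 15,
  again an implementer configuration, deliberately kept separate from any
  published value) with concentration 400, giving realistic between-subject
  pattern variation. Each hand then receives independent Gaussian
  perturbations scaled so the between-hand difference per area has
  standard deviation `asymmetry_sd` = 1 percentage point. That default
  makes sincere bimanual differences rarely exceed 3 points, which is
  exactly the physiological rationale behind the clinical 3-point rule.
* **Effort model** — submaximal trials scale the total force by
  f ~ Uniform(0.5, 0.75), the instructed "grip at ½ to ¾ strength" band,
  times log-normal trial noise (sd 0.05 on the log scale) that applies to
  maximal trials too. The composition shifts by `redistribution_delta`
  (default I +2.5, II +1.5, III −0.5, IV −0.5, V −0.5, TH −1.5, HY −1.0
  percentage points, plus per-trial jitter of sd 0.5), applied on the
  percent scale and renormalised to 100. The direction — thumb and index
  relatively preserved, thenar most unloaded — follows the documented
  qualitative pattern of insincere grips. The hypothenar's direction of
  change is genuinely ambiguous in the source material (reported both as
  increasing and as most neglected, in different bimanual configurations),
  so the default keeps it mildly negative and the sign is fully
  configurable; no default is presented as an established fact.
* **Trial noise** — percents are drawn from a Dirichlet centred on the
  (shifted) baseline with concentration 1500, i.e. a per-area trial sd of
  roughly 1 point; `trial_concentration = Inf` with zero jitter collapses
  to the deterministic target, which the tests use as a closed-form check.

Reproducibility: one base seed in `study_design()`; the cohort is drawn
from it directly, and each trial record draws from its own derived seed
(base and position in the design), so records do not depend on generation
order. Identical seeds give identical studies byte-for-byte through the
CSV writer.

`render_map()` inverts the aggregation for testing and demonstration: it
places seven disjoint rectangular templates on a 16 × 28 grid, activates a
random 60–80% of each template's cells as a smooth Gaussian blob, and
scales cell forces so each area's sum equals its requested force exactly.
Activation therefore stays within 120–200 sensors at the default hand
scale — the range typical of real cylinder grips — and
`aggregate_map(render_map(x))` recovers `x` to floating-point precision.

**What the simulator does not emulate.** Finger kinematics, time-resolved
force curves, fatigue across trials, learning between sessions, sensor
noise and cross-talk, hand-size-dependent mask geometry, and any
correlation between covariates (age, sex) and the *pattern* shift. Passing
tests therefore demonstrate that the pipeline is correct and that the
method ordering (multivariate classifier above the univariate count rule)
holds under the modelled effect structure — they say nothing quantitative
about clinical performance.

## The conventional threshold method

For a bimanual pair, `diff_profile()` takes the absolute percentage-point
difference per corresponding area and counts exceedances of the threshold
(default 3). Exceedance is strict (`> 3`): a tie at exactly 3.0 does not
count. `classify_pair()` labels a pair insincere when the count is at
least the cutoff, so the natural operating points are the nine cutoffs
0–8 (0 labels everything insincere, 8 nothing). `cutoff_roc()` evaluates
all nine, computes the trapezoidal AUC over (1 − specificity,
sensitivity) with endpoints (0,0) and (1,1), and picks the cutoff
maximising Youden's J. Ties break toward the *higher* cutoff, i.e. toward
specificity: wrongly branding a sincere patient a malingerer is the more
damaging error, so when two cutoffs are statistically equivalent the more
conservative one wins.

Pair construction is the one genuinely open design point: insincere pairs
are natural (maximal vs submaximal hand, same subject, session and trial),
but a *sincere* pair needs two maximal efforts from opposite hands, which
the bimanual protocol never produces within a session. The package forms
sincere pairs from the maximal hands of session 1 and session 2 (same
trial index). This is a package decision, flagged here and in the
documentation: other constructions are defensible and would move the
negative-class difficulty, which is one reason the conventional method's
published specificity cannot be reconstructed, only emulated.

`group_area_comparison()` supplies the group-level view: per area, the
paired difference maximal-minus-submaximal (mean, min, max, sd) and a
two-sided Wilcoxon signed-rank p-value, paired within subject, session and
trial.

## The ML harness

`build_features()` produces, per record: age (years), sex (female 0, male
1), handedness (right 0, left 1), total force (N), the percent loads of
II, III, IV, V, HY, TH, the sample variance of the seven percents, and
the natural log of the summed area loads (the log of total contact load;
the base is configurable). The canonical feature list this mirrors is
described as 13 items but enumerates 12; rather than silently inventing a
13th, the thumb percent `pct_I` sits behind `include_thumb = FALSE`.
Features never read the effort label.

`split_data()` defaults to a record-level stratified 80/20 split — the
historical choice, which allows the same subject in both parts and hence
inflates performance through subject leakage — and offers
`group_by_subject = TRUE` as the honest alternative. Both are first-class;
every report names the mode used.

`train_model()` runs stratified k-fold (default 5) cross-validation over a
small seed-stable grid per family (forest: mtry; SVM: cost; boosting:
rounds × depth), selects by mean out-of-fold AUC, and refits on all
training data. Scores are class probabilities where available and signed
decision values for the linear SVM (oriented on the training data so
larger always means more likely submaximal); hard labels threshold at 0.5
or 0 respectively. The gradient-boosting family is implemented in the
package as logistic-loss boosting over `rpart` regression trees with a
per-leaf Newton step, shrinkage 0.1 and leaf values clipped to ±4 for
stability; random forest, linear SVM and XGBoost come from their standard
implementations, single-threaded for determinism.

## Metrics

Positive class everywhere: submaximal/insincere. Sensitivity, specificity
and accuracy come from the confusion matrix; the accuracy interval is
exact Clopper–Pearson via beta quantiles (the conservative standard for
small validation sets — the upstream "(95% CI)" never names a method, so
the package names its own). The ROC groups tied scores into single
threshold steps; its trapezoidal AUC equals the Mann–Whitney probability
with ties counted one half, which the tests verify by brute force. The
AUC interval uses DeLong's placement-value variance with a normal
approximation, clipped to [0, 1]; perfectly separated scores give zero
variance and a collapsed interval, flagged `degenerate` rather than
patched. Reported proportions are formatted to four decimals in the
comparison table, whose rows are Sensitivity / Specificity / Accuracy /
(95% CI) / AUC / (95% CI deLong) with one column per method.

## Numerical and interface choices

* CSV percent columns are renormalised on read when their sum is within
  0.5 of 100 (accommodating rounded exports) and rejected beyond that,
  naming the offending row.
* Compositions are clipped below at 0.1–0.2 points before renormalisation
  in the generator, so Dirichlet concentrations stay strictly positive.
* Dirichlet draws use the normalised-gamma construction.
* Grid search ties resolve to the first grid row; Youden ties to the
  higher cutoff, as above.
* The experiment driver (`run_experiment()`) writes every stage's output
  as CSV, communicates between stages only through those files, and echoes
  the full configuration, seed, versions and split mode into
  `manifest.json`; identical configuration and seed give byte-identical
  CSVs.

## Problem sizes used by the test-suite

The suite exercises the full 54-subject design (648 records) for design
bookkeeping, calibration and determinism checks; miniature 2–10-subject
studies for unit-level contracts; 50 rendered grids for the sensor-count
range; a 2000-replicate stratified bootstrap at 100 scores per class as
the oracle for the DeLong interval; and five full simulate-train-evaluate
cycles for the method-ordering check. Null-calibration checks evaluate
trained models on independently simulated studies (1296 records) so the
Monte-Carlo error of a chance-level AUC stays well inside the ±0.05 band
being asserted.

## Known limitations

The classifiers are only as meaningful as the simulated effect: with a
different redistribution structure (e.g. a strongly positive hypothenar)
the threshold method's chosen cutoff and both methods' absolute
performance move. Record-level splitting leaks subjects by construction;
use the grouped split for honest generalisation estimates. The DeLong
interval is asymptotic and degrades near AUC 1 with small validation sets
— the bootstrap oracle in the tests quantifies how close it stays at the
sizes used here. And none of the numbers produced on synthetic cohorts
transfer to clinical populations; the package's claim is the correctness
of the machinery and the robustness of the qualitative method ordering,
not clinical operating characteristics.
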