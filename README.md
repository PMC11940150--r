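# pdmobility

Machine-learning analysis of single-sensor mobility recordings for
separating Parkinson's disease (PD) from other forms of parkinsonism
(MSA-P, PSP, DLB, CBS, drug-induced and unspecified parkinsonism).
The package is aimed at movement-disorders researchers who work with a
lower-back inertial unit (triaxial accelerometer in g, triaxial
gyroscope in degrees/s, 100 Hz) recorded during a standard clinical
battery: a 32-foot walk, 20 s of quiet standing with eyes open and
closed, and two trials each of the Timed Up and Go (TUG) and cognitive
TUG.

The pipeline covers:

- **Signal conditioning** — a zero-phase (forward–backward) 4th-order
  Butterworth low-pass at 20 Hz, and marker-based task windowing.
- **Subtask segmentation** — turns, sit-to-stand, stand-to-sit and
  walking segments recovered from trapezoidally integrated angular
  velocity, with stationary-period removal.
- **A fixed feature registry** — per channel and segment: 42
  time-domain and 22 frequency-domain statistics plus the top 10 power
  amplitudes of the DFT and of the Lomb–Scargle periodogram, and 3
  cross-channel statistics per channel pair; TUG/cogTUG features carry
  four derivations (trial 1, trial 2, mean, difference).
- **MIEE** — mutual-information-based feature selection for
  EasyEnsemble: the imbalanced training set (by default 260 PD : 18
  non-PD) is undersampled into five class-balanced subsets; in each,
  the top 30 features by a k-nearest-neighbour mutual-information
  estimate are selected and a 1000-tree random forest is trained;
  member probabilities are averaged,

  p(x) = (1/5) Σ_m p_m(x),  label = non-PD iff p(x) ≥ 0.5.

- **Evaluation** — three-fold stratified cross-validation repeated five
  times with per-participant majority voting; balanced accuracy,
  sensitivity, specificity, F1 and rank-statistic AUC-ROC with
  bias-corrected accelerated (BCa) bootstrap intervals on balanced
  per-class resamples; grouped permutation importance of the five
  mobility tasks; selection tallies; misclassification profiling
  (Student's t, Pearson's χ²) and random-forest proximity similarity.
- **Baselines** — unsupervised-RF, MI-top-30, decision-tree-F1 and
  min-AIC feature selection, NCL+SMOTE resampling placements, and
  random undersampling, all under the identical cross-validation
  harness.
- **A synthetic cohort simulator** — piecewise kinematic templates
  (raised-cosine turn and transition pulses, ~2 Hz gait harmonics,
  band-limited stance sway) with known ground-truth boundaries and
  tunable class effects, so the entire pipeline is testable without
  any clinical data.

## Worked example

```r
library(pdmobility)

cfg <- sim_config(n_majority = 60, n_minority = 12, tasks = "tug",
                  seed = 21)
cohort <- simulate_cohort(cfg)
ft     <- subset_task(assemble_feature_table(cohort), "tug")
cv     <- cross_validate(ft, cv = cv_config(n_repeats = 1, seed = 33),
                         miee = miee_config(n_trees = 200, seed = 33))
cm     <- confusion_matrix(ft$labels, cv$final$label, positive = "pd")
round(compute_metrics(cm, scores = 1 - cv$final$prob,
                      truth = ft$labels), 3)
#> balanced_accuracy       sensitivity       specificity
#>             0.967             0.933             1.000
#>                f1               auc
#>             0.966             0.996
```

The minority class in this simulated cohort carries the default class
effects (1.5× transition duration, 0.7× turn angular velocity, 1.5×
sway power), so the cross-validated balanced accuracy is high; with
`effect_scale = 0` the same pipeline calibrates to ~0.5 (chance), and
at `effect_scale = 0.5` it lands in between (~0.70 in the run above
with seed 21/33) — the separation is learnable but tunably imperfect.

Published desk-scale arithmetic is reproduced directly from confusion
matrices:

```r
m <- compute_metrics(confusion_matrix(
  counts = c(tp = 190, fn = 70, fp = 3, tn = 15)))
round(100 * m[["balanced_accuracy"]], 1)   # 78.2
round(100 * m[["sensitivity"]], 1)         # 73.1
round(100 * m[["specificity"]], 1)         # 83.3
round(m[["f1"]], 2)                        # 0.84
```

## Vignette

`vignettes/pdmobility-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
simulator does and does not emulate, and the numerical choices and
known limitations.
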