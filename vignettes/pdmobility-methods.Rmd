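---
title: "Classifying parkinsonism from a single wearable sensor: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying parkinsonism from a single wearable sensor: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease (PD) and the other parkinsonian syndromes (MSA-P,
PSP, DLB, CBS, drug-induced and unspecified parkinsonism) overlap
heavily in their motor presentation, and even expert clinical
diagnosis is imperfect. A single inertial sensor worn on the lower
back during a short mobility battery offers an objective signal:
axial movements — rising from a chair, turning 180°, sitting down —
are differentially affected in atypical parkinsonism. This package
implements a complete analysis path from raw six-channel recordings
(triaxial acceleration in g, triaxial angular velocity in degrees/s,
100 Hz) to a cross-validated two-class classifier, together with the
statistical machinery needed to interpret it under severe class
imbalance (260 PD vs 18 non-PD by default).

Because the clinical recordings themselves are not distributed with
the package, a simulator generates cohorts with the same protocol
structure and known ground truth; every stage is exercised and tested
against it.

## Signal conditioning

Each channel is filtered with a 4th-order low-pass Butterworth at
20 Hz (`filter_spec()`), applied forward and backward. The zero-lag
mechanism is forward–backward filtering: the effective magnitude
response is the squared one-pass response, 1/(1 + (f/f_c)^8) in the
continuous-time approximation, and the phase shift is identically
zero. Edges are padded by odd reflection of length 3 × order, and each
pass starts from the steady state of its first sample, so a constant
channel passes through bit-exactly. Note one practical subtlety: a
digital (bilinear-transform) Butterworth attenuates tones near the
Nyquist frequency considerably more than the continuous-time formula
suggests (at 40 Hz and 100 Hz sampling, ~1e-5 rather than ~4e-3); the
package matches MATLAB/scipy `filtfilt` behaviour.

## Segmentation

Complex tasks are decomposed using trapezoidally integrated angular
velocity (`cumulative_yaw()`). A candidate event opens where the
smoothed absolute rate (0.3 s moving average, which cancels the ~2 Hz
gait oscillation but not the slower event pulses) exceeds a detection
threshold, and its boundaries extend outward until the raw rate falls
below a refinement threshold:

- turns: vertical gyroscope, detection 15 °/s, net yaw ≥ 90°;
- postural transitions: trunk-pitch gyroscope, detection 20 °/s,
  integrated pitch ≥ 20°;
- refinement threshold 2 °/s (4 standard deviations of the default
  simulated gyroscope noise), merge gap 0.5 s, minimum segment 0.3 s.

For a lower-back sensor, trunk pitch is rotation about the
*mediolateral* axis, so transition detection defaults to `gyr_ml`
(`pitch_channel` is configurable for other mounting conventions).
By TUG protocol order the first transition is labeled sit-to-stand and
the last stand-to-sit — positional labeling is robust to sensor
polarity, unlike direction-of-rotation inference. Exactly two turns
are expected between the transitions; the gaps sit-to-stand → turn 1
and turn 1 → turn 2 become walking segments after trimming stationary
samples (the turn 2 → stand-to-sit gap is empty in a canonical TUG,
where the second turn ends at the chair). Stationary samples are
those whose moving 0.5 s standard deviation of total dynamic
acceleration falls below 0.06 g — above the simulated stance sway
(~0.045 g) and far below gait (~0.2 g). Any structural mismatch
raises a segmentation failure so the recording can be excluded rather
than silently mis-featurized.

None of these thresholds is prescribed by a reference; they are the
package's own defaults, chosen to be robust on the kinematic templates
and exposed in `seg_params()`. On 100 simulated TUG trials the median
absolute boundary error is ≤ 0.1 s (the residual bias is the time a
raised-cosine pulse spends below the refinement threshold, ~0.07 s).

## The feature registry

`feature_registry()` fixes a versioned catalogue: 42 time-domain and
22 frequency-domain features per channel and segment, the top 10 DFT
and top 10 Lomb–Scargle power amplitudes, and 3 statistics per channel
pair (Pearson correlation, maximum normalised cross-correlation within
±1 s, magnitude-area ratio). The counts are the contract; the exact
identities are documented in `time_domain_features()` and
`frequency_domain_features()`. Spectral estimates use a rectangular
window over the segment — segments are short and reproducibility
matters more than leakage suppression; the Lomb–Scargle periodogram is
evaluated on a fixed 0.1–20 Hz grid (0.1 Hz step) so the amplitude
features are comparable across segments of different lengths. Sample
entropy (m = 2, r = 0.2 sd) is evaluated on at most the first 600
samples of a segment, which bounds its quadratic cost on 20 s stance
windows while leaving TUG subtask segments untouched.

A full five-task cohort yields 27,999 columns per participant: 549 per
segment window (6 × 84 + 15 × 3), with six TUG subtask windows per
trial and four derivations (trial 1, trial 2, mean, difference) for
the two-trial tasks. Feature values that are undefined for a segment
(autocorrelation of a constant, coefficient of variation at zero mean)
are `NA`; preprocessing (`preprocess_table()`) drops columns that are
constant or non-finite on the fitting rows and median-imputes the
rest, and the fitted state is reusable on held-out rows so no test
information leaks into imputation.

## MIEE and cross-validation

Mutual information between each feature and the class is estimated
with the k-nearest-neighbour estimator for mixed continuous/discrete
pairs (k = 3), with a vanishing jitter (1e-10 of the feature scale) to
break ties — this avoids the binning sensitivity a histogram estimator
would introduce into a top-30 selection, and it reproduces the
closed-form oracle ln 2 nats for a duplicated balanced binary label
within 0.05. EasyEnsemble undersampling draws, per subset, all
minority rows plus an equal-size uniform draw of majority rows;
selection and forest training happen per subset. The decision
threshold on the averaged minority probability is 0.5 with ties to the
minority class — conservative under imbalance.

Cross-validation is stratified three-fold, repeated five times with
different seeds; each participant is tested exactly once per repeat
and the final label is the majority vote (the repeat count must be
odd, so the binary vote cannot tie). Everything that learns —
preprocessing, selection, forests — is fitted inside the training
fold; the test confirms bit-identical models when test rows are
deleted before fitting.

## Evaluation

Balanced accuracy, sensitivity, specificity and F1 come from the
confusion matrix with PD as the positive class; AUC-ROC is the
normalised Mann–Whitney rank statistic (checked against brute-force
pair counting and pROC). Confidence intervals use the balanced
bootstrap — each class resampled with replacement at its own size, so
every replicate preserves the imbalance and class-conditional metrics
stay defined — with BCa correction via `boot::boot.ci`; a degenerate
replicate distribution falls back to a flagged percentile (or
zero-width) interval. Grouped permutation importance permutes all
columns of one mobility task simultaneously with a shared set of row
permutations (50 by default; shared so the result is invariant to
group and feature order) and reports the mean decrease in balanced
accuracy. The χ² test for categorical covariate comparisons defaults
to no continuity correction (a flag enables it).

## The simulator: what it does and does not emulate

`simulate_cohort()` builds recordings from piecewise kinematic
templates: raised-cosine yaw pulses integrating to 180° for turns,
raised-cosine pitch pulses integrating to 45° for transitions, gait
harmonics near 2 Hz (fundamental + second harmonic) on the vertical
and anteroposterior accelerometer during walking, band-limited (≤2 Hz)
sway noise during stance, and additive white Gaussian sensor noise
(0.005 g, 0.5 °/s). Class effects multiply template parameters for
minority participants only: 1.5× transition duration, 0.7× turn
angular velocity, 1.5× sway power (second-harmonic amplitude shift
available, default 1). These defaults produce a learnable but
imperfect separation — cross-validated balanced accuracy ~0.5 at
`effect_scale = 0`, ~0.7 at 0.5 and >0.9 at 1 on small cohorts —
because participants also vary log-normally around the template
(sd 0.12–0.25 on the same parameters). Durations jitter per trial
(cv 0.05; 0.12 for cognitive TUG, mimicking dual-task cost).

The simulator does **not** emulate step-level gait events, tremor,
freezing, medication state, sensor drift, or the heterogeneity of real
non-PD subtypes. Passing tests on simulated cohorts therefore
demonstrate that the pipeline recovers structure it is pointed at —
correct segmentation, leak-free selection, calibrated nulls — not that
the classifier reaches any particular accuracy on clinical data. No
quantitative kinematic group differences are available to calibrate
the effect sizes against, so they are stipulated, not estimated.

## Problem sizes used by the automated checks

The test suite runs the null calibration at the full study imbalance
(260:18, ten seeds) in the TUG-only protocol mode with 200-tree
forests and one CV repeat; the planted-signal and effect-monotonicity
experiments use reduced cohorts (52:10 with all five tasks, and 40:8
TUG-only at three effect levels × ten seeds, respectively). The
acceptance script runs the full five-task cohort at 260:18 with
five-repeat CV and 500-tree forests, and three zero-effect cohorts for
the null. These sizes are the package's own choices; the statistical
behaviour they probe (chance-level nulls, TUG-localised signal
recovery, monotonicity in effect size) is size-stable in the ranges
used.

## Known limitations

- The feature catalogue fixes plausible, standard identities for the
  42/22/3 per-channel and pairwise statistics; other equally valid
  catalogues with the same counts exist.
- The AIC used by the min-AIC baseline is defined over out-of-bag
  binomial likelihood — forests have no canonical likelihood, so this
  is a stipulated definition.
- The "unsupervised RF" ranking uses a shadow-feature contrast (real
  rows vs column-permuted copies); other constructions exist.
- Percentile scores for held-out participants are computed against a
  caller-supplied reference distribution (typically cross-validated
  scores of the training cohort); a reference class with fewer than
  two members is flagged rather than trusted.
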