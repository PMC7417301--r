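---
title: "Movement-screen skill classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-screen skill classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(omat)
```

## The problem and the model

Movement screens grade an athlete's quality of movement over a battery of
standardized dynamic tasks (drop jump, bird-dog, hop-down, lunge, step-down,
L-hop, T-balance; the bilateral tasks are scored per side, giving 13 trials
per athlete). Visual scoring of such screens is notoriously unreliable, so
`omat` implements a fully objective alternative: whole-body kinematic
waveforms are turned into a fixed-length feature vector per athlete, a
principal component analysis (PCA) compresses the cohort's waveform
variance into a small number of modes, an ensemble of feature-ranking
techniques selects the modes that carry skill information, and a
conventional classifier separates *elite* from *novice* athletes on the
selected principal component (PC) scores. Two front ends feed the same
machinery:

* **OPT** — optical-marker input: 26 whole-body positions (14 bilateral
  joint centres, 3 segment centres of gravity, 9 anatomical markers), three
  axes each, time-normalized to 500 frames: a `n x 39,000` matrix per task.
* **sIMU** — simulated inertial input: for each of 13 body segments, the
  Euclidean norm of the CoG linear acceleration (obtained by
  differentiating the CoG linear velocity once) and of the angular
  velocity, time-normalized to 500 frames: a `n x 13,000` matrix per task.
  Norms are used because they are invariant to the orientation of a sensor's
  local axes, which is what makes field deployment with inertial sensors
  credible.

Classification quality is reported as leave-one-out accuracy plus
signal-detection-theory (SDT) metrics: hit (elite classified elite,
sensitivity), miss, false alarm (novice classified elite), correct
rejection (specificity), the sensitivity index `d' = z(hit) − z(FA)`, and
the response criterion `C = −(z(hit) + z(FA))/2` (negative = liberal, i.e.
biased toward calling athletes elite).

## Preprocessing

The stage order is fixed: trim → low-pass filter → height-normalize →
(trunk-align, OPT only) → time-normalize → assemble.

* **Trimming** is configuration-supplied per task (`trim_events`); the
  default keeps the full trial, because synthetic trials are generated
  pre-trimmed and real trimming criteria are laboratory conventions that
  belong in configuration, not code.
* **Filtering** is a dual-pass (zero-phase) low-pass Butterworth, cutoff
  15 Hz, order 2 per pass — the biomechanics convention. Edges use
  odd-reflection padding with the signal level removed per pass, so a
  constant channel passes exactly; a 30 Hz tone at 120 Hz sampling is
  attenuated to below 3% away from the padded edges. Reflection padding
  leaves the unavoidable edge transient of any zero-phase IIR scheme; the
  implementation matches the behaviour of the standard forward–backward
  filtering routines used in this field.
* **Height normalization** divides every sample of every channel family by
  the athlete's height, so that systematically taller elite athletes cannot
  be recognized by size alone. It is applied to all families (positions,
  velocities, angular velocities) for uniformity; `preprocess_trial()` and
  the pipeline log the configuration used.
* **Trunk alignment** (OPT only) builds an anatomical frame from the first
  frame: superior axis T8→T2, anterior axis mid-spine→sternum
  orthogonalized, lateral axis their cross product. One rigid rotation
  (not per-frame) is applied to the whole trial so inter-frame dynamics are
  preserved, then all frames are translated so the frame-0 hip midpoint is
  the origin. Alignment is invariant to any rigid rotation of the capture
  volume.
* **Time normalization** resamples each channel onto `target_frames`
  points spanning normalized time 0..1 inclusive with shape-preserving
  PCHIP interpolation (Fritsch–Carlson slopes, the MATLAB/SciPy
  construction): endpoints exact, monotone segments stay monotone, no
  overshoot.

For the sIMU variant the norms are taken **before** time normalization
(differentiate → norm → resample the scalar norm trace). The Euclidean norm
is exactly rotation invariant, but shape-preserving resampling of the
individual axes is not (the monotonicity limiter is nonlinear), so
resampling first would leave an orientation residual on the order of the
resampling error. Taking the norm first makes the whole sIMU matrix exactly
independent of sensor-axis orientation, which is the stated point of using
norms; the two orders otherwise differ only by the O(h²) interpolation
error.

## Feature selection

PCA is fitted mean-centred (scores are never standardized; scale issues are
handled upstream by the robust scaler for sIMU). Six ranking techniques
order the PC scores by class relevance: absolute Pearson correlation with
the 0/1 label; the chi-squared statistic (scores are min-shifted per
feature — estimated on training data — because the statistic needs
non-negative input); recursive feature elimination under a ridge-regularized
linear discriminant direction, dropping 20% of survivors per round; lasso
coefficient magnitude at a fixed regularization point (`lambda = 0.01`,
no internal cross-validation; exact zeros rank last by index);
random-forest impurity importance (`ranger`, 100 trees, single-threaded,
seed-fixed); and gradient-boosted-tree gain importance (`xgboost`,
50 rounds, depth 3, histogram splits, seed-fixed). Each ranker nominates
its top 25; PCs nominated by at least 3 of the 6 are candidates, ordered by
votes, then mean rank across rankers, then PC index (the deterministic
secondary keys are needed because votes tie heavily). At most
`floor(sqrt(n))` candidates are retained — 20 at n = 401 — and the list is
never padded if fewer candidates exist.

Ranker hyperparameters are package defaults, exposed in code and chosen to
match the common defaults of the libraries practitioners use; they are not
inferred from any reference output.

## Classification protocol

Seven classifiers operate on the retained PC scores: L2-penalized binary
logistic regression (IRLS, penalty 1/C, intercept unpenalized), a decision
tree (`rpart` defaults), k-nearest neighbours (k = 5), linear discriminant
analysis (`MASS::lda`), Gaussian naive Bayes, and support vector machines
with linear and radial kernels (`e1071`, cost 1; RBF gamma defaults to
`1/(k · mean score variance)`).

Validation is leave-one-out with *per-fold re-fitting of the whole stack*:
for each held-out athlete, the robust scaler (sIMU), the PCA, all six
rankings, the ensemble selection and the classifier are fitted on the
remaining athletes only, and the held-out row is projected through those
fitted spaces. Nothing estimated on the full cohort enters a fold. "Use k
PCs" means the first k entries of the fold's vote-ordered retained list;
if a fold retains fewer, k is truncated for that fold with a warning.
`sweep_k()` bounds the sweep with K from one full-cohort selection pass
(used only as a bound, never inside folds) and reports the accuracy-vs-k
curve plus the optimum (highest accuracy, ties to the smallest k). Because
the optimum is selected on the very leave-one-out estimate it reports, the
reported optimum carries the usual model-selection optimism; the package
reports it this way deliberately, to mirror the protocol it implements.

The robust scaler (median/IQR per feature, type-7 linear-interpolation
quartiles, zero-IQR features centred only) is fitted inside each training
fold by default; `scale_discipline = "global"` reproduces the literal
fit-once-on-everything reading, which leaks fold information and is
provided only for comparison. The source description of the scaling as
mapping "between 0 and 1" contradicts its own definition (median/IQR
scaling is unbounded); the definitional parenthetical is implemented.

Inside the cross-validation loop the PCA is computed from the n x n Gram
matrix rather than the feature-space SVD: with far more features than
athletes the two give identical scores (verified to ~1e-12 in the test
suite) and the Gram route avoids ever forming feature-space loadings,
which is what makes per-fold re-fitting affordable.

## The synthetic cohort generator

No public cohort of this kind exists at full scale, so the package ships a
generator whose defaults emulate the study conditions the pipeline assumes:

* **Movement**: each channel is a sum of 3–5 sinusoidal harmonics at
  0.3–2 Hz with per-athlete random amplitudes and phases around a standing
  posture. Segment CoG velocities are the analytic derivatives of generated
  CoG position paths, so both channel families are mutually consistent.
* **Body size**: heights are Gaussian per class (elite 1.82 m, novice
  1.72 m, SD 0.085 — reproducing a strongly significant height gap at
  cohort scale), and *every* generated amplitude is proportional to height.
  Size is therefore a pure global scale, and the pipeline's height
  normalization removes it exactly; a null cohort with unequal heights is a
  genuine test that the normalization works.
* **Skill**: novices receive extra 4–8 Hz jitter harmonics. The jitter
  amplitude multiplier is 1 + shift + athlete trait + channel noise
  (truncated Gaussian; trait SD 0.15, channel SD 0.34), with
  shift = `smoothness_gap` × the total SD, so `smoothness_gap` is exactly
  the per-channel Cohen's d. The two classes have *equal* within-class
  variance by construction, so the Bayes rule on the latent is linear —
  the structure under which linear classifiers should dominate, which is
  the qualitative finding the generator is required to emulate. An
  analogous multiplier with `amplitude_gap` shifts overall movement
  amplitude. Both gaps at 0 give exactly exchangeable classes.
* **Frequencies**: the jitter band (4–8 Hz) lies below the 15 Hz cutoff,
  so preprocessing is exercised without destroying the class signal;
  the jitter share of the acceleration signal is calibrated so that a gap
  of 2 yields a clearly recoverable (>90% leave-one-out accuracy) yet not
  saturated separation.
* **Reproducibility**: one seed governs the whole cohort through
  counter-based substreams keyed by a full-width hash of the athlete id and
  the task index, so any trial can be regenerated in isolation and
  generation order is irrelevant.
* **Metadata realism**: sex is assigned at ~85% male by default and is
  never used by the pipeline; trial durations are uniform on 1–4 s (no
  per-task duration statistics exist to emulate, so this is a free choice).

What the generator does **not** emulate: biomechanically coordinated joint
kinematics (channels are independent oscillators around a posture), real
IMU error sources (bias, drift, placement offsets, gravity leakage), task-
specific waveform shapes, or marker occlusion. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers smoothness- and
amplitude-type class structure without leakage — not that it attains any
particular accuracy on real athletes.

## Numerical choices and degenerate inputs

* Quartiles use linear interpolation between order statistics (type 7),
  matching the scaler convention common in this field, so ports can agree
  bit-for-bit; zero-IQR features are centred with divisor 1.
* PCA keeps components with singular values above 1e-9 of the largest,
  capped at n − 1; explained-variance fractions sum to 1.
* Extreme SDT rates (0 or 1) are replaced by 1/(2N) and 1 − 1/(2N) of the
  relevant class count and flagged in the output, never silently.
* Trunk alignment raises a geometry error on collinear landmarks; trials
  too short for the filter padding, single-class training folds, unknown
  tasks and width mismatches all fail fast with named errors.
* Tie-breaks are deterministic everywhere: vote ties by mean rank then PC
  index, accuracy ties by smallest k, ranker ties by feature index.

## Problem sizes used by the shipped tests

The test suite runs the synthetic studies at 50 time-normalized frames
(matrix widths 3,900/1,300) with cohorts of 200 (null behaviour, 20
generator seeds; signal recovery) and 60 (label permutation); dimensional
contracts are checked at the full 500 frames separately. These sizes were
chosen so the whole suite runs comfortably on a laptop-class single core
while keeping every statistical check at the cohort scale it needs.

## Known limitations

* The reported optimum over k is an optimistically biased estimate (model
  selection on the validation estimate); a held-out test set would be
  needed for an unbiased figure, and none is available at desk scale.
* The C3D support is deliberately minimal: Intel-byte-order files with
  floating-point 3D point data and a standard parameter section.
* Ensemble-selection behaviour with fewer or more than six rankers is
  undefined by design (the vote threshold is tied to the ranker count).
* The generator's class signal is low-dimensional by construction; real
  skill differences are plausibly richer, and nothing here certifies field
  accuracy with physical sensors.
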