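---
title: "Detecting abnormal gait with per-subject NARX walking models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting abnormal gait with per-subject NARX walking models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Abnormal gait — stumbling, tripping, irregular stepping — is a strong
short-horizon predictor of falls. A wearable fall-risk monitor therefore
wants to flag, within a second or so and on very modest hardware, the moment
a person's walk stops looking like *their own* normal walk. `gaitnarx`
implements a model-based detector built on that idea: normal walking is
quasi-periodic, so a subject-specific autoregressive model identified on a
little normal-walk data predicts the next acceleration sample well — until
the gait becomes abnormal, at which point one-step predictions degrade
sharply and a simple threshold on a goodness-of-fit statistic raises the
alarm. No feature engineering and no trained classifier are needed at run
time, which is what makes the approach cheap enough for continuous use.

The sensor model throughout is a tri-axial accelerometer worn on the lower
back (near the body's centre of mass), sampled at 10 Hz. By default the
package models the orientation-robust magnitude channel
$\sqrt{a_x^2+a_y^2+a_z^2}$; a single axis can be selected instead. Signals
are treated as raw accelerometer output in m/s² — gravity is *not* removed,
and the models simply learn the offset.

## The model

Walking is modelled as an autonomous nonlinear autoregression. With
$w(t-1) = (y(t-1), \dots, y(t-n))$ the last $n$ samples of the (z-scored)
scalar acceleration,

$$\hat y(t) = c_0 + \sum_{i=1}^{r} \alpha_i \,
  \sigma\!\left(\beta_i^\top [w(t-1); 1]\right),
  \qquad \sigma(z) = \frac{1}{1+e^{-z}},$$

a single-hidden-layer sigmoid basis expansion. The linear counterpart (a
pure AR model fit by ordinary least squares, coefficients stored in the
left-hand-side sign convention of the linear difference equation) is
provided for comparison; on the same data it is consistently the weaker
predictor, which is the empirical argument for the nonlinear model.

Parameters are estimated by the least-squares prediction-error criterion
$V_N(\theta) = \frac{1}{N}\sum_t (y(t) - \hat y(t))^2$. The objective is
nonconvex; the package minimizes it with analytic-gradient BFGS from seeded
small-weight initializations (weights uniform in $[-0.5, 0.5]$ for output
weights and $[-0.7, 0.7]/\sqrt{n+1}$ for input weights), keeping the best
of 3 restarts, with an iteration cap of 500 and relative convergence
tolerance $10^{-8}$ on the objective. Training is bit-reproducible given
the data, hyperparameters and seed. Because sigmoids saturate, the training
signal is z-scored with its own mean and standard deviation, which are
stored in the model and reused for every later prediction.

Model quality over a window of $n$ one-step predictions $\hat f$ against
measurements $f^\circ$ is summarized by

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i (\hat f_i - f^\circ_i)^2},
  \qquad
  \mathrm{FIT} = 1 - \frac{\mathrm{RMSE}}
  {\sqrt{\tfrac{1}{n}\sum_i (\hat f_i - \overline{\hat f})^2}}.$$

Note the FIT denominator: it is the population standard deviation of the
*predictions*, not of the measurements. That is the definition this
detector is specified with, and it is implemented exactly as written; the
conventional measurement-variance denominator is available behind the
`denominator = "measured"` flag of `goodness_of_fit()` for sensitivity
analysis, but nothing in the package defaults to it. FIT is 1 for a perfect
window, and falls towards (and below) zero under model mismatch.

## The online detector

`classify_stream()` implements the sliding-window rule. At every `hop`-th
sample after a warm-up of `pred_window + fit_window` samples:

1. each sample in the trailing `fit_window` (default 50 samples, 5 s) gets
   an *open-loop* one-step prediction from the `pred_window` (default 10
   samples, 1 s) measured samples preceding it — the model is never fed its
   own predictions;
2. FIT is computed over the window;
3. the window is declared **abnormal when FIT < 0.02** (the default
   threshold), normal otherwise.

Three decisions here were genuinely open and are worth recording:

* **Threshold direction.** High FIT means the window is well explained by
  the subject's *normal-walk* model, so abnormality is low FIT. The
  opposite rule (`rule = "fit_above"`) is kept available because the
  verbal description of such detectors is sometimes stated in the other
  direction, but it is inconsistent with the FIT formula above and is off
  by default.
* **Ties and degeneracy.** FIT exactly at the threshold counts as normal
  (strict inequality triggers the alarm). A window whose predictions have
  zero variance has no FIT; since a flat prediction stream from a walking
  model is itself anomalous, such windows are classified abnormal and
  flagged `degenerate`.
* **Hop.** Decisions default to every sample (`hop = 1`), matching
  real-time use; the trace records the 0-based index of each window's last
  sample, which is also the convention of the exported CSV and of all
  onset metadata.

A whole trial is labelled abnormal if *any* window is (`aggregate = "any"`,
the sensitive choice; `"majority"` is available). Trial-level scoring uses
abnormal as the positive class: accuracy, error rate (= 1 − accuracy),
sensitivity, specificity and generality (= 1 − specificity).

## The synthetic cohort

The recordings the detector was designed for — healthy adults walking
normally, then through scattered obstacles, 5 repetitions of 10 s each per
condition at 10 Hz — are not publicly deposited, so the package ships a
seeded simulator (`cohort_spec()`, `generate_cohort()`) that emulates the
protocol and makes every pipeline stage testable end to end.

Per subject, a gait signature is drawn once from the subject sub-seed: a
stride fundamental uniform in 0.8–1.2 Hz and, for each axis, 3 harmonic
amplitudes (vertical axis dominant, roughly 2.5 m/s² at the fundamental and
decaying with harmonic number, ~0.8 m/s² horizontally) with random phases.
A trial adds a random global phase, standard gravity (9.80665 m/s²) on the
vertical axis, and i.i.d. Gaussian sensor noise of 0.1 m/s². Abnormal
trials start from the *identical* base signal (same sub-seed, so a zero-
amplitude perturbation reproduces the normal trial exactly) and add
stumble-like transients: a Poisson stream of events at 1 event/s, each a
half-sine burst of 3 samples (0.3 s) on all three axes with amplitude 4
times the axis's oscillatory RMS, random sign and sub-sample phase jitter.
Onset indices are recorded in the recording metadata and the cohort
manifest.

These defaults were chosen once as a realistic caricature of lower-back
accelerometry — stumble impacts of a few times the walking oscillation
amplitude, sub-second duration, roughly one obstacle encounter per second —
and the only calibration target admitted for them is the separability
invariant the test suite enforces: per-subject NARX models trained on 3
normal trials must reach at least 0.9 trial-level accuracy under 10-fold
cross-validation on the default cohort. What the simulator does **not**
emulate is just as important for reading the test results: no stride-to-
stride timing variability, no slow drift or posture change, no sensor bias,
no confusable activities (running, stairs, sit-to-stand), and perturbations
that are additive bursts rather than biomechanical events. Passing the
suite therefore demonstrates that the pipeline is implemented correctly and
that the detector separates this family of signals; it is not a clinical
validation on real gait.

At 10 Hz with 3 harmonics of up to 1.2 Hz the highest harmonic (3.6 Hz) is
below the 5 Hz Nyquist limit, but a fourth harmonic would not be; the
default stays at 3.

## Evaluation harness

`cross_validate()` partitions all trials into seeded, label-stratified
folds (10 by default). Within each fold, each subject's model is trained on
up to 3 of that subject's normal trials *outside* the fold — 3 matching the
amount of training data the detector is designed to need — and every
in-fold trial is classified at trial level. Identical training sets across
folds are fitted once and reused (pure memoization). Subjects left without
an out-of-fold normal trial are skipped with a warning rather than
silently dropped.

`latency_study()` measures detection delay on abnormal trials: per trial,
the latency from a perturbation onset to the end of the first abnormal
window at or after it. The onset used is the first one at or after the
first decidable window end. The reason is structural: a sliding detector
emits no decision until one full FIT window of history exists, so an onset
inside that warm-up would charge the warm-up — a property of trial
segmentation, not of the detector — to the latency. In continuous
operation there is no warm-up after the first five seconds of wear. Trials
whose onsets all fall inside the warm-up are excluded and counted
separately. The study reports the median and 90th-percentile latency of
detected trials and the fraction undetected.

`scripts/acceptance.R` chains exactly these pieces — default cohort,
10-fold CV for both model classes, latency study — and writes the resulting
metrics as JSON; the README describes how to run it.

## Numerical choices and degenerate inputs

* Population (1/n) variance everywhere a variance appears (FIT, Hjorth
  activity, co-occurrence marginals); the z-scoring of training signals
  uses the sample standard deviation, as recorded in the model file.
* Derivatives are forward first differences scaled by the sampling rate;
  integrals (energy, signal magnitude area) use the trapezoidal rule.
* Constant (zero-variance) training signals are refused with a typed
  degenerate-signal error rather than producing a meaningless model;
  constant windows make Hjorth mobility/complexity and co-occurrence
  correlation `NA` rather than infinities.
* The co-occurrence matrix quantizes into `K = 8` equal-width bins over the
  window's observed range (a constant window occupies one bin), pairs at
  lag 1, directional (not symmetrized); correlation uses the standard
  deviations of the row/column marginals, the standard texture-analysis
  definition, which keeps it in $[-1, 1]$.
* Model files are versioned plain text with 17-significant-digit floats, so
  a save/load round trip is bit-exact; loading refuses unknown versions,
  truncated files and kind mismatches explicitly.
* Sub-seeds for subjects, trials and optimizer restarts are derived from
  the master seed with a small integer hash kept below $2^{31}$; all
  seeded code paths restore the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the full default cohort (31 subjects × 5 trials × 2
conditions, 100 samples per trial) for the end-to-end checks, 2 000
training samples for planted-model recovery, random inputs up to length
1 000 (100 draws) for the metric oracles, and 20 seeded small cohorts
(2 subjects × 3 trials) for the amplitude-monotonicity property. These
sizes were chosen so that each property is tested at a scale where its
failure modes can actually appear — several full windows per trial, enough
training data to saturate the optimizer — while the whole suite stays quick
to run.

## Known limitations

* The detector is per-subject by design: a model identified on one person
  does not transfer, and three 10-s normal trials are assumed available per
  subject.
* FIT with the prediction-variance denominator is asymmetric: a model that
  predicts an almost-flat signal inflates |FIT| through a small
  denominator. The degeneracy flag catches the exact zero-variance case
  only; the `"measured"` denominator flag exists to probe sensitivity.
* The NARX objective is nonconvex; three restarts make bad local optima
  rare on gait-like signals, not impossible. `train_meta$vn` records the
  achieved objective so outliers are visible.
* The simulator's abnormality model is additive and stationary; detectors
  tuned on it should be re-validated on real accelerometry before any
  clinical use.
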