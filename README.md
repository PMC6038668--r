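# gaitnarx

Real-time abnormal-gait detection from wearable accelerometer data, for
researchers and engineers building fall-risk monitors. The package
identifies a **per-subject NARX model of normal walking** from a few
10-second recordings and then classifies sliding windows of new walking
data as normal or abnormal by thresholding the **FIT** of one-step-ahead
predictions — no feature engineering and no trained classifier at run time,
which keeps the detector cheap enough for continuous on-device use.

## The model

The scalar acceleration signal (by default the orientation-robust magnitude
channel of a lower-back tri-axial accelerometer at 10 Hz, z-scored) is
modelled as an autonomous nonlinear autoregression over its last *n*
samples, with a sigmoid basis-function expansion:

    ŷ(t) = c₀ + Σᵢ₌₁..r αᵢ σ(βᵢ · [y(t−1), …, y(t−n), 1]),   σ(z) = 1/(1+e⁻ᶻ)

fitted by the least-squares prediction-error criterion (seeded,
deterministic multi-start BFGS). The operating point is order *n* = 10 and
*r* = 20 basis functions; a linear AR variant (`fit_arx`) is included for
comparison. Over each sliding window the detector computes

    RMSE = √(1/n Σ (ŷᵢ − yᵢ)²),   FIT = 1 − RMSE / sd_pop(ŷ)

and declares the window abnormal when FIT < 0.02 (10-sample prediction
window, 50-sample FIT window, decision every sample). A trial is abnormal
if any window is. The package also ships the classical comparator feature
set (Hjorth parameters, signal energy, SMA/SMV, peak statistics,
co-occurrence matrix features), a seeded synthetic gait simulator
emulating the normal/obstacle-walk protocol, an evaluation harness
(stratified k-fold cross-validation, detection-latency study), and a CLI
(`inst/cli/gaitnarx.R`).

## Worked example

Train a subject's model on three synthetic normal walks, then classify a
held-out normal and an abnormal (obstacle-perturbed) trial:

```r
library(gaitnarx)

spec  <- cohort_spec(seed = 42)                       # 10 s trials @ 10 Hz
train <- lapply(1:3, function(tr) generate_normal(spec, 1, tr))
model <- train_gait_model(train, method = "narx", seed = 7)
model
#> <narx_model> order=10 r=20 basis=sigmoid fs=10 Hz, V_N=0.00209431 (n=270)

res_n <- classify_trial(model, generate_normal(spec, 1, 4))
res_a <- classify_trial(model, generate_abnormal(spec, 1, 4))
c(res_n$decision, res_a$decision)
#> [1] "normal"   "abnormal"
range(res_n$trace$fit); min(res_a$trace$fit)
#> [1] 0.8928778 0.9623455
#> [1] -0.4228279
```

The normal trial's FIT stays near 1 in every window (the model explains it
well); the perturbed trial drives FIT far below the 0.02 threshold. The
training objective `V_N` ≈ 0.002 is the mean squared one-step error on the
z-scored training signal. Latency from a perturbation onset to the first
abnormal window end is reported in seconds:

```r
trace <- res_a$trace
onset <- generate_abnormal(spec, 1, 4)$meta$onsets
detection_latency(trace, onset[onset >= trace$end_index[1]][1])
#> [1] 0
```

— here the window ending at the onset sample is already abnormal (earlier
perturbations in the same 5 s FIT window), so the detection delay is zero.

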