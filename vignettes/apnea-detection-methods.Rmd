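---
title: "Detecting sleep apnea from a single-lead ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from a single-lead ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneanet)
```

## The problem

Obstructive sleep apnea (SA) is conventionally diagnosed with overnight
polysomnography, which is expensive and uncomfortable. A long-standing
alternative is to screen from a single-lead ECG: repetitive apneas imprint a
characteristic slow cyclic pattern on heart rate (a bradycardia–tachycardia
cycle with a period of tens of seconds) and modulate R-wave amplitude
through respiratory effort. `apneanet` implements a complete
minute-by-minute screening pipeline around these two signals:

1. **Per-segment detection** — label every one-minute ECG segment apnea
   (`"A"`) or normal (`"N"`).
2. **Per-recording diagnosis** — aggregate the minute labels into the
   apnea–hypopnea index, `AHI = 60/T * n` (with `T` annotated minutes and
   `n` apnea minutes), and call a recording SA when `AHI > 5`.

Two classifier families share the same preprocessing front end: a compact
1-D convolutional network that learns its own features from the raw
RR/amplitude window, and four classical models (SVM, logistic regression,
KNN, MLP) over 18 hand-crafted heart-rate-variability features.

## Preprocessing

For each labeled minute we process the minute *plus two minutes of context
on each side* (adjacent segments are informative because apnea episodes
span minute boundaries):

* **R-peak detection.** A Hamilton-style chain: zero-phase Butterworth
  band-pass 8–16 Hz, differentiation, rectification, 80 ms moving-window
  integration, adaptive dual-level thresholding (threshold coefficient
  0.3125, running signal/noise levels with 1/8 update weight) with a 200 ms
  refractory period, then refinement to the raw-signal maximum near each
  detection. The detector is pluggable: everything downstream consumes only
  peak times and amplitudes.
* **RR and amplitude series.** `rr[i] = t[i+1] − t[i]`, timestamped at the
  *later* peak (the interval exists only once its closing beat has
  occurred); the amplitude is the raw signal value at that peak, with no
  baseline correction.
* **Artifact removal.** A local-median rule: an interval deviating from the
  median of its centered 5-point window by more than 20% of that median is
  replaced by the median. We iterate this rule to a fixed point (it
  converges in a pass or two in practice), which makes the operation
  idempotent and absorbs short runs of adjacent outliers, not just isolated
  ones. Amplitudes are never altered and series length is preserved, so
  minute alignment survives.
* **Uniform resampling.** Natural cubic splines map both channels onto a
  3 Hz grid: 900 points per channel over each 5-minute window. 3 Hz is the
  unique rate consistent with 900 points over 300 s; it is comfortably
  above twice the highest HRV band edge (0.4 Hz). Grid points outside the
  support range are held at the nearest support value — no polynomial
  extrapolation — which doubles as the boundary-padding rule for the
  first/last two minutes of a recording. We keep those edge minutes (rather
  than dropping them) because the per-recording AHI needs a prediction for
  every annotated minute.

Tunable parameters, with defaults: grid rate 3 Hz; context ±2 minutes;
median window 5, tolerance 0.2; detector passband 8–16 Hz, integration
80 ms, refractory 200 ms.

## The 1-D convolutional network

The classifier is a LeNet-style 1-D CNN consuming the 900×2 window
(RR, amplitude):

| Layer    | Parameters                  | Output shape | Trainable values |
|----------|-----------------------------|--------------|------------------|
| Input    | –                           | (900, 2)     | 0 |
| Conv1    | 32 filters, kernel 5, stride 2 | (448, 32) | 352 |
| MaxPool2 | pool 3, stride 3            | (149, 32)    | 0 |
| Conv3    | 64 filters, kernel 5, stride 2 | (73, 64)  | 10,304 |
| MaxPool4 | pool 3, stride 3            | (24, 64)     | 0 |
| Dropout5 | drop probability 0.8        | (24, 64)     | 0 |
| FC6      | 32 units, ReLU              | (32,)        | 49,184 |
| Output   | 2 units, softmax            | (2,)         | 66 |

59,906 parameters in total. The shape arithmetic
(`floor((L + 2p − k)/s) + 1`) and the per-layer counts are exposed as data
(`model_shapes()`, `count_parameters()`) so they can be checked without
running any training. Kernels described as "5 × 2" are one-dimensional
kernels of width 5 spanning both input channels; the second convolution
spans all 32 incoming feature maps (its 10,304-parameter count,
64 × (5 × 32) + 64, confirms full-channel fan-in). "Drop rate 0.8" is read
as drop *probability* 0.8 — the aggressive setting that regularizes the
relatively small training cohorts this method targets.

Training minimizes the categorical cross-entropy
$J = -\frac{1}{N}\sum_l \sum_k y_{lk}\log \hat y_{lk}$, with
$\hat y_{lk} = e^{z_k} / \sum_i e^{z_i}$, by minibatch backpropagation.
The implementation is a self-contained matrix-based CPU network (im2col
convolutions, exact gradients — verified against finite differences in the
test suite) so the package has no deep-learning-framework dependency.

Choices the architecture table leaves open, fixed as follows:

* **Conv activations.** ReLU after each convolution (the table lists an
  activation only for FC6); standard for this family and parameter-neutral.
* **Initialization.** He-scaled Gaussian weights, zero biases; the softmax
  head starts with small (sd 0.01) weights so the untrained network
  predicts near-uniform probabilities and the pre-training loss sits at
  $\log 2$ for balanced data.
* **Input scaling.** Channels are standardized with training-set mean/SD
  (stored on the model, applied at inference); pure conditioning, the
  architecture is unchanged.
* **Optimizer.** Adam, learning rate 1e-3, batch 128, up to 100 epochs,
  early stopping on a 10% seeded validation split with patience 10. No
  training hyperparameters are canonical for this architecture; all are
  exposed via `train_config()`. Class reweighting is available but off by
  default.
* **Determinism.** One integer seed fixes initialization, shuffling,
  validation split and dropout masks; seed-fixed reruns are bit-identical.
* **Decision rule.** Hard labels at probability 0.5; ROC analysis uses the
  continuous apnea probability.

## The hand-crafted feature baseline

Eighteen features per window, twelve from RR intervals and six from
amplitudes:

* Time domain (RR only): RMSSD; SDNN; NN50; pNN50; mean RR; mean HR.
  **Convention note:** we compute SDNN as the standard deviation of
  *successive differences* by default — the definition spelled out in the
  screening literature this feature set derives from — with
  `sdnn_convention = "classic"` available for the usual
  standard-deviation-of-intervals reading. pNN50 divides by the number of
  intervals, and NN50 uses a strict `> 50 ms` inequality.
* Frequency domain (RR and amplitude channels): normalized VLF, LF, HF
  band powers, LF/HF, LF/(LF+HF), HF/(LF+HF). Band edges are the standard
  short-term HRV bands — VLF [0.003, 0.04), LF [0.04, 0.15),
  HF [0.15, 0.4) Hz — estimated by Welch's method on the 3 Hz interpolated
  series (Hamming window, segment 256, 50% overlap), powers normalized by
  the VLF+LF+HF total. The estimator and band edges are config-exposed;
  neither is canonical for this problem.

Features are computed over the full 5-minute window, matching the CNN's
input span, so the two families see the same information. Min-max
normalization $x^* = (x - x_{\min})/(x_{\max} - x_{\min})$ is fit on
training rows only; zero-range columns map to 0 and test values may leave
$[0,1]$ (no clipping). Baselines: RBF-SVM (cost 1), ridge logistic
regression ($\lambda = 0.01$), KNN ($k = 5$), one-hidden-layer MLP
(32 units) — none of these hyperparameters is prescribed by the method;
the defaults are ordinary practice and all are exposed.

## Annotation handling and severity classes

Continuously annotated recordings (event start + duration) are converted to
minute labels with the 5-second rule: minute `m` (half-open
`[60m, 60(m+1))`, 0-based) is apnea iff some *single* event overlaps it for
at least 5 s. Two disjoint 3-second events in one minute therefore do
**not** make it an apnea minute — the literal per-event reading; the union
reading is equally defensible but not what the rule's wording says.
Recordings are truncated to whole minutes.

Severity classes: A when `AHI ≥ 10` and `n ≥ 100` apnea minutes; B when
not A, `AHI ≥ 5` and `n ≥ 5`; C otherwise. The customary statement of
class B adds an upper bound `n ≤ 99`, which leaves unclassifiable corners
at extreme (duration, count) combinations never seen in overnight
recordings; folding the bound into "not A" makes the three rules a true
partition while agreeing with the customary rules on all realistic inputs.

## Evaluation

Per-segment: specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, accuracy
`(TP+TN)/(TP+TN+FP+FN)` (apnea positive), and AUC in the Mann–Whitney rank
form, which equals the trapezoidal area under the tie-rank-averaged ROC.
Zero denominators flag a metric `NA` rather than erroring. Per-recording:
the AHI > 5 rule applied to predicted and expert labels alike, plus the
Pearson correlation between estimated and reference AHI (the convention in
this literature; Spearman would hide calibration errors). Cross-validation
folds at the *recording* level — no minute of a test recording can reach
training — with the fold assignment returned so leakage is auditable.
Stratification by severity class is deliberately off by default (plain
random grouping is what the evaluation design this mirrors states).

## The synthetic cohort

Real benchmark recordings cannot ship with the package, so a simulator
provides ground-truthed input for every stage. It emulates exactly the two
correlates the pipeline exploits: within apnea minutes, the instantaneous
heart rate carries a sinusoidal swing (default ±15 bpm, period 45 s — a
1/45 ≈ 0.022 Hz line in the VLF range of the RR spectrum) and the R-peak
amplitude is modulated by ±35%; all minutes carry per-beat Gaussian HR
jitter (SD 2 bpm). Beats are placed by integrating the instantaneous rate
and rendered as a fixed narrow biphasic QRS-like template (peak 1.0) on
Gaussian noise (SD 0.05), 100 Hz sampling, baseline 75 bpm. Apnea minutes
are grouped into contiguous blocks and also emitted as event intervals;
converting those events back through the 5-second rule reproduces the
minute labels exactly. Cohorts draw per-recording apnea-minute counts from
the range realizing a requested severity class (class A needs ≥ 100 apnea
minutes, hence recordings of at least 100 minutes).

What the simulator does *not* emulate: realistic P-QRS-T morphology,
ectopic beats, electrode artifacts, sleep-stage structure, hypopnea/apnea
distinctions, or the weak and variable signatures of real patients. The
synthetic signature is strong and stationary by design. Passing the
end-to-end tests therefore demonstrates that the pipeline is wired
correctly and can recover a planted apnea signature — not that it attains
any particular accuracy on clinical data; benchmark-scale performance
requires the real recordings, which the user must fetch themselves.

## Numerical and degenerate-input behaviour

* Softmax subtracts the row maximum (shift-invariant, overflow-safe);
  cross-entropy clamps probabilities at 1e-12.
* A constant channel has zero oscillatory power: spectral features return
  all zeros with a warning rather than 0/0.
* Zero confusion-matrix denominators yield `NA` metrics with a warning.
* An all-zero ECG yields an empty peak series (not an error); fewer than
  two peaks, a sub-2 s signal, or a sub-5-minute recording are validation
  errors.
* Max-pooling breaks ties toward the earliest position; `knn` tie-breaks
  are seeded.
* Windows with fewer than four supporting beats raise an error naming the
  minute.

## Problem sizes used in the shipped checks

The packaged tests and the reproduction script run entirely on simulated
data at sizes chosen to exercise every code path at interactive speed: a
20-recording, 60-minute-per-recording cohort (1,200 windows; 12 recordings
train / 8 test) for the end-to-end run with the CNN capped at 30 epochs;
5-minute recordings across 40–120 bpm for detector recovery; 10–12-minute
recordings for unit-level pipeline checks. At these sizes the full suite
and the reproduction script each complete in a few minutes on one CPU.

## Known limitations

* The CNN implementation is plain R linear algebra: ample for cohorts of
  this scale, but training on the full 70-recording overnight benchmark
  (~30k windows) would take hours, not minutes.
* The simulator's strong stationary signature makes the synthetic task far
  easier than clinical screening; reported synthetic accuracies are
  pipeline checks, not clinical estimates.
* Only obstructive-style cyclic signatures are modelled; central events
  (which lack the effort-driven amplitude modulation) are not represented.
* WFDB support covers header + signal formats 16 and 212, single channel
  extraction — enough for the apnea benchmarks, not a general WFDB stack.
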