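---
title: "Pre-impact fall-from-height risk prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-impact fall-from-height risk prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Falls from height (FFH) are the dominant cause of fatal accidents on
construction sites. A wearable inertial measurement unit (IMU) on the
worker's upper back senses 3-axis acceleration (g) and 3-axis angular
velocity (deg/s) at 100 Hz. Because injury severity scales with the impact
peak acceleration, a useful early-warning signal is a *predicted* peak: a
regressor that, from the half second of motion observed 0.7 s to 0.2 s
before the impact, estimates how hard the impact will be. Thresholding the
predicted peak at 9 g separates high-hazard falls from height from ordinary
work movements and low-hazard ground-level falls, leaving roughly 0.2 s of
lead time for protective actuation.

`ffhrisk` implements that pipeline end to end: a synthetic-data generator
standing in for a private laboratory dataset, sum-vector-magnitude feature
extraction and windowing, four small neural regressors, grid search,
and threshold-based risk evaluation.

## Signals and features

At each sample the two magnitude features are

$$A_{SVM} = \sqrt{Acc_x^2 + Acc_y^2 + Acc_z^2}, \qquad
  G_{SVM} = \sqrt{Gyro_x^2 + Gyro_y^2 + Gyro_z^2},$$

and each model consumes the 8 channels (AX, AY, AZ, ASVM, GX, GY, GZ, GSVM)
over the 50 samples from 0.7 s to 0.2 s before the $A_{SVM}$ peak
(half-open sample interval $[p-70, p-20)$ at 100 Hz). The regression target
is the true peak $A_{SVM}$ in g. The peak is defined as the global maximum
of $A_{SVM}$ over the trial, earliest sample on exact ties, and one window
is taken per recording; recordings with fewer than 70 samples of pre-peak
history are rejected with an explicit error rather than padded.

## What the synthetic generator emulates

The study design it stands in for comprises 25 movement types: 15 non-fall
work movements (`NF01`--`NF15`), 5 low-hazard ground-level falls
(`LF01`--`LF05`) and 5 falls from height (`HF01`--`HF05`), with 20 human
subjects performing each human movement three times and an anthropomorphic
dummy performing the 2 m and 3 m falls five times each (falls from 2 m and
above are unsafe for human subjects). The default
`dataset_spec()` therefore yields 1260 human and 20 dummy recordings.

Per movement, the generator draws the impact peak from a truncated normal
whose bounds encode the published per-category ranges: NF 1--4 g (NF15, a
0.7 m jump, 5--9 g), LF01/02/05 4--9 g, the slips LF03/04 10--13 g, HF
9--16 g, with forward falls 2 g above vertical falls of equal height
(feet-first landings transfer less mechanical energy to the trunk sensor).
Only these ranges are published numerically, so a bounded unimodal family is
the minimal assumption; the per-movement means and SDs inside those bounds
are this package's own calibration and are overridable via
`dataset_spec(overrides=)`.

The waveform family is intentionally simple:

* **Baseline**: gravity projected on a slightly tilted axis (about 1 g)
  plus moving-average-smoothed Gaussian noise (SD 0.05 g).
* **Activity**: movement-specific low-frequency oscillations (0.4--3.8 Hz,
  one characteristic frequency per movement) whose amplitude scales with
  the drawn peak — more violent pre-impact motion precedes harder impacts.
  For free-fall movements this coupling is capped at 1.5 g: their severity
  is carried by the fall height instead.
* **Free fall**: for falls from height (and the NF15 jump), specific force
  near zero for $\sqrt{2h/9.81}$ s immediately before impact (0.64 s at
  2 m, 0.78 s at 3 m). During this phase forward falls tumble (gyro bursts
  at the profile's intensity, up to 360 deg/s) while vertical falls rotate
  little (≤ 50 deg/s); this gyro signature is what distinguishes the 0.7 m
  forward fall `HF03` from the 0.7 m jump `NF15`, whose windows are
  otherwise similar.
* **Impact**: a 30 ms half-sine pulse whose apex realizes the drawn peak
  exactly; the rest of the trace is capped at $1 + 0.9(P-1)$ g, strictly
  below the drawn peak $P$, so peak picking always recovers the drawn
  value and the peak-containment property holds by construction, not just
  in expectation.
* **Ringing**: decaying post-impact oscillation, then rest.

Seeding is hierarchical: the master seed plus a deterministic hash of
(movement, subject, trial) gives every recording an independent substream,
so generation order is irrelevant and equal specs reproduce byte-identical
CSVs.

What the generator does **not** emulate: validated human-body dynamics, a
real IMU's noise spectrum, sensor saturation or drift, or inter-subject
biomechanical variation beyond randomized phases and amplitudes. Passing
tests on this data demonstrates that the pipeline is implemented correctly
and that severity information present in pre-impact dynamics is
recoverable; it does not certify performance on real falls.

## The regressors

All four architectures map a 50 × 8 window to one linear output unit
(predicted peak, g), with ReLU convolutional activations, dropout 0.25
immediately before the output, batch size 1, and Adam at learning rate
1e-3 (the optimizer is unspecified in the protocol this follows; Adam at
its default rate is the de-facto choice for small networks and is recorded
in the config):

* **1D-CNN** — two blocks of (Conv1D, kernel 2, stride 2; max-pool 2),
  time axis 50 → 25 → 12 → 6 → 3, flatten, dropout, output.
* **2D-CNN** — the window as a 50 × 8 × 1 image; two blocks of (Conv2D,
  kernel (4,4), stride (2,2), same padding; max-pool (2,2)):
  50×8 → 25×4 → 12×2 → 6×1 → 3×1.
* **LSTM** — two stacked LSTM layers over the full 50-step sequence, the
  second returning its last state.
* **Conv-LSTM** — the 1D-CNN convolution stack producing a 3-step feature
  sequence, then two stacked LSTM layers.

Training schedules: 200 epochs with early-stopping patience 100 for the
CNNs; 50 epochs with patience 10 for the recurrent models. Early stopping
monitors the loss on a seeded 20% validation subset of the training
windows (stratified by movement category) and restores the best-epoch
weights. Both training losses are supported: MAE (g) and MSE (g²).

Because no deep-learning framework is available to this package, the layers,
backpropagation and Adam are implemented directly in vectorized base R; the
analytic gradients of every architecture are verified against central finite
differences in the test suite (relative tolerance 1e-4).

Numerical and design choices worth knowing:

* **Pooling at width 1.** No single padding rule makes the published 2D
  dimension trace consistent (valid pooling collapses the width-1 axis,
  same pooling gives 25 → 13). Pool output dims are therefore
  `max(floor(dim/2), 1)`: valid truncation everywhere, pass-through on an
  axis already reduced to one element. This reproduces the trace
  50×8 → 25×4 → 12×2 → 6×1 → 3×1 exactly.
* **Output activation** is identity: targets (up to ~16 g) exceed any
  bounded range and ReLU is specified for hidden layers only.
* **Dropout** (rate 0.25, inverted) is applied uniformly in all four
  architectures on the flattened pre-output features.
* **Initialization** is seeded Glorot-uniform with forget-gate biases of 1;
  repeatability is promised per machine, not bit-exact across BLAS builds.
* **Input scaling.** Window extraction keeps raw amplitudes by default, and
  per-channel z-scoring (fitted on training windows only) is available as
  `fit_normalizer()`/`apply_normalizer()`. The `run_config()` pipeline
  enables it by default: the gyro channels are two orders of magnitude
  larger than the acceleration channels, and batch-size-1 first-order
  training on the raw mixture does not converge in the configured budgets.
* **Grid search** enumerates both layer sizes of the CNNs and the LSTM over
  {8, 16, 32, 64} and the four Conv-LSTM sizes over {16, 64} (16
  combinations each), trains every point with a shared seed and identical
  validation split, and selects by *validation* error — never by test
  error, which would leak the held-out split into model choice. Ties go to
  the configuration with fewer parameters, then lexicographically smaller
  sizes. When the grid is off, the defaults are the best-performing
  combinations for this task: 1D-CNN (16, 16), 2D-CNN (32, 16), LSTM
  (8, 16), Conv-LSTM (64, 64, 64, 16).

## Evaluation

Regression error is reported as MAE (g) and MSE (g²); the report writer
asserts the Jensen inequality MAE ≤ √MSE as a self-check. Risk
classification thresholds both the measured and the predicted peak at 9 g
(boundary inclusive): the measured label is the ground truth, so a
low-hazard slip whose measured peak reaches 10 g counts as a positive
regardless of its movement category — the hazard criterion is impact
severity, not choreography. Sensitivity, specificity and accuracy are
percentages; a metric with a zero denominator (e.g. sensitivity on a split
with no positives) is reported as `NA` and flagged in `undefined` rather
than silently zeroed. Per-movement tables give mean ± SD (n−1 denominator,
`NA` at n = 1) of true and predicted peaks.

The train/test split assigns 70% of human and 60% of dummy recordings to
training, stratified by movement code (floor rule per stratum) so that the
rare dummy movements are never starved from either side.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery completes in minutes on one core: generator
calibration on the full default dataset (1280 recordings), model unit tests
on 25–200 windows, and the end-to-end recovery run on 4 subjects (272
recordings, 180 training windows). At that scale the 1D-CNN and Conv-LSTM
trained with MAE reach held-out MAE well under 1 g and threshold accuracy
above 90%, with the LSTM consistently the weakest of the three — the same
qualitative ordering the full-scale study design motivates. Every stage is
driven by explicit seeds; a full `ffh_run()` rerun with equal seeds
produces byte-identical summary CSVs on the same machine.

## Known limitations

* The generator's waveform family is a deliberate simplification; its
  within-movement severity signal (activity amplitude coupled to the drawn
  peak) is stronger and cleaner than anything a real sensor provides, so
  absolute error levels here are optimistic.
* Free-fall physics uses the ideal point-mass drop time; air drag, body
  rotation during the fall and harness effects are ignored.
* One window per recording; trials with multiple impacts are summarized by
  their global peak only.
* Cross-platform bit-reproducibility of training is not guaranteed
  (floating-point accumulation order differs across BLAS libraries).
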