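---
title: "Methods: multi-scale multi-task blood-pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale multi-task blood-pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstbp)
```

## The problem and the model

Cuff-less continuous blood-pressure (BP) estimation asks for beat-scale
systolic (SBP), diastolic (DBP) and mean arterial pressure (MAP) from two
non-invasive waveforms — the electrocardiogram (ECG) and the
photoplethysmogram (PPG) — using the invasive arterial pressure trace (ABP)
only to supply reference labels during training. The estimator here is a
one-dimensional convolutional network that reads an 8-s, two-channel
(ECG, PPG) segment of 1000 samples at 125 Hz and regresses the three
pressures jointly:

$$z_i^{\mathrm{SBP}},\, z_i^{\mathrm{DBP}},\, z_i^{\mathrm{MAP}}
   = F(x_i;\theta),$$

with a shared trunk and a single 3-neuron output, trained on the joint
mean-squared-error loss

$$\mathrm{MSE} = \frac1n \sum_i \big[(y_i^{\mathrm{SBP}}-z_i^{\mathrm{SBP}})^2
  + (y_i^{\mathrm{DBP}}-z_i^{\mathrm{DBP}})^2
  + (y_i^{\mathrm{MAP}}-z_i^{\mathrm{MAP}})^2\big]$$

plus an L2 penalty $\lambda \sum w^2$ on convolution and dense weights.
Multi-task output shares every feature between the three pressures, which
regularizes each task and gives all three values in one forward pass.

The architecture is multi-scale: after a shared stem (kernel-15
convolution, 3-wide max-pool), three parallel streams with kernel sizes 5,
7 and 9 observe the same features at different receptive fields. Each
stream stacks four modules of two convolutions (filters 64/128/256/512),
each convolution followed by batch normalization and a ReLU; global average
pooling and a 512-wide dense layer close each stream, so the concatenation
presents $3 \times 512 = 1536$ features to the 256-wide head and the
3-neuron output.

```{r trace}
model <- build_mstnet(mstnet_config(), seed = 1)
model$trace
```

### Choices the architecture description leaves open

The published layer table specifies kernels and filter counts but neither
strides, padding, nor the stem's filter count. The package's choices, all
configurable through `mstnet_config()`:

* **Temporal downsampling.** The first convolution of each module uses
  stride 2 (the rest stride 1 with same-length zero padding), giving the
  standard pyramid 1000 → 333 → 167 → 84 → 42 → 21 time steps before
  global pooling.
* **Global average pooling.** The table's penultimate "average pool" row is
  read as adaptive pooling to temporal length 1. A kernel-1 average pool
  would be the identity and would leave the following 512-wide dense layer
  acting on an input whose width depends on the segment length — inconsistent
  with a fixed 1536-feature concatenation.
* **Shared stem.** The stem rows sit above the stream split in the layer
  table, so one stem feeds all three streams; its filter count (unstated)
  defaults to 32.
* **Max-pool stride.** Non-overlapping (stride = pool size = 3).
* **L2 scope.** The penalty covers convolution and dense weights only;
  biases and batch-norm scale/shift are excluded, since shrinking
  normalization statistics does not reduce the complexity of the mapping.
* **Initialization.** Kaiming fan-in initialization, seeded; the output
  layer uses a smaller (linear-layer) scale, and training can start its
  bias at the mean of the training labels so optimization begins at the
  label scale rather than at zero.

The learning-rate schedule is a stepped decay,
$\mathrm{lr} = \mathrm{lr}_{\mathrm{base}} \cdot
\gamma^{\lfloor \mathrm{epoch}/5 \rfloor}$, read with the floor convention
("decayed once every 5 epochs"); the continuous reading would decay every
step and contradicts the stated block behavior. The decay factor
$\gamma$ and the L2 coefficient $\lambda$ have no published values; the
package defaults, $\gamma = 0.5$ and $\lambda = 10^{-4}$, are package
choices surfaced in `train_config()`.

## Preprocessing

`build_segments()` composes the pipeline per record:

1. **Segmentation** into non-overlapping 8-s windows (1000 samples), all
   three channels cut synchronously, trailing partial window dropped.
2. **Beat detection on the raw ABP** (`detect_abp_beats()`). Candidate
   peaks are strict local maxima. A greedy highest-first pass suppresses
   any candidate within 0.6 s of a higher retained peak — this is the
   peak-to-peak time limit that removes dicrotic ("false") peaks, which sit
   0.2–0.4 s after the true systolic peak. Peaks must lie in [80, 180]
   mmHg, troughs (the minimum between consecutive retained peaks) in
   [60, 130] mmHg; a window containing any out-of-range beat is dropped.
   The candidate finder and the suppression order are unspecified in the
   source description; greedy highest-first is deterministic and
   order-independent.
3. **Labels** (`extract_labels()`): SBP and DBP are the arithmetic mean of
   the window's peak and trough values (median available); MAP =
   (SBP + 2·DBP)/3. Whether a multi-beat window should be summarized by
   mean, median or per-beat replication is never stated; the mean is the
   unbiased summary of an 8-s window.
4. **Wavelet denoising** (`dwt_denoise()`) of ECG (7 levels) and PPG
   (8 levels) with the Daubechies-8 wavelet: the level-1 detail band and
   the deepest approximation band are zeroed, remaining detail bands are
   soft-thresholded, and the signal is reconstructed. At 125 Hz the zeroed
   bands are the exact dyadic bands 31.25–62.5 Hz (high-frequency noise)
   and 0–0.49 Hz / 0–0.24 Hz (baseline drift for 7 and 8 levels). Printed
   band edges elsewhere ("31.125–62.25", "0–0.5", "0–0.25") are rounded
   descriptions of these dyadic bands; the level counts are the operative
   specification. The soft threshold is the universal threshold
   $\sigma\sqrt{2\ln N}$ with $\sigma$ = MAD(level-1 details)/0.6745, the
   standard wavelet-denoising default, since no magnitude is published.
   Boundary handling uses symmetric signal extension; with thresholding and
   band-zeroing disabled the transform round-trips to machine precision.
5. **Amplitude normalization** (`layer_normalize()`):
   $2(x - x_{\min})/(x_{\max} - x_{\min}) - 1$ per channel per segment, so
   every channel spans exactly [-1, 1]. Constant channels are rejected.

Whether denoising precedes or follows segmentation is ambiguous in the
source pipeline figure; the package denoises per segment after cutting
(both orders are supported through the public functions). Segments are
non-overlapping; indices are 1-based throughout, following R convention.
A record-level minimum-duration gate (default off; 480 s reproduces the
whole-record screening used for clinical data) is available for long
recordings.

## The synthetic generator

`generate_record()` produces the study conditions for every test: a pulse
train whose k-th beat is a raised-cosine systolic upstroke and diastolic
decay plus a Gaussian dicrotic bump, rescaled per beat so the requested
per-beat SBP/DBP are attained *exactly* (to machine precision) at the
annotated peak and onset trough. The ECG is a triangular R-spike train
(with small P/T bumps) preceding each ABP peak by a pulse-transit delay;
the PPG is a low-pass-filtered, delayed, rescaled copy of the pulse train.
The channels are morphologically distinct periodic signals — which is what
the network consumes — not clinically realistic waveforms.

Defaults: 125 Hz, 75 bpm, SBP 120 / DBP 80 mmHg, dicrotic bump at 0.25 s
after the peak with relative amplitude 0.1 (a shoulder on the decay; a
`false_peak_boost` raises it into a genuine local maximum, the false-peak
mechanism), pulse-transit delay 0.2 s. `make_dataset()` samples heart rate
uniformly from 60–100 bpm and pressures from the label windows the
pipeline accepts (SBP [80, 180], DBP [60, 130] mmHg) with ±2 mmHg per-beat
jitter. Injectable artifacts target exactly the bands the denoiser
removes: sinusoidal drift below 0.5 Hz and a tone above 31 Hz.

What passing tests on these signals do show: the pipeline's contracts
(segmentation arithmetic, false-peak suppression, exact label recovery,
band removal, shape propagation, convergence of the optimizer) hold on
well-posed periodic input with known ground truth. What they do not show:
robustness to arrhythmia, motion artifacts, sensor saturation, pulse-shape
pathology, or distribution shift in real intensive-care waveforms —
clinical accuracy claims require the external clinical dataset and are out
of scope here.

## Training and validation

`train_mstnet()` minimizes the joint loss with Adam (moment coefficients
0.9/0.999, $\varepsilon = 10^{-8}$ — conventional values, unstated in the
source), shuffling every epoch under the run seed; runs are bit-reproducible
with a fixed seed and single-threaded BLAS. After the final epoch the
batch-normalization running statistics are recomputed in one pass over the
training set ("precise" batch-norm, `train_config(recalibrate_bn = TRUE)`):
with small batches the exponential running estimates lag the final weights,
and evaluation-mode predictions would otherwise be measurably worse than
the training-mode fit. The reference recipe (batch
100, 150 epochs, initial rate 0.01) is the `train_config()` default.
Validation loss is computed on a 10% hold-out of the training fold — the
source plots a validation curve but never defines its origin. Early
stopping is deliberately absent (fixed-epoch training).

`cross_validate()` implements five-fold cross-validation at the segment
level ("randomly divided into five equal-sized subsets"), with an optional
subject-grouped mode that is stricter than the reference protocol:
segment-level splits let segments of one subject appear in both train and
test folds, a known leakage concern that the reference protocol does not
resolve.

The test suite exercises training at desk scale: an overfit check drives a
reduced-width model (filters 8/16/32/64, 64-wide dense layers — same depth,
narrower) to memorize 32 synthetic segments within 200 epochs, using a
training recipe sized to that problem (batch 8, initial rate 0.005,
$\gamma = 0.95$, no weight penalty), reaching a joint training loss below
1 mmHg²; the smoke cross-validation uses a deliberately tiny network and
2 epochs per fold so the full generate → preprocess → cross-validate →
evaluate chain runs in seconds. These problem sizes are
the package's chosen desk-scale study conditions; the published clinical
accuracies (MAE ≈ 2–4 mmHg on 21,334 segments from 514 subjects) require
the external clinical dataset and long training, and the package makes no
attempt to reproduce them.

## Evaluation

`evaluate_model()` reports, per task: Pearson r, mean error
ME = mean(y − z) (note the orientation: positive ME means the estimator
runs low), MAE, and the error SD. The printed SD formula subtracts the ME
(defined as mean(y − z)) from the differences z − y, which double-counts
the bias; the package computes the sample standard deviation of the signed
differences about their own mean — the quantity Bland–Altman limits and
device standards actually use — and keeps the literal variant behind
`error_sd(..., literal = TRUE)` for audit.

The AAMI verdict requires |ME| ≤ 5 mmHg, SD ≤ 8 mmHg and ≥ 85 subjects,
all bounds inclusive as printed. BHS grading computes cumulative
percentages of absolute errors within 5/10/15 mmHg and awards the best
grade whose all three thresholds are met (A: 60/85/95, B: 50/75/90,
C: 40/65/80); the package emits "D" below grade C, a case the published
table does not list. Bland–Altman summaries use mean difference ±
1.96·SD, and error histograms use 1-mmHg bins over [−20, 20] mmHg (the
source shows histograms "concentrated around 0" without a bin
specification).

## Numerical notes and limitations

* The wavelet bank stores only the published 16-tap Daubechies-8 analysis
  low-pass filter; the other three filters follow from the
  quadrature-mirror relations. Multi-level analysis refuses depths whose
  step inputs no longer cover the filter support, reporting the minimum
  length.
* Batch normalization uses per-channel statistics over (batch × time) with
  momentum 0.1 running estimates (unbiased variance), matching common
  deep-learning practice; evaluation mode is deterministic.
* Convolutions are evaluated as BLAS matrix products against a sparse
  im2col gather built once per layer, so CPU training of the desk-scale
  configurations stays within seconds per epoch.
* Ties in peak detection (plateau maxima) are broken toward the earlier
  sample; exact plateaus have measure zero in the synthetic signals and
  are rare in floating-point clinical data.
* Record I/O is plain-text CSV (`t, ecg, ppg, abp`); segment datasets are
  CSV pairs (labels + flattened signals). The adapter for the public
  clinical extract is a stub that validates channel order by an
  ABP-plausibility check and is never exercised against real data by the
  test suite.
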