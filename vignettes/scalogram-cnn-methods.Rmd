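---
title: "Methods: scalogram-based convolutional EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scalogram-based convolutional EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalocnn)
```

## The problem and the model

Epileptic activity changes the time–frequency structure of the EEG: ictal
segments carry sustained high-amplitude low-frequency rhythmic discharge,
interictal segments show sporadic transient spikes, and healthy recordings
are dominated by ongoing oscillatory background. `scalocnn` classifies
single-channel EEG segments by making that structure visible to a small
image classifier instead of extracting hand-crafted features.

Each segment $x(t)$ is mapped to its Morlet continuous wavelet transform

$$W(s,\tau) = \frac{1}{\sqrt{s}} \int x(t)\, \psi^*\!\left(\frac{t-\tau}{s}\right) dt,
\qquad \psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2},$$

whose energy density $|W(s,\tau)|^2$ (the scalogram) is rendered as an
image, min–max normalized to $[0,1]$, resized to $32\times 32$ by cubic
interpolation, and classified by a network with the fixed trace
$32{\times}32 \to 16@28{\times}28 \to 16@14{\times}14 \to 64@10{\times}10
\to 64@5{\times}5 \to 1600 \to 1000 \to \mathrm{softmax}$ (valid $5\times5$
convolutions, ReLU, $2\times2$ stride-2 max pooling, categorical
cross-entropy, Adadelta). Performance is estimated by stratified 10-fold
cross-validation with per-fold test confusion matrices summed, so every
segment is tested exactly once.

The model assumes a single channel at a fixed sampling rate (173.61 Hz by
default, the rate of the public five-set reference corpus), bandlimited
content (the corpus is bandpass filtered 0.53–40 Hz), and class-distinct
energy distributions over the 0.5–40 Hz band. Nothing in the pipeline
depends on the corpus segment length of 4097 samples; segments are
length-agnostic, with an edge-effect flag when a segment is shorter than
the widest wavelet's support.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `omega0` | 6 | – | Standard admissible Morlet trade-off; pseudo-frequency $f=\omega_0/(2\pi s)$. |
| scale grid | 64 log-spaced scales, 0.5–40 Hz | s / Hz | Covers the recordings' bandpass; log spacing matches the wavelet's constant-Q resolution. |
| `value_mode` | `energy` | – | The scalogram is defined as an energy density; `magnitude` is exposed for inspection. |
| `input_size` | 32×32 | px | The classifier's hard input contract. |
| `interpolation` | cubic (Keys, $a=-0.5$) | – | The cubic-convolution kernel of the common image toolboxes. |
| `channels` | 1 | – | Grayscale carries all scalogram information; a 3-channel colormap mode exists for visual fidelity. |
| `learning_rate` | 0.001 | – | Protocol fidelity; classical Adadelta uses 1.0 and 0.001 trains very slowly (see below). |
| `rho` | 0.9 | – | Adadelta decay coefficient; the protocol's "momentum 0.9" is read as $\rho$ since classical Adadelta has no momentum term. |
| `epochs`, `batch_size` | 50, 4 | – | Reference protocol. |
| `validation_fraction` | 0.20 | – | Stratified hold-out used for monitoring only; never updates weights. |
| `k` | 10 | folds | Reference protocol; per-fold counts for 2–5 classes of 100 are 144/36/20 … 360/90/50 (train/validation/test). |

## The synthetic generator

The generator emulates the five recording conditions of the reference
corpus with deliberately simple ingredients: 1/f-shaped Gaussian background
restricted to 0.5–40 Hz (all classes); an 8–13 Hz narrowband rhythm at
roughly doubled amplitude for the eyes-closed class (B vs A); Poisson-timed
biphasic spikes of ~70 ms (sharp positive lobe, smaller negative lobe) at
low rate/amplitude for one interictal class (C) and higher rate/amplitude
for the other (D); and a sustained 3–5 Hz sinusoidal discharge at five
times the background RMS, with slow amplitude modulation, for the ictal
class (E). Amplitudes are unitless, as the corpus' physical units are
undocumented. Each segment draws from a stream derived from
`(seed, label, index)`, so any one segment is reproducible independently of
generation order.

What it does *not* emulate: real EEG nonstationarity, electrode artifacts,
inter-subject variability, the corpus' amplitude histograms, or any
physiological generative mechanism. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that it
separates classes whose time–frequency signatures differ in the intended
way — not that real-data accuracies are reproduced. Real-corpus results
additionally depend on stochastic training and on the corpus download
itself, which is why the test suite asserts properties (ridge recovery,
determinism, separability floors) rather than published accuracy values.

## Numerical choices

* **CWT evaluation.** Zero-padded linear convolution, evaluated in the
  frequency domain; tests verify agreement with direct time-domain
  summation to $10^{-10}$. Wavelet support is truncated at $\pm 4s$
  (four Gaussian standard deviations, amplitude $<3\cdot10^{-4}$ of peak).
  Segments shorter than the widest support get a warning-level log line and
  an `edge_effect` flag rather than an error.
* **Orientation.** Row 1 of every scalogram and image is the smallest scale
  (highest frequency); scales increase down the image.
* **Normalization and resizing.** Per-image min–max to $[0,1]$ *before*
  resizing; a constant image maps to all-zeros by convention. Cubic
  interpolation can overshoot, so resized images are clipped back to
  $[0,1]$, making the resize contractive in range. The default path resizes
  the scalogram matrix directly to 32×32; an optional `render_size` raster
  (e.g. 662×536, the figure size of the original workflow) is exposed for
  fidelity, at no change in the contracts.
* **Initialization.** Glorot-uniform with an explicit seed; a build with the
  same seed is bit-identical.
* **Pooling ties.** The unpooling mask breaks ties toward the first window
  slot (column-major order), keeping backpropagation deterministic.
* **Adadelta.** $\epsilon = 10^{-6}$; accumulators start at zero. The
  learning-rate multiplier defaults to the protocol value 0.001 but the
  package's own property tests train with 1.0, the classical Adadelta
  rate — with 0.001 the accumulator bootstrap makes early steps of order
  $10^{-6}$ and a 10-epoch run barely moves.
* **Undefined metrics.** Zero denominators yield `NA` (an explicit
  undefined marker), never `NaN`; the F-score is 0 when precision and
  recall are both defined and zero.
* **Reported precision.** Report formatting rounds half-up to 2 decimals;
  full precision is kept internally.

## Metric conventions

The published result tables this package's reference matrices come from use
more than one labelling convention, so `confusion_metrics()` computes all
of them, labelled, instead of guessing one:

* `sensitivity_ppv` $= TP/(TP+FP)$ — the "sensitivity" of the binary
  tables (identical to precision); `recall` $= TP/(TP+FN)$ — the
  "sensitivity" of the multiclass tables.
* `specificity` $= TN/(FP+TN)$; `npv` $= TN/(TN+FN)$ — what the binary
  tables print as "specificity".
* `accuracy` $= (TP+TN)/\mathrm{total}$, and `accuracy_cc`
  $= (TP+TN_d)/(TP+TN_d+FP+FN)$ with $TN_d$ the sum of the *other diagonal
  entries* — i.e. only correctly-classified negatives counted. The
  multiclass tables' per-class accuracy and specificity columns follow the
  $TN_d$ variant; `specificity_cc` $= TN_d/(FP+TN_d)$.

Overall accuracy is always trace/total. In the two-class case the
one-vs-rest accuracy of either class coincides with it; for more classes it
does not, which the tests assert rather than assume. A handful of published
cells are inconsistent with their own matrices under every convention; the
test suite pins the reproducible cells (about 170 of them) and asserts the
known exceptions as exceptions.

## Problem sizes

The package's own checks use synthetic data at sizes chosen to exercise
every code path at desk scale: 40 segments per class and 10 epochs for the
two-class separability check (held-out accuracy floor 0.9), 20 per class
and 1 epoch for the 10-fold determinism check, 100 per class for the
fold-arithmetic checks, and 1000 random matrices for the metric-formula
cross-check. The acceptance script (`scripts/acceptance.R`) recomputes all
of these plus the reference-matrix arithmetic from scratch under a single
seed.

## Known limitations

* Single-channel only; no EDF/BDF montage support, artifact rejection or
  re-referencing.
* Training is CPU-bound R; fine at the package's scales (a two-class
  40-per-class, 10-epoch run takes seconds), but not meant for large
  corpora or architecture search.
* The published per-class metric conventions were recovered from the
  printed tables themselves; where a printed cell contradicts its own
  matrix, the matrix arithmetic is taken as authoritative.
* No cone-of-influence masking beyond the edge-effect flag; border
  coefficients of short segments are attenuated by the zero padding.
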