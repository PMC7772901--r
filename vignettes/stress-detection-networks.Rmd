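---
title: "Stress and affect classification from raw wearable sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress and affect classification from raw wearable sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearnet)
```

## The problem

Physiological arousal leaves signatures across many body signals at once:
heart rate rises under acute stress, electrodermal activity (EDA) shows a
higher tonic skin-conductance level and more frequent phasic events,
respiration quickens, and movement patterns change. `wearnet` classifies
short multi-channel windows of such signals into affective conditions, in
two formulations:

* **binary stress detection** — stressed vs. non-stressed (baseline and
  amusement both count as non-stress);
* **3-class affect classification** — baseline vs. stressed vs. amused.

The data model follows the common wearable-study layout: per subject, a
chest device records ECG, EDA, EMG, respiration, skin temperature and a
3-axis accelerometer, all at 700 Hz, while a wrist device records blood
volume pulse (BVP, 64 Hz), a 3-axis accelerometer (32 Hz), EDA (4 Hz) and
skin temperature (4 Hz); a 700 Hz integer label track marks the condition
protocol. Channels are never resampled: every model consumes each channel
at its native rate, which is why the two sites get two different network
families.

## Windowing

Records are cut into fixed 5 s windows (configurable), non-overlapping by
default (`strideS = windowS`). At 700 Hz a chest window is a 3500-sample
vector per channel; wrist windows are 320/160/20/20 samples for
BVP/ACC-axis/EDA/TEMP.

A window needs a single label. The rule in `assignWindowCondition()` takes
the modal code of the window's 700 Hz label slice and accepts it only if
its share is at least `purity`. The default `purity = 1` accepts only
single-condition windows, so windows straddling a condition transition are
dropped rather than given an ambiguous label; a majority rule
(`purity = 0.5`) is available. Only the three study conditions are eligible
by default; transient, meditation and other documented codes are excluded
from modelling (widening the eligible set is supported, and
`mapTaskLabels()` then drops and counts such windows).

The evaluation protocol scrambles windows into a 7:3 train/test split
(`scrambleSplit()`), with tenfold cross-validation available on the
training portion. The scramble is window-level, which lets nearby windows
of one subject fall on both sides of the split; that matches the protocol
this package implements but inflates accuracy relative to
subject-independent evaluation, so `bySubject = TRUE` is provided as the
stricter alternative. We reconcile the hold-out and the cross-validation as
follows: folds are built on the 70% training portion for model-selection
telemetry, and all reported metrics come from the untouched 30% hold-out
(`runProtocol()` exposes both, plus the per-fold reports).

## The two networks

### Chest: multi-branch 1D CNN

Each of the 8 chest inputs (5 physiological channels + 3 accelerometer
axes, each axis a separate input) passes through an identical 3-stage 1D
convolutional block; parameter sharing across a long raw window is what
makes training on 3500-sample inputs tractable. A stage is a valid
(no-padding) 1D convolution with ReLU followed by 1D max pooling:

| stage | filters | kernel | stride | pool | pool stride |
|------:|--------:|-------:|-------:|-----:|------------:|
| 1     | 8       | 15     | 2      | 4    | 4           |
| 2     | 16      | 7      | 2      | 4    | 4           |
| 3     | 32      | 3      | 1      | 2    | 2           |

All convolution/pooling arithmetic is
`floor((len - kernel) / stride) + 1` (`layerOutLen()`). On a 3500-sample
input the chain runs 3500 → 1743 → 435 → 215 → 53 → 51 → 25, giving 32
maps of length 25. A single-change variant with final pool size/stride 3
(`chestConvBlock(variant = "finalPool3")`) yields 32 × 17 instead; both
configurations are first-class, and the default follows the stated
stage hyperparameters. The 8 block outputs are flattened, concatenated
(branch order is the declared channel order and is fixed), and fused by
dense layers of 32 and 16 ReLU units before the task output: 1 sigmoid
unit (binary) or 3 softmax units (3-class). The two task variants are
identical except for that last layer, which `graphDiff()` verifies.

### Wrist: multilayer perceptron

Wrist inputs are short enough that dense layers suffice. BVP (320) passes
through 64- and 32-unit ReLU layers; the three accelerometer axes are
flattened axis-major into one 480-vector and pass through a 32-unit ReLU
layer; the raw 20-sample EDA and temperature windows are concatenated
untouched with both branch outputs (32 + 32 + 20 + 20 = 104). The fused
head is three dense layers: a first hidden layer, 8 ReLU units, and the
task output (8 → 1 sigmoid or 8 → 3 softmax). The width of the first fused
layer is not pinned down by the architecture's description; the default is
64 (configurable via `headWidth`), chosen to sit between the 104-wide
concatenation and the 8-unit bottleneck.

## Training

`trainModel()` implements seeded minibatch training: Adam (learning rate
0.001 by default, the customary choice where none is specified), binary or
categorical cross-entropy bound to the task, 100 epochs and batch size 40
by default. There is no early stopping and no class weighting. The engine
(valid 1D convolution as im2col + matrix product, running-max pooling,
dense layers, fused softmax/sigmoid cross-entropy gradients) is
implemented in the package and verified against central finite differences
in the test suite; max-pooling ties split the gradient equally among tied
inputs, a valid subgradient that keeps runs deterministic.

Numerical choices: weights are initialized with seeded variance-scaling
(Glorot) uniform draws; softmax is computed with a max shift;
cross-entropy clamps probabilities at 1e-12; predictions decode by argmax
(3-class, ties to the lowest class index) or a 0.5 threshold on the
sigmoid. Everything runs in plain double arithmetic with all randomness
drawn from one seeded stream, so a (graph, data, config) triple reproduces
bit-for-bit — the determinism contract the tests assert.

Per-channel z-scoring, with statistics fit on the training split only, is
applied by default: raw channels differ by orders of magnitude (ECG ~1 mV
templates vs. skin temperature ~34 °C) and unnormalized inputs would
swamp the shared-scale initialization. `normalize = FALSE` preserves the
literal raw-input reading.

Metrics follow the standard confusion-matrix definitions; for the 3-class
task the headline precision/recall/F1 are macro averages (the unweighted
mean over per-class one-vs-rest values), with micro and support-weighted
variants kept in the report metadata, since a single reported F1 does not
identify its averaging rule. Zero denominators yield 0 rather than NaN.

## The synthetic benchmark

`generateSubject()` produces study-shaped records so every pipeline stage
runs and is testable without any dataset download. Per condition, the
generator drives: a sharp periodic pulse template (ECG) and a two-harmonic
sinusoid (BVP) at the condition's pulse rate; EDA as a tonic level plus
Poisson-arriving phasic events with 2 s exponential decay; a sinusoidal
respiration channel; a slowly drifting temperature; and Gaussian
accelerometer/EMG activity. Defaults (pulse 70/95/80 beats/min, EDA tonic
2/8/4 µS with 2/10/5 events/min, respiration 14/20/16 breaths/min,
temperature 34.0/34.3/34.3 °C for baseline/stress/amusement) are
physiologically plausible and deliberately overlap stress and amusement on
temperature, so the 3-class task is learnable but not trivial from a
single channel. Subjects are jittered lognormally (5% relative sd by
default) around these parameters, each deterministically seeded from the
master seed.

What the generator does **not** emulate: real inter-subject variability
structure, sensor artifacts, motion contamination, baseline drift in EDA,
or any coupling between channels beyond the shared condition. Passing the
learnability bar therefore demonstrates that the pipeline — windowing,
label mapping, splits, both architectures, the optimizer and the metrics —
is wired correctly, not that the networks would reach comparable accuracy
on real recordings.

The test suite's benchmark uses 6 subjects × 60 s per condition (216
five-second windows, 151 train / 65 hold-out) and 20 training epochs —
sizes chosen so the chest CNN comfortably exceeds 95% hold-out accuracy
on separable data while a label-permuted control stays at chance, which is
the meaningful pair of checks at this scale. A linear probe on per-window
channel means is asserted to beat chance first, so the network bar never
tests a miracle.

## Reading native records

Native per-subject records are Python pickles; `readWesadSubject()`
converts them through a bundled Python helper into the package's
self-describing columnar text fixture and validates the result (8 chest
channels at the label rate, wrist lengths matching rate × duration, label
codes within the documented 0–7 set). Accelerometer arrays, nested N×3 or
flat, are always split into separate axis channels. The fixture format
itself (`writeSubjectFixture()`/`readSubjectFixture()`) writes 17
significant digits, so round trips are bit-exact.

## Known limitations

* Window-level scrambling is the default evaluation; subject-level splits
  are stricter and supported but not the default.
* The engine is CPU-only and single-threaded beyond BLAS; it is sized for
  the scaled benchmark and for moderate real datasets, not for large-scale
  experimentation.
* The wrist fused head's first width and the window-label rule are
  package decisions (documented above), since the architecture description
  leaves them open.
* `runProtocol()` reports hold-out metrics, fold telemetry and their
  spread; which of these a published accuracy corresponds to is not always
  identifiable, so all are exposed.
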