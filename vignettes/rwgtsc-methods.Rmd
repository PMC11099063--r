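---
title: "Label-free single-cell adhesion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free single-cell adhesion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rwgtsc)
```

## The measurement and what the package models

A resonant waveguide grating (RWG) biosensor reads out the resonant
wavelength shift (WS, in picometres) of an 80x80-pixel sensor per well.
The shift is proportional to the biomass within ~150 nm of the surface, so
an adhering cell appears as a compact bright peak (typically 1-4 pixels)
whose time course traces its adhesion kinetics: a lag after cell addition,
a sigmoidal spreading phase, and a plateau whose height reflects adhesion
strength. `rwgtsc` implements the full analysis chain for such recordings:

1. **sensor pipeline** — raw multi-well frames to per-cell kinetic signals;
2. **dataset construction** — offsets, batch correction, fixed-length
   cuts, stratified folds, SMOTE balancing, standardization;
3. **classifiers** — six 1D time-series neural architectures with a
   cross-validated training protocol;
4. **interpretation** — grad-CAM and false-negative amplitude
   distributions;
5. **synthetic generator** — ground-truthed wells and signal sets so every
   stage is testable without instrument data.

## The synthetic kinetic model

The generator renders each cell's curve from a generalized logistic:

$$S(t) = A\,\frac{g(t) - g(0)}{1 - g(0)} + s\,t,\qquad
  g(t) = \left(1 + e^{-(t - t_{\mathrm{mid}})/\tau}\right)^{-m},$$

with amplitude $A$ (pm), rise time $\tau$ (min), shape exponent $m$ and
residual plateau slope $s$ (pm/min). Two choices are deliberate:

* **Onset anchoring.** The midpoint is placed at
  $t_{\mathrm{mid}} = t_0 + c(m)\tau$ with $c(m) = \log(0.03^{-1/m} - 1)$,
  which pins the curve to 3% of its amplitude at the onset delay $t_0$
  for *every* shape exponent. A centred logistic would already sit at half
  amplitude at $t_0$, which contradicts what "onset" means for an
  adhesion lag. With this parameterization "the cell has not started
  adhering before $t_0$" holds by construction.
* **Exact zero at $t=0$.** The $g(0)$ anchoring makes $S(0)=0$ to machine
  precision, matching zero-offset biosensor exports and making
  amplitude-conservation checks exact rather than asymptotic.

An optional second logistic phase (own amplitude/onset/rise) models
biphasic adhesion; it is how the package realizes validation tasks whose
classes differ only late in the recording.

A well video adds, on top of the rendered peaks (centre pixel at full
amplitude, up to three 4-neighbours at 40%): a linear baseline drift, an
injection-artifact step common to all pixels at the cell-addition frame,
and i.i.d. Gaussian sensor noise. These are the three nuisance terms the
processing chain is supposed to remove; the generator makes them
separately controllable so each removal step can be verified against
ground truth.

**What the generator does not emulate:** cell migration (peaks are
static), focal drift, non-Gaussian read noise, optical crosstalk between
adjacent cells beyond the footprint overlap, and any biophysics of
integrin-mediated adhesion — curves are phenomenological. Tests passing on
synthetic data therefore validate the *pipeline mechanics and the training
protocol*, not classification performance on real cells.

## Sensor pipeline choices

* **Background selection.** A pixel counts as background when its
  value never rises above the detection threshold *relative to the
  per-frame spatial median*; the median tracks drift and the injection
  artifact because cells occupy a small minority of pixels. The 1-px
  fringe around above-threshold pixels is also excluded, since footprints
  bleed sub-threshold signal into neighbours and would bias the
  background average. After subtracting the per-frame background mean,
  the background average is exactly zero and all common-mode signal is
  gone.
* **Peak detection.** A pixel is a peak when strictly greater than its
  8-connected neighbours; exact plateau ties go to the smallest
  (row, col) in lexicographic order, making detection deterministic.
  Peaks below the user threshold are discarded; peaks closer than
  `min_distance` (default 2 px) are thinned greedily in descending
  amplitude order. Detection runs on the final frame by default (cells
  fully developed); a max-projection mode is available.
* **Voronoi ROIs.** Each pixel joins its nearest peak (Euclidean, pixel
  centres); equidistant pixels go to the lower peak index, i.e. the
  higher-amplitude peak. The per-cell signal is the ROI maximum per frame
  (maxWS).
* **Containers.** The raw format is package-defined (the instrument
  format is proprietary): a documented plain-text dialect and a
  little-endian float32 binary dialect, both holding 12 concatenated
  80x80 well matrices per frame plus the time axis.

## Dataset construction

The order is fixed: zero-offset, batch-artifact correction, cut to
length, stratified split, SMOTE on the training portion only,
standardization with training statistics only. Points worth recording:

* **Cuts.** Datasets are named by their duration from cell addition (30,
  60, 90, 120, 150 min by convention); the sample count is
  $L = \lfloor 60\,\mathrm{duration} / \Delta t \rfloor$. The frame
  period $\Delta t$ is a free parameter everywhere (9 s by default):
  the instrument's export cadence is not fixed by the hardware, and all
  length-dependent quantities in this package scale with it. Records
  shorter than the cut are dropped, never padded — padding would
  fabricate kinetics.
* **SMOTE.** One interpolation factor $\lambda \sim U(0,1)$ per synthetic
  sample, applied to all timesteps, between a minority sample and one of
  its $k=5$ nearest same-class neighbours (Euclidean distance on the
  full-length vectors). A per-timestep independent $\lambda$ would
  destroy the kinetic shape that the classifiers are supposed to read.
  Every synthetic row's provenance (base, neighbour, $\lambda$) is kept,
  which makes leakage audits and convexity checks exact.
* **Standardization.** Two global scalars (mean and sd over all training
  values). Per-timestep statistics would distort relative amplitudes
  across time; the global transform preserves curve shape and amplitude
  ratios, consistent with the observation that magnitude-preserving
  alternatives do not improve performance.
* **Batch artifacts.** The per-measurement additive artifact is estimated
  from background pixels across the injection frame (post minus pre) and
  subtracted from every signal of that measurement. The exact estimator
  in the original acquisition software is not documented; this one is the
  package's choice and is validated against planted artifacts.

## The six classifiers

`build_model()` instantiates MLP, CNN, FCN, ResNet, MCDCNN and Inception
for univariate inputs. Layer *counts* and component types (normalization,
pooling, feature layer, activation) follow the standard tabulation of
these architectures; widths and kernel sizes follow the reference
time-series-classification benchmark implementations (e.g. FCN
128/256/128 channels with kernels 8/5/3 and a GAP head; MCDCNN two
conv(8, kernel 5) + max-pool stages and a 732-unit dense feature layer;
InceptionTime with bottleneck 32, three parallel kernels, a max-pool
branch and residual connections every three modules). The CNN row's
activation is unspecified in that tabulation; the reference Time-CNN's
sigmoid is used. `count_conv_layers()` verifies the conv-stage counts
(0/3/3/9/2/6) by introspection; shortcut 1x1 convolutions are not counted,
matching how the architectures are conventionally tabulated.

The engine itself — forward passes, reverse-mode gradients, Adam,
AdaDelta and SGD-with-momentum, batch normalization, dropout, pooling —
is implemented in the package in plain R on BLAS-backed matrix products.
Gradients of every layer are validated against central finite
differences in the test suite (BN-free paths to ~1e-7; through
batch-norm + ReLU stacks the comparison is limited by ReLU kinks at
BN-centred pre-activations, not by the backward pass, which is verified
exactly at block level).

Training defaults per architecture: optimizer (AdaDelta for MLP, Adam
for CNN/FCN/ResNet/Inception, SGD momentum 0.9 for MCDCNN),
cross-entropy loss, 500-epoch budget, batch 16 for CNN and 32 otherwise,
learning rate 1e-3 (MLP, MCDCNN) or 1e-4 (others), and a 0.5
reduce-on-plateau factor where listed. Early stopping monitors
validation loss with patience 50 by default and restores the best
weights; the patience is a package choice, as is using the fold's test
split as the early-stopping monitor (a known, conventional optimistic
bias, configurable by passing a separate validation set).

**Cross-validation.** Stratified 5-fold (per-class round-robin after a
seeded shuffle, so per-fold class counts deviate by at most one sample;
each test fold is ~20%). Within each fold: SMOTE on the training rows,
standardization from the (balanced) training rows, a freshly built model
with a fold-derived seed. Reports carry per-fold metrics, mean +- sd, and
the pooled-test confusion matrix (each sample tested exactly once).
Both pooled accuracy and mean-of-folds accuracy are emitted, since
either convention appears in practice.

## grad-CAM

For a class score $y^c$ (pre-softmax) and the feature maps $A^k$ of a
convolutional stage, neuron importances are
$\alpha_k^c = \frac{1}{Z}\sum_l \partial y^c / \partial A^k_l$ and the map
is $L^c = \mathrm{ReLU}(\sum_k \alpha_k^c A^k)$, linearly upsampled to the
input length. The default target is the last convolutional stage, the
conventional choice. An independent finite-difference oracle
(`gradcam_alpha_fd()`) recomputes $\alpha_k^c$ by perturbing whole feature
maps and re-running only the stages above the target.

One practical finding is recorded here because it shapes the validation
setup: behind a flatten + dense head (MCDCNN, CNN), globally
average-pooling the gradients can cancel positional evidence — on a task
whose classes differ only late in the signal, correctly classified
"late" cells can receive an identically zero CAM. Behind a
global-average-pooling head (FCN, ResNet, Inception) the pooled gradient
is exactly the GAP-path sensitivity and the maps localize as intended.
The localization checks therefore use FCN; grad-CAM on flatten-head
models remains available but should be read with this caveat.

## Validation design and problem sizes

The package validates itself on synthetic study conditions chosen once:

* *Oracle equivalence*: detection and tessellation against brute-force
  re-implementations on random frames (including plateau-tie and
  equidistant-tie constructions).
* *Conservation*: with fast kinetics (onset + 3.5 tau well inside the
  recording) and zero plateau slope, curves reach their amplitude to
  machine precision, so the noiseless pipeline must return endpoints
  within 1e-6 pm of truth — any bias in background handling fails this.
* *Classifier sanity*: five classes, 400 cells each, disjoint amplitude
  bands (100-250 through 1300-1500 pm) with kinetics reaching plateau
  inside the 30-min cut, noise sd 10 pm. An early draft of these specs
  had slower kinetics under which the bands did not translate into
  separated endpoints at 30 min (an endpoint-only multinomial fit reached
  0.36 accuracy); the conditions were corrected to match their stated
  intent — amplitude-separated classes — before the acceptance suite was
  frozen. MCDCNN at its protocol defaults reaches ~1.0 test accuracy
  there within 40 epochs; a permuted-label control sits at chance.
* *Late information*: two classes identical until minute 60 (second
  adhesion phase at ~75 min). At a 54-s frame period, FCN reaches
  ~0.98 at the 90-min cut and chance at the 30-min cut, and >= 70% of its
  CAM mass falls in the final third for correctly classified cells.
  The coarser frame period keeps the reference-width FCN affordable on a
  single CPU; it changes nothing structurally since every length is
  $\Delta t$-parameterized.

Problem sizes throughout (2000 cells for the CV check, 300 for the
late-information task, 100 random frames, 50 peak sets, three noisy wells)
are the package's chosen desk-scale conditions: large enough for the
binomial noise on the checked proportions to be far from the thresholds,
small enough to run routinely.

## Numerical notes and limitations

* Batch norm uses biased batch variance, eps 1e-3, running-stat momentum
  0.9; inference uses running statistics, so single-sample prediction is
  deterministic.
* Weight init is Glorot-uniform throughout; all randomness (init,
  shuffling, dropout, SMOTE, splits) flows from explicit seeds, and a
  master seed fans out via a fixed Lehmer-style rule (`split_seed()`), so
  any stage is reproducible in isolation.
* Softmax/cross-entropy are computed via log-sum-exp; training aborts
  with a diagnostic on non-finite loss.
* The engine targets the modest problem sizes above; it is not a
  general-purpose deep-learning framework (no GPU, no stride other than
  pooling, "same" padding only), and the large reference widths of
  FCN/ResNet/Inception make them the slow end of the zoo in this
  implementation.
* Real-data reproduction of published headline accuracies requires the
  original measurement database, which is an external download; nothing
  in the test suite depends on it.
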