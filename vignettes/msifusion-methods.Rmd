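---
title: "Methods: cross-modal spectral-image fusion for grain variety identification"
author: "msifusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal spectral-image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifusion)
```

## The problem

Sorghum varieties used in solid-state (Baijiu) brewing differ in moisture,
starch, fat and protein content, and those differences matter for the
fermentation outcome. Near-infrared hyperspectral imaging (HSI) captures the
chemistry — absorption features from O–H, C–H and N–H overtones — but at low
spatial resolution; microscope imaging captures grain colour, shape and
surface texture at high resolution but no chemistry. `msifusion` implements
an end-to-end pipeline that classifies grain variety from *both*
measurements: reflectance correction and grain extraction from hypercubes,
foreground extraction from microscope images, and MSI-FusionNet, a two-branch
neural network joined by a cross-modal attention (CMA) fusion block.

Because instrument data of this kind is rarely deposited, the package ships a
first-class synthetic-data module that emulates the statistical structure of
such a study (12 varieties × 300 grains; 512 bands spanning 886–1735.34 nm;
5×5 grain layouts per cube; class-correlated grain colour/shape/texture), so
the entire pipeline is testable on any machine.

## Hyperspectral preprocessing

Raw push-broom intensities are converted to reflectance with the standard
two-reference normalisation

$$R = \frac{\mathrm{raw} - \mathrm{dark}}{\mathrm{white} - \mathrm{dark} + \epsilon},$$

per pixel and band, with $\epsilon = 10^{-8}$ guarding empty denominators.
The formula cancels dark current and uneven illumination; it is exactly
invertible on the synthetic generator's raw cubes, which are built as
`raw = dark + R · (white − dark)`. Negative reflectances are clipped to 0 and
counted; values above 1 (specular pixels) are kept because they carry masking
information. Imager response is weak at the range ends, so the first 9 and
last 32 of 512 bands are dropped, retaining 471 effective bands
(`selectEffectiveBands()`); the synthetic generator plants 10× inflated noise
on exactly those bands so the screen is doing real work in tests.

One wrinkle inherited from the source pipeline: the spectral branch of the
network is specified for a 480-length input (its dense head expects a
3584-long flatten), while band screening yields 471. We keep the input length
configurable with default 480; conveniently, both 480 and 471 propagate
through the six stride-2 convolutions to a length-7 feature map, so the same
3584-feature head serves both.

**Indexing.** All band indices and pixel coordinates in this package are
1-based, matching R. Descriptions of this workflow in the literature use
0-based indices (e.g. false-colour channel bands 41/25/11); here the same
bands are 42/26/12.

## Grain ROI extraction

`segmentGrains()` works on a 0–250 score image (by default the band plane
nearest 954.15 nm — the false-colour R channel — scaled by 250; the choice of
plane is configurable because no single choice is canonical). A coarse
threshold of 70 marks bright grain cores; a dilated envelope of those cores,
optionally intersected with a user polygon, bounds the candidate region; a
fine threshold of 25 recovers full grain extent inside it; morphological
opening removes isolated noise and closing plus hole filling completes grain
interiors (3×3 disc kernel). The fine step can alternatively compute Otsu's
threshold on the candidate region (`fineMethod = "otsu"`); we default to the
fixed printed constant for reproducibility and record both values when Otsu
is used.

Components are labelled with 8-connectivity and components under 80 px are
discarded — dust and endosperm specks, which the cube generator deliberately
plants below threshold. Raster ordering groups centroids into 5 rows by
splitting the sorted Y coordinates at the 4 largest gaps (deterministic and
robust to a few pixels of row jitter, unlike fixed-height binning), orders
rows top-to-bottom and ROIs left-to-right within each row. Each grain's
spectrum is the mean reflectance over its pixels.

## Microscope image path

`grabCutForeground()` is a native GrabCut: diagonal-covariance colour
mixture models for foreground and background, re-fit each round against the
current labelling, with labels re-solved as a minimum s–t cut over the
4-connected pixel lattice (contrast weights
$\gamma e^{-\beta\|z_i - z_j\|^2}$, $\gamma = 50$, $\beta$ set from the mean
neighbour contrast; cut solved by `igraph::max_flow`). The mixture fit uses
luminance-quantile-seeded k-means, so the segmentation is fully deterministic
given the image and rectangle — a property the tests rely on. The default
rectangle is the image shrunk 5% per side, 5 iterations. The foreground is
composited onto pure black (`compositeBlack()`), and model input is resized
to 224×224, randomly flipped (p = 0.5, training only) and standardised with
ImageNet channel statistics — configurable, and chosen because the 2-D
backbones are ImageNet-era designs. Backbones start from random
initialisation; nothing in the protocol implies transfer learning.

## MSI-FusionNet

The **spectral branch** is six 1-D convolutions (channels
1→16→32→64→128→256→512, kernels 7/7/5/5/3/3, stride 2, padding 1), each
followed by batch normalisation and ReLU (conv→BN→ReLU order, one of two
readings of the stated design), then CBAM-style channel attention over the
512 channels,

$$M_c(F) = \sigma\!\big(\mathrm{MLP}(\mathrm{AvgPool}(F)) + \mathrm{MLP}(\mathrm{MaxPool}(F))\big),$$

with a shared bottleneck perceptron (reduction 8), placed after the last
convolution where the channel count is largest; then flatten (3584) → 256 →
128 → a shared 64-dimensional layer. The **image branch** is a registered 2-D
backbone — ShuffleNetV2 1.0× implemented natively (channel split, pointwise/
depthwise/pointwise branch, concat, channel shuffle; stages of 4/8/4 units;
final 1×1 conv to 1024 channels) with VGG16 as the registered alternative —
followed by a squeeze-and-excitation block
($s = \sigma(W_2\,\delta(W_1 z))$, reduction 16, inserted after the final
feature stage), global average pooling, a 128-unit layer and the same shared
64-unit layer. "Shared" is read literally: one weight-tied 128→64 map serves
both branches (an untied option exists).

**CMA fusion** treats each 64-vector as a 64-channel sequence. 1×1
projections (implemented as linear maps, which is what a 1×1 convolution on a
64×1×1 map is) produce the query from image features and key/value from
spectral features; the 64×64 attention matrix is
$\mathrm{softmax}(QK^\top/\sqrt{C'})$ with rows summing to 1; the attended
value is re-projected and added to the image features (residual), then batch
normalised and passed through leaky ReLU (slope 0.01). Two readings were
resolved as design choices: the published scaling "$/C'$" is taken as a
typeset loss of $\sqrt{C'}$ (the standard scaled dot product; $C'$ remains
available via `scaleMode = "dim"`), and the attention/value product is
interpreted over the channel axis so shapes are consistent. A linear
classifier head with softmax completes the model. The ablation lattice —
spectral-only, image-only, concatenation fusion without attention, and the
full model — shares one builder (`modelSpec(fusion = ...)`).

No deep-learning framework is involved: layers are implemented directly on
R arrays with hand-written backpropagation, with im2col/col2im, depthwise
convolution, max-pooling and the Adam update as compiled (Rcpp) kernels.
Every layer's gradient is verified against central finite differences in the
test suite. Parameter accounting (`countParameters()`) reports trainable
parameters and float32 size (`count × 4 / 2^20` MiB); the published
count↔size relation for the ShuffleNetV2 and VGG16 variants is reproduced
exactly by this formula. The exact published total parameter count is not
promised: attention insertion points and width multipliers are
under-specified, so the testable surface is the size⇄count relation and the
shape contract.

## Evaluation protocol

`makeSplits()` performs a stratified 80/20 train/test split and assigns
5 cross-validation folds (class proportions within one sample). `runCV()`
trains a freshly initialised model per fold (Adam, learning rate $10^{-4}$,
200 epochs in the full protocol), records validation accuracy, and keeps the
weights of the best fold (ties to the lowest index). `finalTrain()`
re-initialises from those weights and retrains on the full training set. The
protocol's "monitor the test set during final training" step risks selection
leakage; the default mode monitors but always reports the final-epoch model,
and `honest = TRUE` withholds the test set until a single final evaluation.
Loss is cross-entropy (the natural choice for a softmax classifier; the
protocol does not state one); batch size defaults to 32; precision and recall
are macro-averaged over classes (also unstated; macro treats the balanced
classes symmetrically). `decisionFusionBaseline()` implements late fusion by
probability averaging (majority vote available). `embedFeatures()` provides
PCA (via `prcomp`, eigen-checked), an exact $O(N^2)$ t-SNE and a small-N
UMAP-style fuzzy-graph layout — native implementations sized for the
package's sample counts.

## What the synthetic generator does and does not emulate

Spectra are smooth baselines minus class-specific Gaussian dips (σ = 15 nm)
at 920/980/1030/1130/1230/1480 nm — the moisture/starch/lipid/protein
overtone bands — with per-class depths drawn once from a Dirichlet-scaled
template (total depth 0.45, baseline 0.85), i.i.d. noise (sd 0.01), and 10×
noise on the screened edge bands. Grain images are shaded ellipses with
class-dependent hue, axis ratio and speckle density on a textured non-black
background, with optional dark-spot defects. Hypercubes place spectra onto
disk-shaped grains (radius 7 px, 20 px pitch, ±2 px jitter) with intensity
levels chosen so the fixed 70/250 and 25/250 thresholds segment correctly by
construction. None of this emulates instrument line-scan geometry, scatter
artefacts, touching grains, or realistic grain morphology — so green tests
demonstrate pipeline correctness, not field performance. Published per-class
spectral variances were not available to calibrate against; generator
parameters are the package's own choices of what is realistic.

## The fusion-advantage construction

To test that fusion is *implemented* correctly — not merely that it runs —
the generator can split class information across modalities
(`makeFusionAdvantageSet()`): classes 1–10 are distinct (spectral, visual)
archetype pairs from a 4×4 grid, so either modality alone narrows 12 classes
only to about 3; classes 11 and 12 are mixtures over the same two spectral
and two visual archetypes, crossed oppositely. The marginal distribution of
each modality is identical for classes 11 and 12, so *any* decision-level
combination of unimodal posteriors is blind to the distinction, and a linear
head on concatenated features cannot express the required exclusive-or
either; only a joint, interaction-capable model (such as the CMA block, whose
attention logits multiply projections of both modalities) can resolve it.
The information-theoretic ceilings are ≈ 1/3 for either unimodal model,
10/12 for calibrated decision fusion, 11/12 for concatenation with a linear
head, and 1 for the full model. The acceptance suite trains all variants at
12 classes × 30 samples, 15 epochs, batch 32, and checks the orderings as
medians over 5 seeds.

## Numerical and schedule choices

* Scaled experiments use 32×32 image input and 192-band spectra (screened to
  151): ShuffleNetV2 is fully convolutional, so the architecture is unchanged,
  and both lengths propagate validly through the spectral stack. The full
  224×224/480-band configuration is exercised by shape and forward tests.
* Short (15–30-epoch) schedules use learning rate 3e-3, chosen so training
  converges (training accuracy ≈ 1) within the schedule on the scaled tasks;
  the 200-epoch protocol default remains 1e-4. Both are `trainConfig()`
  parameters.
* Batch-norm running moments are seeded from the first training batch: with
  an (0, 1) initialisation, the decayed initial variance can dominate small
  true feature variances for tens of steps and distort eval-mode predictions
  on short schedules.
* Weight initialisation is uniform $\pm 1/\sqrt{\mathrm{fan_{in}}}$;
  degenerate segmentation inputs (empty images, all-background) return empty
  masks rather than erroring; ties in raster-row splitting resolve to the
  earlier gap; `which.min`/`max.col` tie-breaks are first-index and
  documented where they matter.
* GrabCut assumes one grain per frame, centred enough that the default
  rectangle contains it.

## Known limitations

Training is CPU-bound R; the full 3600-sample, 200-epoch protocol is
expressible but slow — the package's experiments run the scaled
configurations above, and the vignette's claims are limited to what the test
suite computes. The native t-SNE is exact ($O(N^2)$): fine for thousands of
samples, not for millions. ShuffleNetV2 is the only natively implemented
lightweight backbone (VGG16 is the heavyweight alternative);
MobileNetV3/GhostNet can be added through `registerBackbone()`.
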