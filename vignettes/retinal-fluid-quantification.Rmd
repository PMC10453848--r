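---
title: "Visualization-driven retinal fluid volumetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualization-driven retinal fluid volumetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidcam)
```

## The problem

Exudative retinal disease (most prominently neovascular age-related macular
degeneration) produces fluid in three compartments visible on spectral-domain
optical coherence tomography (OCT): intraretinal fluid (IRF) inside the
neurosensory retina, subretinal fluid (SRF) between the retina and the retinal
pigment epithelium (RPE), and pigmented epithelial detachment (PED), where the
RPE lifts off Bruch's membrane. Fluid volume is the biomarker that drives
anti-VEGF treatment decisions: a patient whose fluid volume drops by strictly
more than 10% after treatment is categorized a *Responder*, anything else
(growth, stasis, or a reduction of 10% or less) a *Nonresponder*
(`responder_status()`).

`fluidcam` quantifies that volume **from the explanation of a classifier
rather than from a segmentation network**. A binary per-pathology classifier
says *whether* a B-scan shows fluid; class activation mapping (CAM) techniques
say *where* the classifier looked; post-processing sharpens those coarse
relevance blobs into fluid masks; and voxel geometry turns mask pixels into
cubic millimetres. The package implements the full chain plus a synthetic
phantom generator so that every stage is testable without clinical data.

## Pipeline

For each slice of a C-scan (`cscan_volume()`):

1. optional despeckling (`denoise()`),
2. classification (`predict()`); the slice continues only if the
   pathology-present softmax score is **strictly** greater than the gate
   (default 0.5),
3. a heat map from the selected CAM technique, Otsu-binarized at the model's
   analysis resolution,
4. nearest-neighbour resize of the *binary* map back to B-scan resolution,
5. refinement on the original gray levels: seeded region growing, selective
   thresholding, or none,
6. volume accumulation: `sum(mask pixels) * dx*dy*dz`, with the default
   scanner geometry 11.7 x 47.2 x 2.0 um (1104.48 um^3 per pixel), reported
   in mm^3.

Resizing after binarization (step 4) keeps masks strictly binary and defines
pixel counting on scanner pixels, where the voxel volume is defined. The gate
comparison is strict because the decision rule is "score more than 0.5"; a
score of exactly 0.5 does not enter the visualization stage.

## The classifiers

One binary model per pathology, in the Inception-ResNet family: stem, a stack
of Inception-ResNet-A blocks, Reduction-A, B blocks, Reduction-B, C blocks,
global average pooling, dropout, and a two-way softmax. The presets fix the
published block counts — `standard` 10/20/10 and `small` 8/7/4, the small
variant having roughly half the trainable parameters — plus a `tiny` 1/1/1
preset at reduced width for desk-scale experiments. Parameter counts decrease
strictly from standard to small to tiny.

Because no deep-learning framework is assumed, the package carries its own
compact CNN engine (im2col convolutions in C++, backpropagation and Adam in
R). Blocks are realized economically: parallel 1x1 / 3x3 (factorized 1x3+3x1
in B and C blocks) branches, concatenated, projected back to the trunk width
by a linear 1x1 convolution, and added residually with scale 0.2; reductions
are stride-2 convolutions. This preserves the architecture's skeleton and
every property the pipeline relies on (exposed final-stage activations and
their gradients) while remaining trainable on a single CPU.

Training choices:

* loss: categorical cross-entropy with natural logarithm (the universal
  convention), predictions clamped to [1e-7, 1] so a hard zero stays finite;
* optimizer: Adam; the configured default learning rate is 1e-4, the
  conventional fine-tuning value for this architecture family. The
  desk-scale runs in the tests and acceptance script train a `tiny` model
  from random initialization and configure 3e-3, which converges on the
  separable phantom task within 20 epochs;
* grayscale B-scans are bilinearly resized to the square model input
  (default 450 px; desk-scale runs use 48-96 px), replicated to three
  channels, and scaled to [-1, 1] (the Inception input convention);
* no pretraining is bundled; `set_model_params()` accepts externally trained
  weights. Initialization is seeded He-normal, and training (shuffling,
  dropout) is fully reproducible given the seed.

## The despeckler

OCT speckle is multiplicative; the package models it as per-pixel gamma noise
and provides a gated convolution-deconvolution despeckler: five encoder
convolutions, a mirrored deconvolution decoder, and one learnable gate per
skip connection. The gate g in [0, 1] (sigmoid-parameterized, so the bound
holds throughout training) splits each encoder output: g*e crosses the skip
to the mirrored decoder layer, (1-g)*e continues down the encoder. This
orientation makes "all gates zero" mean "the decoder sees only the bottleneck
path", which is the meaningful degenerate case of a gated skip. Kernel sizes
(3x3), widths (32, 64, 128, 256, 256) and the mean-squared-error loss are the
smallest faithful realization of the described topology; none are fixed by
the method itself. Training pairs come from the phantom generator (clean
render vs speckled render). The despeckler is optional: with `denoiser =
NULL` the pipeline consumes raw images unchanged.

## CAM techniques and Ensemble-CAM

All five techniques share one contract: a heat map in [0, 1] at the model
input resolution, produced from the activations A^k of the last convolutional
stage, rectified, bilinearly upsampled, min-max normalized (an all-constant
map maps to all-zero rather than dividing by zero).

* **Grad-CAM** — channel weights are spatial means of dy_c/dA^k.
* **Grad-CAM++** — per-pixel weights
  `alpha = g^2 / (2 g^2 + S_k g^3)` (g the per-pixel gradient, S_k the
  spatial sum of channel k, 0/0 -> 0), combined as `w_k = sum(alpha *
  relu(g))`. This closed form arises from taking the second and third
  derivatives of the *exponential* of the class score; it is exact here
  because the score head (global average pooling then dense) is linear in
  the target activations. In the fully linear case with uniform positive
  gradients it reduces to Grad-CAM up to normalization, which the tests
  assert.
* **Score-CAM** — gradient-free; each normalized upsampled activation map
  masks the input (pixel-wise product) and the channel weight is the softmax
  across channels of the masked-input score increase over an all-zero
  baseline image (the common baseline convention).
* **Ablation-CAM** — gradient-free; `w_k = (y - y_k)/y` with channel k
  zeroed; guarded to 0 when |y| < 1e-12.
* **Self-Matching-CAM** — the technique is named in the literature this
  package follows but not specified there; the package's documented
  realization matches each upsampled, normalized activation map against the
  normalized input image by cosine similarity and uses the similarities as
  channel weights.

Binarization is in-package Otsu: the [0,1] map is quantized to 256 levels,
the threshold maximizes between-class variance over the 256-bin histogram,
ties break toward the smallest threshold, the mask is `level > t*`, and a
constant map yields an all-false mask. **Ensemble-CAM** fuses the five
binarized maps by pixelwise majority: a pixel is foreground when at least
three of five techniques agree — equivalently, sum the five binary maps and
threshold at three. Fusion is permutation-invariant and monotone.

## Post-processing

Fluid appears *dark*. Two refiners exploit that:

* **Seeded region growing** (`extract_seeds()`, `region_grow()`): one seed
  per connected contour of the binarized CAM (the pixel-rounded centroid,
  snapped to the component if the centroid falls outside a non-convex
  shape), then breadth-first expansion admitting a neighbour when its
  absolute intensity difference to the reference is strictly below the
  threshold (default 15 gray levels). The reference is the originating
  *seed* by default; because the inclusion phrase "between the seed pixel
  and the neighbouring pixel" is genuinely ambiguous, a `neighbor` mode
  (chained similarity) is provided. Regions from multiple seeds are
  unioned; connectivity is 8 by default (4 available). Growth under the
  seed reference is monotone in the threshold.
* **Selective thresholding** (`selective_threshold()`): pixel-wise product
  of image and CAM mask, then keep gray levels in [20, 50], endpoints
  inclusive. The histogram of fluid regions spikes at 25-50; the applied
  band deliberately starts at 20, and both the observed spike range and the
  applied band are kept distinct in the documentation because they differ
  in the source method. `roi_histogram()` exposes the masked 256-bin
  histogram on which that choice rests.

Neither refiner suits PED — there the target is a lifted bright layer, not a
dark pocket — so for PED the documented choice is `postproc_method = "none"`:
the raw Otsu-binarized CAM mask feeds volume computation.

## Quantification

Jaccard/IoU and Dice are set overlaps of binary masks; `dice = 2J/(1+J)`
always, and the package treats two empty masks as perfectly agreeing
(`empty_value = 1`, configurable to 0). Volumetric IoU/Dice are computed on
the stacked 3-D masks of a C-scan; cohort summaries report mean and
*population* standard deviation per (pathology, technique, post-processing)
group, since the published tables those summaries mirror do not state a
variance convention. Volumes are reported in mm^3: the source tables print
unitless volumes around 0.15-0.62 for ground truth, which is anatomically
plausible only in mm^3, and the conversion (1 mm^3 = 1e9 um^3) is explicit in
the code. Classification metrics (accuracy, precision, sensitivity,
specificity, F1) follow the standard confusion-count definitions; a metric
whose denominator vanishes is reported `NA` rather than invented.
`reference_confusion_counts()` ships the published benchmark tallies the test
suite replicates; one printed accuracy cell contradicts its own tallies, and
the package documents and sides with the tallies.

Evaluation modes: `restrict_to_true_positives` counts masks only on slices
that are classification true positives (requires labels — an evaluation-only
notion), and `gate_on_labels` replaces the classifier gate with ground-truth
labels to isolate the mask-and-volume stages from classifier quality.

## The phantom generator

`phantom_spec()` / `generate_cscan()` emulate the contrast structure the
pipeline exploits, not OCT physics: a dark vitreous, a stack of bright
retinal bands over a curved surface, a bright RPE line, a mid-bright choroid,
and per-pathology elliptical lesions — IRF inside the band stack, SRF resting
on the RPE, PED as a dome lifting a redrawn bright membrane. Lesion interiors
are drawn from the configurable band [25, 50] (per-lesion base level in the
central part of the band plus small jitter, clamped), so that lesions are
darker than any 5-pixel dilated ring around them and selective thresholding
is meaningful. Speckle is multiplicative gamma noise with mean one (theta =
1/k), applied last, clipped to [0, 255] and quantized to integers to match
8-bit I/O. The default shape k = 40 yields a *mildly* speckled render —
the generator emulates B-scans as the volume pipeline consumes them, i.e.
after acquisition-side despeckling; raw-speckle conditions (e.g. k = 4, the
level used to exercise the despeckler) are one parameter away. Default
volume 128 x 256 x 32 slices, configurable up to scanner sizes.

What passing phantom tests shows: the pipeline mechanics — gating, CAM
binarization, refinement, voxel arithmetic — recover known volumes under the
stated contrast and noise model. What it does not show: performance on
clinical morphology (real fluid pockets are not ellipses, real speckle is
not stationary, band anatomy varies), so phantom numbers must not be read as
clinical accuracy.

## Numerical choices and degenerate inputs

* Min-max normalization guards all-constant maps to all-zero.
* Otsu ties break to the smallest threshold (within 1e-12 slack);
  constant maps give all-false masks.
* Ablation-CAM guards |y| < 1e-12; Grad-CAM++ sets 0/0 alpha terms to 0.
* Interpolation: bilinear for images and heat maps, nearest-neighbour for
  masks, always after binarization.
* Empty-empty overlap = 1 by default, configurable.
* A region-growing threshold of 0 returns exactly the seed pixels (strict
  inequality); seeds out of bounds are errors; an empty CAM mask yields an
  empty seed list, not an error.
* All randomness (phantom, initialization, shuffling, dropout) flows through
  explicit integer seeds; equal seeds give bit-identical results.

## Problem sizes used by the tests and the acceptance script

The suite trains `tiny` models at input sizes 48-96 on 60-200 phantom
slices, despecklers at widths 6-8 on 32 x 48 slices, and measures volume
recovery on 20 C-scans of 64 x 128 x 8. These sizes were chosen so the whole
chain — including from-scratch training — runs comfortably on one CPU core
while leaving every contract observable; all of them scale up by
configuration only.

## Known limitations

* The CNN engine is single-core and single-example; it is a faithful,
  verifiable realization, not a performance claim. Full-scale 450-px
  training of the standard preset is out of its intended range.
* Self-Matching-CAM follows this package's documented matching rule; other
  realizations of the name exist.
* The published parameter counts (56M / 28M) of the full-width models are
  not reproduced; the presets preserve block counts and the strict ordering
  of capacities instead.
* The phantom validates mechanics, not clinical accuracy (above).
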