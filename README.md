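# fluidcam

Retinal fluid quantification from OCT classifier visualizations.

Clinicians grading exudative macular disease on optical coherence tomography
(OCT) need the *volume* of intraretinal fluid (IRF), subretinal fluid (SRF)
and pigmented epithelial detachment (PED) — it drives anti-VEGF treatment
decisions (a fluid reduction of strictly more than 10% after treatment makes
a patient a Responder). `fluidcam` computes that volume not from a
segmentation network but from the *explanation* of a binary per-pathology
classifier: class activation maps (CAMs) localize the classifier's evidence,
post-processing sharpens them into fluid masks, and scanner voxel geometry
turns mask pixels into mm³. The package is aimed at researchers studying
explainability-based quantification pipelines and at anyone who needs a
fully testable, dependency-light reference implementation of this chain.

## Method

Per B-scan *I* of a C-scan, with a trained binary classifier:

1. **Gate**: the slice proceeds iff the pathology-present softmax score
   exceeds 0.5 strictly.
2. **Visualize**: a heat map `L ∈ [0,1]` from one of Grad-CAM, Grad-CAM++,
   Score-CAM, Ablation-CAM or Self-Matching-CAM, all of the form
   `L = norm(ReLU(Σₖ wₖ Aᵏ))` over the final convolutional activations `Aᵏ`
   with technique-specific channel weights `wₖ` (e.g. Grad-CAM:
   `wₖ = meanᵢⱼ ∂y_c/∂Aᵏᵢⱼ`).
3. **Binarize**: Otsu thresholding on the 256-level histogram of `L`.
4. **Ensemble-CAM** (optional): fuse the five binary maps by pixelwise
   majority — foreground where ≥ 3 of 5 techniques agree.
5. **Refine**: seeded region growing (seeds at CAM contour centroids,
   neighbours join while `|I(p) − I(seed)| < 15`) or selective thresholding
   (keep CAM-masked pixels with gray level in `[20, 50]`, the dark band
   fluid occupies); PED uses the raw CAM mask.
6. **Quantify**: `V = (Σ mask pixels) · dx·dy·dz`, default voxel
   `11.7 × 47.2 × 2.0 µm³ = 1104.48 µm³`, reported in mm³, with volumetric
   Jaccard/Dice against expert masks where available:
   `J(A,B) = |A∩B|/|A∪B|`, `Dice = 2|A∩B|/(|A|+|B|)`.

Classifiers are Inception-ResNet-style binary models (presets keep the
published block counts: standard 10/20/10, small 8/7/4, plus a desk-scale
`tiny` 1/1/1), trained with Adam on categorical cross-entropy on a compact
in-package CNN engine (C++ im2col convolutions, R backprop). An optional
gated convolution–deconvolution despeckler handles the multiplicative
gamma-distributed speckle of OCT. A seeded phantom generator renders
synthetic C-scans (bright retinal bands, dark elliptical lesions in the
correct compartments, gamma speckle) with exact ground truth, so the whole
chain is testable without clinical data. See the methods vignette
(`vignettes/retinal-fluid-quantification.Rmd`) for modelling choices.

## Worked example

```r
library(fluidcam)

## a synthetic 8-slice C-scan with one IRF lesion per slice
spec    <- phantom_spec(height = 64, width = 96, n_slices = 8,
                        lesion_counts = c(IRF = 1, SRF = 0, PED = 0), seed = 42)
phantom <- generate_cscan(spec)
phantom$cscan
#> <cscan 'phantom': 8 slices of 64 x 96, voxel 11.7 x 47.2 x 2.0 um>

## train a desk-scale classifier on 120 labelled phantom slices
config <- model_config("tiny", input_size = 48, learning_rate = 3e-3)
model  <- build_classifier(config, seed = 1, pathology = "IRF")
model  <- train_classifier(model, images, labels, epochs = 12, seed = 1,
                           batch_size = 8)   # images/labels: 60 + 60 slices
classification_accuracy(model, images, labels)
#> [1] 0.9583333

## volume through Grad-CAM + Otsu + selective thresholding
report <- cscan_volume(phantom$cscan, model, pathology = "IRF",
                       technique = "gradcam", postproc_method = "selective",
                       gt_masks = phantom$masks$IRF)
print(report, digits = 3)
#>   scan_id pathology technique postproc_method predicted_volume_mm3
#> 1 phantom       IRF   gradcam       selective             0.000162
#>   ground_truth_volume_mm3 volumetric_iou volumetric_dice n_positive_slices
#> 1                0.000652          0.243           0.391                 3
```

Reading the output: three of eight slices passed the 0.5 gate; the refined
CAM masks overlap the true lesions with volumetric IoU 0.24 (Dice 0.39), and
the recovered volume underestimates the phantom's 6.5·10⁻⁴ mm³ of fluid —
typical for a coarse CAM grid and exactly the kind of behaviour the
refinement stages and Ensemble-CAM fusion are there to improve.

Classification metrics replicate published confusion tallies exactly:

```r
classification_metrics(tp = 8407, fp = 2213, tn = 40930, fn = 1100)
#> accuracy: 0.9371  precision: 0.7916  sensitivity: 0.8843  specificity: 0.9487  f1: 0.8354

responder_status(pre_volume = 0.62, post_volume = 0.48)
#> [1] "Responder"
```

A thin CLI wraps the same functions
(`inst/cli/fluidcam.R`: `generate`, `train`, `denoise`, `explain`,
`volume`, `evaluate`, `report`), e.g.

```sh
Rscript inst/cli/fluidcam.R generate --spec spec.yaml --out data/ --seed 7
```

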