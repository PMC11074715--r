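# contourtl

Binary brain-tumor detection from 2-D MRI slices, as one reproducible R
pipeline: contour-based brain cropping, grey-level-preserving threshold
segmentation, deterministic augmentation, leakage-guarded dataset
partitioning, a VGG-16-style transfer-learning classifier, and a
seven-metric evaluation suite. A synthetic phantom generator makes every
stage testable without downloading any image collection.

## Who this is for

Medical-imaging researchers and engineers who want the classic
"crop → enhance → threshold → fine-tune a frozen CNN" detection recipe as
auditable, unit-tested components rather than a notebook: each stage is an
exported function with a documented contract, and the whole experiment runs
from a single seeded YAML config.

## The method

**Preprocessing (brain contour cropping).** An input slice is converted to
grayscale (BT.601 luma), Gaussian-smoothed, binarized at a global threshold
*T* (pixel < *T* → 0, else 255), cleaned by erosion/dilation with a 3×3
structuring element, and reduced to its external contours (one per
8-connected blob, outermost boundary only, collinear runs collapsed to
endpoints). The original image is cropped to the bounding box of the
largest-area contour — the brain.

**Segmentation.** The crop is resized to 144×144 (bilinear), enhanced by an
affine map `clip(α·f + β, 0, 255)`, and thresholded grey-level-preservingly:

```
f(x, y) = f(x, y)  if f(x, y) ≥ threshold
        = 0        otherwise
```

The threshold is the Otsu value — the grey level maximizing the
between-class variance of the 256-bin histogram — or a fixed manual level.

**Augmentation.** Deterministic plans built from rotations `R(θ)`, vertical
and horizontal flips (`Y → −Y`, `X → −X`), and centre zooms. The ×8 plan
(identity, 90°/180°/270°, two flips, zoom 1.25/0.8) and the ×36 plan
(rotations × flips × zooms) expand a manifest by an exact factor: 253
sources × 8 = 2024 images, 3000 × 8 = 24000, 253 × 36 = 9108.

**Partitioning.** `test = ⌈0.2·N⌉`, `val = ⌈0.2·(N − test)⌉`, remainder to
train (the 80/20(+20 %-of-pool) scheme), or 70/30 train/validation with a
wholly disjoint external test set (the "unseen case"). Splits are
stratified, seeded, and by default grouped so all augmented variants of one
source image land in one split; cross-manifest overlap raises a leakage
error.

**Classifier.** A VGG-16-style network: 13 convolutional layers (3×3,
stride 1, ReLU) in five blocks separated by 2×2 stride-2 max-pools — first
10 convolutions frozen, last 3 fine-tuned — then three dense+dropout blocks
and a 2-way softmax. A 144×144×3 input yields a 4×4×512 pre-flatten feature
map. Training uses RMSprop (default learning rate 2e-5) on sparse
categorical cross-entropy with early stopping and best-weight restoration.
The CNN engine (im2col convolution over BLAS, max-pool, dropout, RMSprop)
is implemented in base R; `width_multiplier` builds reduced-width models
with identical topology for CPU-scale work.

**Evaluation.** Sensitivity, specificity, precision (PPV), NPV, accuracy,
F1 (percent, 2 decimals, half-up) and rank-based ROC-AUC, plus
`solve_confusion()`, which reconstructs the unique TP/FP/TN/FN counts
behind a printed metric row by exhaustive search.

## Worked example

A complete phantom experiment — generate 50 labeled phantoms, crop, segment,
split 80/20, train a reduced-width model, evaluate:

```r
library(contourtl)

report <- run_experiment(list(
  seed = 42,
  out_dir = file.path(tempdir(), "demo"),
  scenario = "single",
  phantoms = list(n_tumor = 25, n_normal = 25),
  model = list(width_multiplier = 1/16, head_widths = c(32, 16, 8),
               dropout_rate = 0.3),
  train = list(learning_rate = 1e-3, max_epochs = 8, batch_size = 16,
               patience = 8)
))
print(report$metrics)
#> sensitivity  100.00%
#> specificity  60.00%
#> precision    71.43%
#> npv          100.00%
#> accuracy     80.00%
#> f1           83.33%
#> roc_auc      1.0000
print(report$confusion)
#>         predicted
#> truth    tumor normal
#>   tumor      5      0
#>   normal     2      3
print(report$partition)
#>      train validation       test
#>         32          8         10
```

All seven tumor phantoms in the ten-image test set score higher than every
normal (ROC-AUC 1.0); at the default 0.5 decision point the model still
miscalls two normals after eight short epochs, which the thresholded
metrics show (specificity 60 %, accuracy 80 %). The run directory contains
the config copy, seed, split manifests, per-image thresholds, training
history and weights needed to re-execute it.

The same stages are scriptable individually (`extract_brain()`,
`segment_pipeline()`, `apply_plan()`, `split_dataset()`,
`build_contourtl_net()` + `train_model()`, `metrics()`), and
`inst/cli/contourtl.R` exposes them as shell subcommands
(`phantoms`, `crop`, `segment`, `augment`, `split`, `evaluate`, `run`).

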