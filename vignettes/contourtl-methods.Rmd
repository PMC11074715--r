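---
title: "Contour-based tumor detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-based tumor detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourtl)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the phantom generator does and does not emulate, and
where the design was genuinely open.

## The problem and the pipeline

The task is binary: does a 2-D brain MRI slice contain a tumor? The
pipeline follows the classic thresholding-plus-transfer-learning recipe:

1. **Brain contour cropping** — isolate the brain blob and discard
   background and annotations.
2. **Enhancement and threshold segmentation** — suppress normal tissue and
   keep hyperintense (suspect) pixels at their native grey levels.
3. **Deterministic augmentation** — expand small collections by exact
   geometric plans.
4. **Partitioning** — seeded, stratified, leakage-guarded splits.
5. **Classification** — a VGG-16-style network with a frozen feature
   prefix and a fine-tuned suffix.
6. **Evaluation** — confusion-matrix algebra and seven metrics.

## Brain contour cropping

The stage assumes the brain is the largest bright connected region on a
dark background — true for skull-stripped or black-background export
formats, and for the phantoms. Pipeline: grayscale (BT.601 weights 0.299 /
0.587 / 0.114, half-up rounding), Gaussian smoothing, global binarization,
morphological opening, external contour retrieval, largest-area bounding
box, crop of the *original* image.

Tunable parameters, with units and defaults:

| parameter | default | why |
|---|---|---|
| Gaussian kernel | 5×5 px, σ from the `0.3((k−1)/2−1)+0.8` size heuristic | smooths speckle without moving the brain boundary |
| binarization threshold `T` | 45 grey levels | separates tissue (typically ≳ 60) from near-black background (≲ 20) with margin on both sides |
| structuring element | 3×3 square | the conventional small element |
| erode / dilate iterations | 2 / 2 | an opening strong enough to delete annotation specks a single erosion leaves behind |

None of these is prescribed by the source recipe beyond the 3×3 element;
all are config-overridable. Contours are 8-connected (a 4-connected
labeling splits diagonal bridges and over-counts blobs), traced by
Moore-neighbour following with Jacob's stopping criterion, and stored with
collinear runs collapsed to endpoints. Ties on the largest area go to the
first blob in scan order, for determinism.

## Enhancement and segmentation

Segmentation is grey-level-preserving: pixels below the threshold become 0,
pixels at or above keep their value. It is idempotent, never raises a
pixel, and its zero-set grows monotonically with the threshold — properties
the test suite asserts.

The threshold selector is Otsu's between-class-variance maximizer over the
256-bin histogram (smallest maximizer on ties; a constant image raises a
degenerate-histogram error). A fixed manual threshold is available
everywhere as a config alternative, and is the right choice for noise-free
synthetic inputs whose enhanced histogram can collapse to one level.

**Why the pipeline default enhancement is a bright-end window.** On a
cropped brain the histogram has three modes: background corners (~21 % of
the bounding box of an ellipse), normal tissue (~70–75 %), and lesion
(2–12 %). Under a mild affine gain (e.g. α = 1.3, β = 10) the
background/tissue split dominates the between-class variance — the analytic
comparison gives roughly 4000 vs 900 in squared grey levels for typical
phantom intensities — so a single global threshold "segments" the whole
brain, not the lesion. The pipeline therefore defaults to a window,
α = 3, β = −420, which maps grey levels ≤ 140 to 0 and ≥ 225 to 255:
background and normal tissue are compressed together (≤ 30 after
windowing), the lesion stays ≥ 150, and the Otsu threshold lands in the
gap. Under these defaults the surviving pixels overlap the phantom's true
tumor disc with Dice ≥ 0.98 across the generator's whole parameter range.
`enhance()` itself keeps generic defaults (α = 1.3, β = 10) for use as an
ordinary brightness/contrast tool.

A lesion-free brain is entirely below the window floor, so its enhanced
image is constant and Otsu is undefined. At the orchestration level this is
*information*, not an error: nothing is above the window, so the
segmentation is empty. `run_experiment()` maps the degenerate case to an
all-zero image by default (`segmentation$on_degenerate = "zero"`);
`segment_pipeline()` itself keeps the strict erroring contract so callers
can distinguish the cases.

Whether the classifier should consume the segmented image or the enhanced
crop is not settled by the source description; this package feeds the
segmented image by default and exposes `segmentation$enabled = FALSE` to
feed the resized crop instead.

## Augmentation

Two fixed plans reproduce the published dataset arithmetic exactly — the
per-image factors 8 and 36 are forced by the printed totals (3000×8 =
24000, 253×36 = 9108, 253×8 = 2024), while the specific operation lists
inside each plan are this package's choice, constrained to
rotation/flip/zoom:

* ×8: identity, rotations 90°/180°/270°, flips h/v, zooms 1.25/0.8;
* ×36: rotations {0°, 90°, 180°, 270°, 15°, 345°} × flips {none, h, v} ×
  zooms {1, 1.25}, identity first.

Right-angle rotations and flips are exact pixel permutations; other angles
use bilinear resampling with zero (background-black) fill. For non-square
inputs a 90°/270° permutation necessarily transposes the shape — the
operation-level "exact permutation" contract wins over shape preservation
there; every image is resized to a square before the classifier, so the
distinction is immaterial downstream. Augmented rows inherit their source
label (geometric transforms are label-preserving) and record the source
path, which is what the leakage guard groups on.

## Partitioning

Counts use ceiling rounding on test and validation with the remainder to
train — the only rule consistent with the published split table
(9108 → 5828/1458/1822). Splits are stratified by label by default
(preserving the 155:98 imbalance within ±1 row per class via
largest-remainder allocation) and grouped by source image by default, so
augmented near-duplicates can never straddle a split. Grouping and exact
row counts can conflict (1822 test rows is not a multiple of a 36-variant
group); grouped splits hit the target to within one group, and
`group_by_source = FALSE` restores exact row-level counts. The unseen-case
builder takes train/validation from one manifest (70/30) and the *entire*
second manifest as the test set, erroring on any shared path or source.
One published split row (the 24000-image case) prints validation/test
counts of 4800/3840, which contradicts its own stated rule (20 % of total
to test ⇒ 4800; 20 % of the pool to validation ⇒ 3840); the package follows
the rule.

## The classifier

Thirteen 3×3 stride-1 convolutions in blocks of 2/2/3/3/3 with five 2×2
stride-2 max-pools; 144 → 72 → 36 → 18 → 9 → 4, so the pre-flatten map is
4×4×512. The first ten convolutions are frozen (transfer-learning
fine-tuning of the last block only); the head is three dense+dropout blocks
(512/256/64, dropout 0.5) and a 2-way softmax. The printed trainable
parameter count this architecture implies (11,422,146) is close to, but not
exactly, the figure the source reports (11,602,818); no standard head on a
4×4×512 map reproduces that figure, so the head widths are config-exposed
and the count is not enforced. The "14 × 144 × 3" input the source prints
is treated as a typo for 144×144×3.

The engine is written in base R: convolution is im2col + BLAS gemm,
max-pool argmaxes break ties to the first window position, dropout is
inverted (scaled at train time), softmax subtracts the max before
exponentiation, and cross-entropy clips probabilities at 1e-12. RMSprop
(ρ = 0.9, ε = 1e-7) updates only trainable parameters; frozen layers are
excluded from the backward pass entirely, and their feature maps are
computed once per image and cached across epochs, which is what makes
CPU-scale training practical. Analytical gradients were verified against
central finite differences (relative error ≈ 1e-8) during development.

Defaults: learning rate 2e-5 (the fine-tuning rate for pretrained
weights — randomly initialized reduced models use a larger rate such as
1e-3), batch 32, up to 30 epochs, early-stopping patience 5 with
best-validation-loss weight restoration. Pretrained convolutional weights
can be injected through `build_contourtl_net(weights = ...)` if a
compatible export is available; nothing in the package downloads or
requires them, and every test runs from seeded He-normal initialization.

`width_multiplier` scales all filter counts while keeping the topology —
the 1/16 model (filters 4…32) used throughout the test suite trains on a
few hundred phantoms in seconds.

## Evaluation

Six threshold metrics are percentages rounded half-up to 2 decimals at
reporting time only; undefined ratios (zero denominators) are reported as
`NA` with a warning rather than as 0, because silent zeros corrupt
averages. ROC-AUC is the rank-based Mann-Whitney statistic (ties one half),
identical to trapezoidal ROC area. `solve_confusion()` inverts a printed
metric row by exhaustive search over TP and TN and insists on uniqueness —
it either returns the single consistent matrix or says why it cannot.

## The phantom generator

Phantoms emulate the gross structure the pipeline exploits: a bright
ellipse (brain) with ±5 % centre jitter on a dark background, an optional
brighter disc (tumor) strictly inside it, additive Gaussian noise, clipped
8-bit quantization. Default ranges, chosen once as plausible for
modest-resolution axial exports: sides 180–260 px, brain semi-axes 30–42 %
of the half-side, brain intensity 110–150, tumor 80–110 grey levels above
the brain, background 10, tumor radius 15–35 % of the smaller brain axis,
noise σ = 3. Everything is deterministic in (spec, seed) down to file
bytes.

What the phantoms do **not** emulate: MRI physics (bias fields, partial
volume, T1/T2 contrast mechanisms), skulls and extra-cranial tissue,
non-elliptical anatomy, infiltrative or hypointense lesions, 3-D context.
A passing suite therefore demonstrates that the machinery is correct and
that the pipeline separates geometrically simple, intensity-separable
classes; it says nothing about accuracy on clinical images, and the
published real-data accuracies are explicitly not reproduced here.

## Problem sizes used by the suite

Tests run on reduced problem sizes chosen as a deliberate design point:
phantoms of 72–96 px (intensity and separability conditions unchanged),
the 1/16-width model, and an unseen-case smoke run of 200 phantoms
(140 train-source / 60 test-source, 15 epochs, three seeds) that must reach
90 % test accuracy in at least two of three seeds. The full-width model is
built and given one real optimization step to verify the layer census and
bit-exact frozen weights. The acceptance script generates 253 phantoms at
the generator's full default sizes and counts the ×8 plan output.

## Known limitations

* A single global threshold cannot separate lesion from tissue when their
  enhanced histograms overlap; the window default assumes hyperintense
  lesions.
* The cropper assumes one dominant bright blob; slices where the brain is
  split into several comparable blobs keep only the largest.
* The CNN engine is single-threaded per gemm call and has no GPU path; it
  is sized for reduced-width experiments, not full-scale fine-tuning.
* Grouped splitting trades exact split sizes for leakage safety (see
  above).
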