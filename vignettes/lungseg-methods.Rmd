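---
title: "Weakly supervised lung parenchyma segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised lung parenchyma segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung parenchyma — the low-attenuation gas-exchange tissue — looks remarkably
alike across subjects, diseases and scanners, while lung lesions (nodules,
effusion, consolidation) vary widely. `lungseg` exploits that asymmetry: it
segments the *parenchyma* of a thoracic CT volume with a small supervised
classifier whose training labels are produced entirely by unsupervised
clustering, so no manual annotation is ever needed. Lesions embedded in the
lung then appear as holes in the parenchyma mask and can be recovered (or
deliberately not) by post-processing.

The pipeline has three stages:

1. **Weak-label generation** (`build_labeled_dataset()`): slices are tiled
   into 8 × 8 patches; two-class k-means is run twice, once on the patch
   *mean* and once on the patch *minimum* intensity; each low-intensity set
   is pruned by cross-shaped verification; the two kept masks are
   intersected; 3-D connected-component analysis retains the lungs; each
   surviving 8 × 8 cell is expanded to a centred 32 × 32 window. An equal
   number of negative windows is sampled uniformly from the remaining
   addresses.
2. **Patch classification** (`patch_cnn()`): a single-convolution network
   labels 32 × 32 windows as parenchyma (LP) or not (NLP).
3. **Segmentation** (`segment_volume()`): every voxel (or every 8 × 8 block
   in the fast patch-wise mode) is classified by the window centred on it;
   the largest connected component(s) are kept and per-slice holes filled.

## Why two statistics, and why the cross-shaped rule

A patch's *mean* intensity separates "dark" (air, parenchyma) from "bright"
(body, bed) tissue with crisp boundaries, but cannot tell enclosed dark
structures from the dark air gap between the body and the scanner bed. The
patch *minimum* is maximally sensitive — any patch touching parenchyma goes
into the low cluster — so it dilates the lung boundary instead. The two
branches therefore fail in complementary places, and the intersection of
their verified masks cancels both artifacts.

Cross-shaped verification keeps a low patch only if every one of its four
in-slice rays (entire row/column to the left, right, up, down) contains at
least one high patch. Outside-body air always has at least one open ray to
the slice border, so it is discarded; in particular no patch on the grid
border can ever be kept. The rays deliberately span the whole slice — the
rule's purpose is to discard outside air, and any bounded neighbourhood
would re-admit it on large empty slices.

### Exact 1-D two-means

For scalars, the optimal two-cluster k-means solution is a threshold cut of
the sorted values. `kmeans_two_class()` finds it exactly by a prefix-sum
sweep over all n − 1 cuts (O(n log n), deterministic, no initialization).
We chose the exact solver over Lloyd iterations after observing that Lloyd
initialized at the extremes converges to a non-optimal local partition on
roughly 15% of random small inputs; the exact cut is also what the
verification-and-intersection logic assumes ("the" low cluster). Inputs with
all values identical are rejected as degenerate. When the optimal cut falls
inside a run of tied values the tie is kept intact (assignment is a function
of the value), which cannot increase the objective.

## The classifier

Architecture: input 32 × 32 → convolution (5 × 5, 6 kernels) → ReLU →
cross-channel local response normalization (window 3, AlexNet constants
α = 1e-4, β = 0.75, k = 2) → 2 × 2 max-pool (stride 2) → fully connected
120 → dropout 0.5 → ReLU → FC 2 → softmax. All nine tunable settings live in
`cnn_config()`; a normalization window of 1 means each channel is normalized
by itself alone. The unusual FC → dropout → ReLU order is kept as specified
for the reference design.

Numerical choices, each of which matters:

* **Input normalization**: HU are mapped linearly from [−1024, 1024] to
  [0, 1] with clipping, so air sits at exactly 0. We tried a zero-centred
  variant and rejected it: with air at the most-negative input, gradient
  descent aligns all six kernels to "bright tissue" detectors, after which
  air and parenchyma collapse onto identical all-zero ReLU activations and
  can never be separated again (both classes ended near p = 0.63). With air
  at 0 the dark-class contrast survives in every positive-sum channel.
* **Initialization**: weights are Gaussian with standard deviation
  `sqrt(2 / fan_in)`; biases start at 1, the AlexNet convention that keeps
  every ReLU unit initially active and avoids the same dead-unit collapse.
* **Optimizer**: mini-batch SGD with momentum 0.9 (the MATLAB `sgdm`
  default, matching the toolchain of the reference design) on the softmax
  cross-entropy. Training is deterministic given `seed` (initialization,
  shuffling and dropout all draw from it).
* **Decision rule**: LP when the softmax LP probability exceeds 0.5; ties go
  to NLP, since a false parenchyma voxel is costlier downstream (it feeds
  hole filling).

### Shortened training schedules

The reference protocol tuned its learning rate (1e-4) for a ~41,500
iteration schedule (50 epochs on a ~106k-patch split at batch 128). First-
order SGD progress is governed by the product of learning rate and iteration
count, so a 10-epoch run on a phantom-scale dataset (a few hundred to a few
thousand iterations) at 1e-4 stops far short of convergence — we measured
accuracy plateaus of 65–80% across several design variants. The package
therefore exposes `scaled_learning_rate()`, which preserves
lr × iterations relative to the reference schedule (capped at the reference
default rate 0.01), and the end-to-end tests train with it. This is a
schedule equivalence, not a re-tuning: architecture, batch size, dropout and
pooling stay at the reference optimum.

### Voxel-wise inference at full speed

Classifying the 32 × 32 window around *every* voxel naively repeats the
convolution ~1000-fold. Because all windows share one slice, `lungseg`
computes convolution, ReLU, LRN and a dense 2 × 2 block-maximum once per
padded slice; the pooled features of any window are then a pure index gather
from that block-max map (windows shifted by one voxel use pooling grids of a
different phase, which the dense map contains), and only the two FC layers
run per voxel, batched through BLAS. The fast path is algebraically
identical to the per-window forward pass, and the test suite asserts
equality to 1e-10 for both pooling types. Border windows are padded with
−1024 HU (air), the same rule used when expanding training patches, so
training and inference distributions agree at the volume edge.

Patch-wise mode classifies one window per 8 × 8 block and broadcasts the
decision, a ~64× saving; on blockwise-constant volumes it agrees exactly
with voxel-wise mode for any deterministic classifier.

## Post-processing

* `max_connected_component()`: 26-connectivity 3-D labelling, keeping the
  largest component — or the two largest (`n_keep = 2`) when the lungs are
  not bridged. The synthetic phantom has no trachea, so its lungs are
  genuinely disconnected and the two-component option is the appropriate
  setting there; size ties break towards the component appearing first in
  array order, for determinism.
* `fill_holes()`: per-slice 2-D filling with 4-connected background; any
  background region not connected to the slice border becomes foreground.
  Per-slice (not 3-D) filling is deliberate: it reproduces the documented
  failure mode in which effusion-like regions at the *boundary* of the lung
  field are not recovered — their background connects to the surrounding
  body — while fully interior lesions are. Both operations are idempotent,
  and the three stages are monotone (max-component ⊆ raw; filled ⊇
  max-component).

## Evaluation

`dsc()` is 2|A∩B|/(|A|+|B|) (1 when both masks are empty, 0 when exactly
one is). `hausdorff()` is the exact symmetric max–min distance between
boundary voxel sets (foreground voxels with a 6-neighbour in the background;
the volume edge counts as background), scaled by the voxel spacing — not a
percentile variant. Because the averaging behind reported "mean Hausdorff"
values is often left unstated, the function returns both the exact 3-D
value and an explicitly-labelled per-slice-mean variant. `sens_spec()`
counts voxels against the reference. `self_adaptability()` is the
percentage of cohort volumes carried to a usable (non-empty) mask without
intervention; the success rule is replaceable.

Classifier quality uses per-class precision/recall, their macro-averaged
F-score (`f_avg()` — the sum of the two per-class PR/(P+R) terms, i.e. the
mean of the two F1 scores), and a threshold-sweep ROC whose trapezoidal AUC
equals normalized pairwise concordance (asserted against a brute-force
count and against an independent ROC implementation in the tests).
`cross_validate()` runs seeded stratified 8-fold cross-validation — each
fold is a 7:1 train/validation split.

## The synthetic phantom

`phantom_spec()`/`generate_phantom()` produce the study volumes: background
air (−1000 HU), an elliptical body (+40), two elliptical lung fields (−850)
strictly inside it, a thin scanner-bed slab (+100) separated from the body
by an air gap, optional spherical soft-tissue lesions (+30, interior or
boundary-touching), mild apex/base tapering of the lungs, and additive
Gaussian noise (default σ = 20 HU, a realistic CT level). Geometry is
specified as fractions of the slice shape, so one spec scales across
resolutions; the ground-truth parenchyma mask is the analytic lung interior
minus lesion voxels. The bed with its air gap exists precisely because the
mean-intensity clustering branch keeps patches in that gap — the failure the
dual clustering and intersection are designed to fix — and the default body
ring is kept at least two patch widths thick so the minimum-intensity
branch always finds pure-body patches on its verification rays (at 8 × 8
patches this requires slices of roughly 128 × 128 or finer).

What the phantom does *not* emulate: vascular and airway texture inside the
parenchyma, the trachea (hence disconnected lungs), partial-volume ramps at
tissue boundaries, scanner-specific intensity shifts, and anatomical
variation across subjects. Passing the end-to-end tests therefore
demonstrates that the pipeline's machinery is correct and self-consistent
under its stated assumptions, not that the trained toy classifier would
transfer to clinical CT.

## Study sizes used by the tests and the acceptance script

Chosen once as the package's desk-scale study conditions: the end-to-end
study uses a noise-free 20-slice 256 × 256 phantom with one interior lesion
(radius 5% of the slice rows), training at the reference architecture
settings for 10 epochs with `scaled_learning_rate()`, and voxel-wise
segmentation keeping two components; failure-mode and mode-agreement checks
use 192 × 192 and 128 × 128 phantoms with threshold stub classifiers; the
oracle-equivalence checks use 1000 (k-means) and 200 (Hausdorff, AUC)
random cases; the tiling worked example streams 2,460 blank 512 × 512
slices in chunks. Unit tests use 64–192 px phantoms.

## Known limitations

* The weak labeller assumes the slice shows outside air, a closed body
  outline and a bed gap; cropped or contrast-enhanced acquisitions violate
  its premises.
* Patch-level labels are conservative at the lung boundary (the intersection
  trims straddling patches), so the classifier sees few boundary-mixed
  positives; segmentation accuracy at the boundary comes mostly from the
  window context.
* Exact Hausdorff is quadratic in boundary size; volumes beyond ~10^5
  boundary voxels take minutes.
* Only axial, fixed-resolution, single-window (32 × 32) analysis; no
  multi-scale ensembles, no lesion-specific segmentation.
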