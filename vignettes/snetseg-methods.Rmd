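---
title: "Methods: attention encoder-decoder segmentation of liver tumors on CT phantoms"
author: "snetseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention encoder-decoder segmentation of liver tumors on CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Liver tumors on CT are hard to segment automatically: lesions vary in size,
shape and location, and their Hounsfield-unit (HU) distribution overlaps the
surrounding parenchyma. `snetseg` implements a complete 2D slice-wise
pipeline for this problem: intensity preprocessing that amplifies the
liver/tumor contrast, a compact U-shaped convolutional network with a
channel + spatial attention block at its bottleneck, soft-Dice training with
plateau-based learning-rate reduction, morphological closing of the
predicted masks, and the LiTS metric family for evaluation. A seeded
synthetic phantom generator supplies liver-and-tumor CT look-alikes so the
entire pipeline builds, trains and validates on one CPU with no external
data.

The network and its training loop are implemented natively (R plus C++
convolution kernels): the forward and backward passes of every layer —
convolution, batch normalization, max-pooling, upsampling, attention — are
written out explicitly, and the whole composite gradient is verified against
central finite differences in the test suite (relative error around 1e-10
on sampled parameters of every layer class). A consequence worth knowing:
training here is exact mini-batch SGD with momentum, with none of the
nondeterminism of parallel GPU kernels, so identical seeds give identical
runs.

## The phantom generator

Each case is a small 3D volume whose axial slices contain, over an air
background at -1000 HU, a soft-tissue body ellipse and an elliptical liver
whose semi-axes follow a spherical-cap profile along z (end slices may hold
little or no liver). Tumors are unions of a main disk and up to two
satellite disks — giving irregular, non-convex borders so that closing and
the surface metrics are exercised on non-trivial shapes — placed entirely
inside the liver and spanning one to three consecutive slices with tapered
radii. Voxel HU values are drawn from configurable normal distributions
(defaults: liver 60 +/- 10 HU; tumor mean = liver mean - `contrast_gap`,
default gap 30 HU, +/- 10 HU; body 20 +/- 15 HU) plus additive acquisition
noise (5 HU). These defaults sit in the range reported for portal-venous
abdominal CT, where most hepatic lesions are hypodense relative to
parenchyma.

Per-case seeds derive from the master seed through a counter-based map, so
any case is bit-reproducible independently of cohort size or generation
order, and cohort generation spreads tumor radii across the configured
range so both size strata are populated.

What the phantom deliberately does not emulate: vessels and biliary
structures, partial-volume effects, reconstruction kernels and streak
artifacts, multi-organ anatomy, contrast-phase variation, and truly
ambiguous lesion borders. Passing the end-to-end test therefore shows that
the pipeline is wired correctly and can learn an HU-contrast segmentation
task — it does not certify clinical-grade accuracy on real scans, which is
exactly why external benchmark numbers are out of scope here.

## Preprocessing

* **Windowing**: clip to `(-100, 300)` HU and map linearly to `[0, 1]`.
  The window brackets parenchyma and lesions while discarding air and bone.
* **Point-to-point flip**: on the 8-bit rendering, every foreground
  (liver-mask) pixel `p` becomes `255 - p` and everything outside the liver
  becomes 0. Hypodense tumors turn bright on a gray liver over a black
  background. The flip is an involution on the foreground and is applied
  identically at train and inference time. The foreground mask is the
  ground-truth liver label during training and any user-supplied liver mask
  at inference; the package does not include a liver segmenter.
* **Grayscale float** (train only): one multiplicative factor
  `u ~ U(0.8, 1.2)` and one additive shift `v ~ U(-0.2, 0.2)` per image,
  applied to the `[0, 1]` image with clipping. The additive term is only
  meaningful on a normalized scale, which is why the float runs after
  normalization.
* **Geometric augmentation** (train only): one affine transform per slice
  per epoch — rotation up to 10 degrees, integer translation up to 4 px,
  optional mirror, shear up to 0.05 — applied jointly to the image
  (bilinear) and the masks (nearest neighbour, so masks stay binary and
  tumor-inside-liver containment is preserved). The warp is inverse-mapped
  about the pixel-grid center, so right-angle rotations permute grid points
  exactly.
* **Contrast filter** (train only): a tumor-bearing slice is dropped when
  `|mean HU(tumor) - mean HU(liver minus tumor)| < threshold` (default
  10 HU). Slices without tumor pass unconditionally, and validation/test
  sets are never filtered. The statistic and threshold are package choices
  (config-exposed): a difference of region means is the simplest statistic
  consistent with deciding contrast from the two HU histograms of a slice.

## The network

A U-shaped encoder-decoder configured by `snet_config()`:

* `depth` resolution levels (default 4), channels doubling from
  `base_channels` (default 32): 32-64-128-256. 3x3 kernels, two
  convolutions per block, each followed by batch normalization and ReLU;
  2x2 max-pooling between levels.
* The deepest block is the bottleneck and is refined by the attention
  block; placing attention once, at the junction of the contraction and
  expansion paths, keeps the module lightweight.
* The decoder mirrors the encoder: 2x upsampling (nearest-neighbour
  followed by a 3x3 convolution by default; a zero-insertion
  "transposed" variant is available), channel halving, and a long skip
  connection that **concatenates** each encoder level's output onto the
  same-resolution decoder level. Concatenation rather than addition: the
  two semantic streams are fused and the following convolution learns the
  mixture.
* A final 1x1 convolution and sigmoid give the per-pixel tumor
  probability. The network segments tumor only, on liver-masked input;
  predicting the liver itself is out of scope.

Defaults were chosen to keep the model small and CPU-trainable at 64-128 px
(depth 4/base 32 as the reference configuration, depth 3/base 16 for the
desk-scale experiments below).

**Attention.** The channel branch pools each channel plane to its spatial
average and maximum, passes both length-C descriptors through one shared
two-layer perceptron (hidden width `C/r`, reduction `r = 8`, ReLU), sums
the two outputs and normalizes. The spatial branch pools across channels to
per-position average and maximum maps, combines them with a 1x1 convolution
and normalizes. Refinement is sequential: multiply by channel weights, then
by the spatial map computed on the channel-refined features.

Numerical choices worth recording:

* **Softmax vs sigmoid.** The default normalization is softmax — weights
  are then probabilities over channels / positions. Softmax-normalized maps
  scale as `1/C` and `1/(H*W)` and would shrink the refined features, so by
  default the products are rescaled by the element count (`rescale = TRUE`),
  making uniform attention the exact identity. A sigmoid option (the usual
  choice in the convolutional block attention literature) is provided;
  rescaling does not apply to it.
* **Branch combination.** The two pooled descriptors are summed before the
  activation, the convention of the attention-module design this block
  reproduces.
* **Permutation equivariance.** The attention map is equivariant to channel
  permutation *jointly with its parameters*: permuting the input channels
  together with the perceptron's channel dimensions permutes the weights
  identically (this is what the tests check). Raw-parameter equivariance
  cannot hold for any perceptron that mixes channels; the spatial branch,
  which only pools over channels, is fully channel-order invariant.

**Initialization.** He-normal convolution weights; batch-norm scale 1 /
shift 0; and the final-layer bias starts at **-2**. The bias prior matters:
tumor pixels are a small minority, and a fresh network emitting probability
0.5 everywhere puts soft-Dice training into a long cold start in which it
must first unlearn a sea of false positives. Starting near background
(sigmoid(-2) is about 0.12) removes that plateau.

## Training

`train_snet()` runs exact SGD with momentum 0.9 (a conventional value; the
optimizer family is a momentum gradient method) on the soft Dice loss

    loss = 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)

computed per slice and averaged over the batch (default batch 16). The
initial learning rate is 0.01; when the validation loss has not improved
for 3 consecutive epochs the rate is multiplied by 0.1 (the reduction
factor is a package choice; the patience and initial rate follow the
training protocol the package implements). The weights from the epoch with
the highest validation Dice — hard Dice of thresholded maps at 0.5, the
evaluation-time statistic, distinct from the soft training loss — are
returned. A non-finite loss aborts with a diagnostic rather than continuing
from poisoned weights. "Cycles" in the source protocol are read as epochs.

**The smoothing constant `eps` defaults to 1**, the conventional
smooth-Dice constant, not a tiny epsilon. The difference is not cosmetic:
on a tumor-free slice the loss is `1 - eps / (sum(p) + eps)`, whose
gradient with a tiny epsilon is numerically zero — the network would feel
almost no pressure to suppress false positives on the many tumor-free
slices of a liver CT. With `eps = 1` those slices contribute a usable
gradient, and a slice predicted empty on an empty target scores loss 0.

Training-time augmentation is re-sampled every epoch and is configurable
(`augment = FALSE` turns it off); the deterministic preprocessing (window,
flip) is always applied and is embedded in the returned checkpoint so
inference replays it exactly — a mismatch raises an error.

## Post-processing and inference

`predict_volume()` preprocesses each axial slice, runs the network,
thresholds at 0.5 (ties to foreground), restacks, applies morphological
closing slice-wise (disk radius 1 by default; a 3D ball variant exists) and
finally re-intersects with the liver mask, since closing near the liver
border can bleed outside the region the network ever saw. Closing — dilate
then erode, outside of the array treated as background — removes narrow
interruptions and fills small cavities; it is extensive (never removes
foreground) and idempotent, and the implementation is tested for exact
equality with a brute-force per-pixel oracle.

## Evaluation metrics

For binary masks A (prediction) and B (reference):

* Dice `= 2|A n B| / (|A| + |B|)`; **Dice per case (DC)** averages the
  per-case Dice, **Dice global (DG)** pools all voxels first, so DG is
  dominated by large tumors. Conventions: both masks empty gives Dice 1;
  exactly one empty gives 0.
* **VOE** `= 1 - |A n B| / |A u B|`; the identity `VOE = 1 - D/(2 - D)` is
  checked property-style on random masks.
* **ASSD / RMSD**: boundary voxels are foreground voxels with a background
  face-neighbour (4-connectivity in 2D, 6 in 3D; the outside counts as
  background); directed boundary-to-boundary Euclidean distances (voxel
  spacing in mm) are pooled in both directions; ASSD is their mean and RMSD
  the root of their mean square. "RMSE" in the LiTS metric family is read
  as this RMS surface distance, the member of the same symmetric-surface
  family as ASSD. Empty masks leave the distances undefined: they are
  reported as `NA`, excluded from cohort means, and flagged with a warning.
* **Size stratification**: cases are labelled small/large by tumor voxel
  count against a cutoff, by default 0.2 of the cohort's maximum per-case
  count (an absolute-count mode is exposed, since a bare "0.2" threshold is
  ambiguous between the two readings); ties go to "large". Per-stratum DC
  and DG are reported alongside the cohort summary.

## Desk-scale problem sizes

The experiments the package runs on itself (test suite and
`scripts/acceptance.R`) use a 30-case phantom cohort of 8 slices at
64 x 64 px (about 200 liver-bearing slices), contrast gap 30 HU, a
case-level 70/10/20 split, a depth-3/base-16 network, and 30 epochs of
batch-8 SGD without augmentation — augmentation combats overfitting on real
data, whereas this scenario checks fast convergence on a clean task. The
batch of 8 doubles the number of gradient updates per epoch relative to the
package-wide default of 16, which matters at this small scale: soft-Dice
confidence grows slowly out of the background-prior initialization, and
with too few updates the thresholded masks of a slowly converging run can
remain empty for the whole budget. Under these conditions training reaches
a held-out Dice per case around 0.9 in about six minutes on one CPU. These
sizes are the package's reference desk-scale configuration; all of them
scale up through the configs.

## Known limitations

* 2D slice-wise only; no 3D convolutions and no cross-slice consistency
  beyond 3D closing.
* The liver mask is an input, not a prediction; a cascaded liver-then-tumor
  system is out of scope.
* The phantom's simplifications (above) mean phantom accuracy does not
  transfer to clinical data claims.
* Single-channel input, binary tumor output; no multi-class 0/1/2 head.
* Exact SGD on one CPU: wall-clock scales linearly with pixels x channels;
  the defaults are tuned for 64-128 px experiments, not 512 px clinical
  resolution.
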