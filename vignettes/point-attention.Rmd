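---
title: "Attention-weighted edge convolutions for point sets: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-weighted edge convolutions for point sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pointattn)
```

This vignette is the package's account of the method it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data does and does not emulate, and the numerical and design decisions made
where more than one reasonable choice existed.

## The model

A point cloud is an unordered set of N points in R³. Any function of it
must be permutation-invariant (classification) or permutation-equivariant
(per-point segmentation); the architecture achieves this by using only
shared per-point/per-edge maps and symmetric reductions (max, mean).

**Channel-weighted edge convolution.** Each layer builds a kNN graph: every
point is grouped with itself (stored first) and its k−1 nearest neighbors
under the Euclidean metric. Edge features (x_j − x_i, x_i) — the local
displacement plus the absolute position — are lifted by a shared 1×1 MLP
with batch normalization and a leaky-ReLU, then a squeeze-and-excitation
(SE) gate rescales each channel by a learned sigmoid scalar, and a max over
the group aggregates neighbors into the point's output feature. The max
(rather than a sum) follows the point-set convention: the strongest edge
response is the most informative statistic of a neighborhood. The channel
gate implements *channel attention*: it lets the layer emphasize the feature
channels that are discriminative for the task and damp the rest.

**Global attention mask.** The first layer's grouping is additionally
described by 10 fixed geometric channels per edge: {x_i, x_j, x_j − x_i,
‖x_j − x_i‖₂}. Feeding the Euclidean distance explicitly, although it is a
function of the other channels, spares the small mask MLP from having to
approximate a norm and accelerates learning of the mask. Two shared MLP
stages reduce these 10 channels to one response, a sigmoid maps it into
(0,1), and a max over each group yields one soft weight per point. The
global feature is multiplied point-wise by this mask and rectified. This is
*point attention*: characteristic regions (corners, boundaries, appendages)
get weights near 1, redundant interior points get damped, and the pooled
global representation is dominated by what distinguishes the object.

**Heads.** For classification, the masked global feature is max- and
average-pooled over points, the two pooled vectors are concatenated (2048-d
at the reference widths), and a three-layer MLP with dropout produces the
class logits. For segmentation, each point's feature is the concatenation of
the tiled one-hot object category, the point's masked global feature, and
the tiled rectified max-pool of the masked feature; a four-layer shared MLP
scores every point over the part vocabulary.

**Alternative attention modules.** The hard-attention variant averages the
sigmoid responses over the group and thresholds at 0.5 (inclusive — a mean
of exactly 0.5 keeps the point), producing a boolean mask that zeroes
dropped points entirely. The spatial-attention edge convolution attaches a
mask branch to a plain edge convolution; its descriptor omits the distance
channel, because the gradient of ‖x_j − x_i‖ is unbounded as two points
coincide and destabilizes training when the mask sits inside every layer.
Both are implemented as inference building blocks for comparison; the
trained pipelines use the soft global mask.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 20 | group size of the kNN query (self + 19 neighbors). Small k misses context; large k blurs local patterns at fixed point density. |
| `layers` | (64, 64, 128, 256) | output widths of the edge-convolution trunk (reference scale). |
| `global_width` | 1024 | per-point global feature width; pooled head input is twice that under max&avg pooling. |
| `activation` | leaky (slope 0.2) | leaky-ReLU trains slightly better than plain ReLU here; both are available. |
| `graph` | `"features"` | metric space of the kNN query for layers ≥ 2: dynamic (feature-space) graphs let deep layers group semantically; `"coords"` reuses the coordinate graph and is cheaper. |
| `dropout` | 0.5 | on the two hidden classification head layers. |
| `lr` | 0.03 | initial SGD learning rate, cosine-annealed to 0 over the epoch budget: lr(e) = 0.015·(1 + cos(πe/E)). |
| momentum / weight decay | 0.9 / 1e-4 | standard values for this model family; both configurable. |
| translation / scale augmentation | [−0.2, 0.2], [2/3, 3/2] | per-cloud uniform offset per axis and anisotropic per-axis scale; plus point shuffling. No rotation augmentation, by design. |

Units are those of the normalized clouds: coordinates live in the
centroid-centered unit sphere, so a translation of 0.2 is 20% of the
object's radius.

## Design decisions where the design was open

* **Group membership.** The center belongs to its own group and is stored
  first, so a group has exactly k members and the self edge feature
  (0, x_i) is always defined — also making k = 1 a valid degenerate layer.
* **Tie-breaking.** Neighbor ties in distance are broken by ascending point
  index. This makes the grouping, and hence every downstream computation,
  deterministic and permutation-consistent, which the permutation tests
  rely on.
* **Graph recomputation.** The dynamic-graph lineage recomputes the kNN
  query in each layer's feature space; the first layer always groups on
  coordinates. Both behaviors are exposed (`graph = "features"|"coords"`).
* **SE topology.** The gate squeezes by averaging each channel over all
  spatial positions of a sample, then applies two full-width dense stages
  with the layer nonlinearity between and a sigmoid after. There is no
  bottleneck reduction: at these widths the parameter saving is not worth
  the expressiveness loss.
* **Excitation/mask widths.** The internal width of the mask branch is not
  dictated by the architecture; 64 is the default here (`mask_hidden`).
  Batch normalization sits after the first mask stage, before the
  activation; the final stage feeds the sigmoid directly.
* **Biases before batch norm.** Dense layers immediately followed by batch
  normalization carry no bias: the normalization subtracts any constant
  shift, so such a bias is an exactly-zero-gradient dead parameter (the
  finite-difference suite confirms this), and its shift role is taken by
  the normalization's beta.
* **Global feature input.** By default the global MLP consumes the
  concatenation of all trunk layer outputs (512 channels at reference
  widths), consistent with a 1024-wide global feature and a 2048-wide
  pooled head input; a narrower variant consuming only the last layer is
  available (`global_from = "last"`).
* **Head widths.** The classification head is 512 → 256 → m with dropout on
  the hidden layers; the reduction factor between the hidden widths is the
  configurable quantity.
* **Loss.** Cross-entropy on raw logits; softmax lives only inside the
  loss. No label smoothing.
* **Rotation-robustness axis.** Rotation sweeps default to the gravity (z)
  axis — the axis about which real scanned objects are most plausibly
  re-oriented — and the axis is configurable.
* **Absent-part IoU.** A part admissible for a category but present in
  neither prediction nor ground truth contributes IoU 1 to the shape mean,
  matching the established part-segmentation evaluation lineage.

## Synthetic data: what it emulates and what it does not

`make_shape` draws uniform area-weighted surface samples from five analytic
families (sphere, cube, torus, cylinder, cone), generated directly at their
unit-normalized size (farthest surface point at radius 1, centered) and
jittered with Gaussian noise (σ = 0.01 by default, in normalized units).
`make_part_labeled_shape` labels cylinder points side/top/bottom and cone
points side/base, exactly at the analytic boundaries when σ = 0.
`sample_volume` emulates fixed-size point sets extracted from 3-D density
maps: a mixture of Gaussian blobs is rasterized on a voxel grid spanning
[−1, 1]³, exactly n voxels are drawn with probability proportional to
density, and each point is jittered uniformly within its voxel. "Constant
sampling" is interpreted as this density-proportional draw of a constant
point count per volume. `make_dataset` builds stratified, disjoint,
seed-reproducible train/test splits in either mode.

These generators give the network data with the right *structure* —
unordered, unit-normalized, fixed-size clouds whose classes differ in local
geometry — and a nearest-centroid baseline on crude shape descriptors
already separates the classes, so the learning task is well-posed. They do
**not** emulate the hard parts of real data: CAD meshes' sharp feature
distributions, scanning occlusion, or cryo-tomography physics (missing
wedge, contrast transfer, structured noise). Passing the test suite
therefore demonstrates that the implementation is correct and that the
architecture learns and degrades as designed — not that it attains any
particular accuracy on real benchmarks, which require external datasets and
GPU-scale training far beyond this package's scope.

## Study problem sizes

The desk-scale classification study used throughout the tests and the
acceptance script is: 4 shape classes, 400 training and 100 test clouds of
256 points, k = 20, trunk widths (16, 16, 32), global width 64, coordinate
graphs. 40 of the 400 training clouds are held out as validation; training
runs SGD with the cosine schedule over a 30-epoch budget and stops early
once validation accuracy saturates at 100% (on this task that typically
happens within a handful of epochs). The part-segmentation study uses two
categories (cylinder, cone) with a joint 5-part vocabulary, 72 training, 8
validation and 20 test shapes, trained without translation/scale
augmentation: the analytic part boundaries live in object coordinates, and
at this model scale augmentation-invariance and part discrimination compete. These sizes were chosen as the smallest at
which the learning behavior is unambiguous; the full-scale reference
configuration (1024-point clouds, widths (64, 64, 128, 256), hundreds of
epochs) is expressible with the same configuration objects.

## Numerical choices

* Batch normalization uses the biased batch variance with eps = 1e-5 and
  running statistics updated with momentum 0.1; inference uses the running
  statistics (so single-cloud inference is well-defined and
  permutation-invariant). The functional layer ops normalize with the
  statistics of the given input.
* The kNN query computes exact squared Euclidean distances and selects with
  a lexicographic (distance, index) comparator — no approximate
  nearest-neighbor structures at these problem sizes.
* Gradients are hand-written for every block; the test suite validates all
  of them against central differences per parameter tensor (relative error
  below 1e-4 at double precision). The kNN graph itself is treated as
  non-differentiable (gather indices), as in the dynamic-graph lineage.
  Gradient checks use batches of at least two clouds: batch statistics over
  a single sample make the head's normalization degenerate and sink the
  upstream gradients below finite-difference resolution.
* Max reductions break ties by the first maximal entry; subgradients are
  routed to that entry alone.
* Dropout is inverted (scaling at train time), so inference is a plain
  forward pass.
* Checkpoints are R serializations of the full parameter set, configuration
  and seed; they round-trip bit-exactly.

## Known limitations

* Training is CPU-bound and memory-bandwidth-limited; the reference-scale
  configuration is expressible but not practical to train here.
* The per-point attention mask consumes only first-order geometry of the
  input grouping; masks on deeper feature-space groupings are the
  spatial-attention variant's territory and are provided for inference
  only.
* Point-cloud I/O covers OFF, PLY (ascii and binary little-endian),
  whitespace XYZ and a plain-text stacked-cloud table; meshes are consumed
  by area-weighted vertex/surface sampling only — no rendering, repair or
  topology handling.
* `evaluate_model` assumes single-label whole-cloud classes; multi-label
  clouds are out of scope.
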