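---
title: "Fused texture and keypoint features for expression recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused texture and keypoint features for expression recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(exprfeat)
```

## Overview

`exprfeat` implements a classical (non-deep-learning) feature pipeline for
recognizing facial expressions from static images, aimed at settings where
hardware budgets rule out neural networks. The pipeline is:

1. **Face region extraction** — a 68-point facial landmark set (supplied by
   the caller, by a sidecar file, or by the synthetic generator) defines the
   face; the axis-aligned bounding box of points 1–27 (jaw plus both
   eyebrows) is cropped and resized to a standardized 130×130 grayscale
   region.
2. **Uniform-LBP texture features** — local binary pattern codes over the
   128×128 interior, pooled into per-patch 59-bin uniform-pattern histograms.
3. **Region-balanced ORB keypoint features** — FAST corners detected under a
   per-region budget, oriented by the intensity centroid, and described by
   steered 256-bit BRIEF descriptors.
4. **Fusion** — per-block Z-score standardization (spread `K`, offset `C`)
   and concatenation.
5. **Classification** — an RBF-kernel support vector machine evaluated under
   subject-dependent (SD) and subject-independent (SI) repeated 10-fold
   cross-validation.

Everything runs end-to-end on synthetic face images with known ground truth,
so the whole pipeline is testable without any external image collection.

## The LBP stage

The LBP operator thresholds the 8 neighbors of each pixel at the center
intensity: bit $n$ is $s(i_n - i_c)$ with $s(u) = 1$ for $u \ge 0$ and $0$
otherwise, and the code is $\sum_{n=0}^{7} 2^n s(i_n - i_c)$. Ties count as
1 — so a perfectly flat neighborhood codes 255, and the code map is exactly
invariant to adding a constant to, or positively rescaling, the image.

Choices the operator definition leaves open, and how they are fixed here:

* **Neighbor ordering.** Bits are assigned clockwise from the top-left of
  the 3×3 neighborhood. Any fixed ordering is a bit permutation that leaves
  uniform-pattern membership unchanged; the convention is pinned in code and
  tests so codes are reproducible.
* **Uniform binning.** A code is *uniform* when its circular bit string has
  at most 2 transitions; exhaustive enumeration gives exactly 58 such codes,
  assigned bins 0–57 in ascending code order, with all 198 remaining codes
  pooled into bin 58 (59 bins total).
* **Patch geometry.** The phrase "16×16 patches with a resolution of 8×8"
  admits two readings; we take 16×16-*pixel* patches, i.e. an 8×8 grid of 64
  patches on the 128×128 code map, giving a 64 × 59 = 3776-dimensional
  feature. `patch_size` is a configuration field, so the other reading
  (8×8-pixel patches, 256 × 59 dimensions) is one argument away.
* **Histogram normalization.** Patch histograms are kept as raw counts; all
  scaling is deferred to the fusion stage, whose per-block standardization
  makes any positive rescaling of the LBP block a no-op anyway (this is
  asserted as a regression test).

## The keypoint stage

**FAST segment test.** A pixel is a corner when at least 12 contiguous
pixels of the 16-pixel Bresenham circle are all at or above $I_p + t$ or all
at or below $I_p - t$. The corner score is the larger of
$\sum_{x \in S_{bright}} (I_x - I_p - t)$ and
$\sum_{x \in S_{dark}} (I_p - I_x - t)$ — the threshold subtracted per
pixel, the standard reading, which makes the score monotone in contrast and
zero on flat images.

**Region-balanced budgeting.** The image is tiled into `grid_m × grid_n`
even regions sharing a total budget of `n_keypoints` corners, quota
$T = \lfloor n/(MN) \rfloor$ per region. When a region yields fewer than $T$
corners, its threshold is relaxed geometrically ($t \leftarrow \max(1,
\lfloor t/2 \rfloor)$), stopping at $t = 1$ — the floor prevents the
infinite relaxation loop a flat region would otherwise cause, and a
remaining deficit is refilled from the best surplus candidates of other
regions (so the total equals `n` whenever enough corners exist anywhere;
truly flat images return fewer, with a warning, and the feature vector is
zero-padded with a validity mask). The budget remainder goes one-each to the
regions with the strongest top corner. Non-maximal suppression keeps a
corner only when its score is a strict 3×3 local maximum among the region's
detections, ties broken by row-major position. The motivating property —
per-region keypoint counts under balanced detection vary strictly less than
under global top-`n` selection on contrast-clustered images — is asserted in
the test suite.

**Orientation and description.** Keypoint orientation is the intensity
centroid angle $\theta = \mathrm{atan2}(m_{01}, m_{10})$ over a radius-15
disk. Descriptors compare box-smoothed (5×5) intensities at 256 Gaussian
placed pairs — i.i.d. $\mathcal{N}(0, S^2/25)$ with $S = 31$, rounded and
clipped to the 31×31 window — with the pair coordinates rotated by $\theta$
(nearest pixel) before lookup. The realized sampling pattern is generated
from a pinned seed (`pattern_seed`, default 1234) so descriptors are
bit-reproducible across machines. Corners whose 35×35 window would leave the
image are excluded at detection time (a 17-pixel candidate margin), so every
retained corner is describable. Descriptors are concatenated region-major,
within region by descending score, into a fixed `n_keypoints × 256`-bit
vector — a fixed-length assembly chosen here because a variable keypoint set
must become a fixed-length classifier input somehow and the source method
leaves this unspecified.

Default detector settings (`n_keypoints = 160`, `grid_m = grid_n = 4`,
`t0 = 30`) are configuration fields; no published values exist for them, so
they were chosen once as round numbers that fill a 130×130 face with a 10
corner quota per region.

No scale pyramid is implemented: the method description contains no
multi-octave machinery, so none was invented.

## Fusion

The LBP block is first max-normalized to $[0,1]$ ($L = l / \max l$, the
all-zero vector mapping to itself), then each block is standardized
independently to mean `C` and *population* standard deviation `K` and the
blocks concatenated LBP-first. Two printed ambiguities are resolved as
follows: the spread formula is taken as the population standard deviation
(the printed form, a bare sum of squares, is dimensionally inconsistent with
a Z-score), and the offset constant `C` — never assigned a value in the
source — defaults to 0. `K = 100` as stated. Standardization is per-vector
and per-block: the block index runs over one feature vector's entries.
A constant block (zero spread) maps to the constant `C`.

## Classification protocol

The classifier is a C-SVM with RBF kernel (libsvm via `e1071`, one-vs-one
multiclass). Two protocols are implemented:

* **SD (subject-dependent)** — a label-stratified random partition of the
  *images* into 10 folds; a subject may appear on both sides of a fold.
* **SI (subject-independent)** — a partition of the *subjects* into 10
  groups; no subject identifier ever appears on both sides. This is the
  deployment-realistic protocol.

Each experiment is repeated (10 repetitions by default; fresh folds each
time) and accuracies pooled. Hyperparameters are chosen by an *inner* 5-fold
grid search on each outer training fold — a nested search, since a grid
search on the full data would leak test information into model selection.

Two numerical choices deserve explanation:

* **Relative kernel-width grid.** Fused vectors are standardized to spread
  `K = 100`, so squared distances between them are of order $10^8$–$10^9$;
  any fixed absolute $\gamma$ grid either collapses the kernel to the
  identity or flattens it to all-ones. The grid is therefore expressed as
  multipliers of the median heuristic $\gamma_0 = 1/\mathrm{median}(\|x_i -
  x_j\|^2)$ computed on the training fold, which adapts the search to
  whatever feature scaling is in force. The default grid is cost
  $\in \{2^{-1}, 2^3, 2^7\}$ × multiplier $\in \{2^{-2}, 2^0, 2^2\}$ — a
  compact grid whose extremes were never selected as best in exploratory
  runs; wider grids are one `svm_config()` call away.
* **Distance-preserving embedding.** The RBF kernel sees the features only
  through pairwise squared distances, so before fitting, the feature rows
  are re-expressed by classical multidimensional scaling of the full
  squared-distance matrix into at most $n$ coordinates. This is exact (not a
  dimensionality reduction: measured distance error is at machine
  precision), leaves every kernel value unchanged, and lets libsvm work on
  length-$n$ vectors instead of ~40,000-dimensional ones. It is equivalent
  to precomputing the kernel on the pooled data and is label-free.

Degenerate folds: in SD mode a fold whose training side lost a class is
redrawn from a shifted seed (bounded retries); in SI mode — where a subject
partition can force class absence — the fold is accepted with a warning.
Folds are always computed on records sorted by `(path, subject, label)`, so
the partition is invariant to manifest row order.

## The synthetic generator

`synthetic_spec()` describes a deterministic generator of face-like images
with known ground truth, standing in for a small laboratory expression
database (default 10 subjects × 7 classes × 3 replicates = 210 images of
160×160 pixels). Each image is a pure function of
`(seed, subject, class, replicate)`.

What it emulates, and how:

* **Faces and landmarks.** A canonical 68-point layout (jaw arc, brows,
  nose, eye hexagons, lip ellipses) is placed on an oval face and warped by
  a per-subject similarity jitter (±5% scale, ±3° rotation, ±2 px
  translation). The ground truth records the exact crop box implied by
  points 1–27, so the cropper can be checked pixel-wise against the
  generator's own stored patch.
* **Class signal, two channels.** A class is a *(texture, constellation)*
  pair: an oriented sinusoidal grating inside the face oval (4 orientation /
  frequency combinations, read by the LBP histograms) and a constellation of
  12 high-contrast 3×3 blobs (2 layouts, read by the corner detector).
  With 7 classes some pairs share their texture and differ only in the
  constellation, and vice versa — so neither feature family alone separates
  every class, and fusing them genuinely helps. This mirrors the reason the
  two families are fused in the first place.
* **Subject identity.** Subjects carry a global brightness offset, the
  similarity warp, a subject-specific distortion of the class texture
  (orientation offset up to ±18°, frequency scaling ±10%, slight blob
  displacement), and a *subject identity grating* — a secondary oriented
  texture, fixed per subject across all classes and replicates, emulating
  identity-specific skin and facial structure. The distortions overlap
  neighboring classes across subjects while staying consistent within a
  subject: this is what makes recognizing a new subject (SI) genuinely
  harder than held-out images of a known subject (SD).
* **Replicates.** The grating phase belongs to the (subject, class) pair,
  with a small per-replicate drift (0.4 rad) plus fresh pixel noise
  (Gaussian, SD 12, clipped to [0, 255]) — replicates are repeated
  photographs of the same face, alike but not identical, which is exactly
  the mechanism that inflates SD accuracy over SI in real databases.

What it does **not** emulate: photorealistic faces, illumination direction,
pose, occlusion, demographic diversity, or detector failure on landmarks.
Passing tests therefore show the pipeline's internal contracts and its
qualitative protocol behavior (SD ≥ SI, fusion competitive with the best
single family), not performance on real photographs.

## Problem sizes and determinism

The default end-to-end benchmark (`synthetic_benchmark()`) runs the full 210
image dataset with 2 repetitions of 10-fold cross-validation and the compact
3×3 hyperparameter grid — sizes chosen so a complete run finishes in minutes
on a single CPU while leaving the qualitative orderings stable across seeds.
Users reproducing the full published protocol scale (10 repetitions, wider
grids) can pass `repeats = 10` and a larger `svm_config()`.

All randomness flows from explicit integer seeds: the generator derives a
sub-seed per image, fold assignment derives one per repetition, and the
BRIEF pattern seed is pinned in the configuration. Pixel outputs are
integer-valued, so generated datasets are identical across platforms.

## Known limitations

* The crop uses the bounding rectangle of landmark points 1–27 without
  polygon masking; background pixels inside the rectangle reach the texture
  operators. Masking was rejected because zeroed regions would create
  artificial LBP codes and FAST corners along the mask boundary.
* Only PNG and PGM images are read natively.
* Keypoint counts below the budget (flat inputs) are zero-padded; the
  validity mask is carried on the feature object but the classifier does not
  currently use it.
* The SD > SI accuracy ordering is a property of data with subject-specific
  structure; on data without it the two protocols coincide up to fold noise.
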