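---
title: "Tracing the left-ventricle endocardium with a double-DQN agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the left-ventricle endocardium with a double-DQN agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgewalk)
```

## The problem and the model

Delineating the left-ventricle (LV) endocardium in short-axis cardiac MR
slices is usually posed as dense per-pixel classification. `edgewalk`
implements a different formulation: segmentation as *sequential boundary
tracing*. A convolutional **first-point network** looks at the whole image
once and proposes (a) a coarse edge-probability map at 1/8 resolution and
(b) the first boundary point. A **double deep Q-network (DQN) agent** then
walks along the boundary: at each step it observes a small window centred on
the current edge point and chooses one of eight directions; the visited
points, joined in order and closed, are the segmentation contour, and their
filled polygon is the mask. This mirrors how a human delineates a structure —
fixate an edge, then follow it — and it outputs an ordered point list rather
than independent pixel probabilities.

### The Markov decision process

**State.** The agent sees a `w × w × 5` stack centred on the current point:

1. the grayscale window,
2. its Sobel gradient-magnitude window,
3. a window of the 8×-bilinearly-upsampled edge-probability map,
4. a binary window of previously visited points, and
5. the whole probability map resized to `w × w` (fixed per episode — the
   global shape prior).

All image-derived layers are min–max normalized to [−1, 1]. When the window
overruns the image border, the in-bounds part is cropped and bilinearly
resized back to exactly `w × w` (the crop-and-resize rule familiar from
region-based detectors); the resized past-points layer is re-binarized by
rounding so its invariant (values in {0, 1}) survives interpolation.
Layer subsets ("SP": drop both probability layers; "SCG": drop the
past-points layer) are exposed as a configuration switch so the state
ablation can be run without code changes.

**Actions.** Eight *skip neighborhoods*: the candidate points at offset `n`
pixels in the eight compass directions. Only two directions are anchored by
the source description (action 4 is "down", action 7 is "up-right"); the
full map is the counterclockwise-from-up assignment `0 = up, 1 = up-left,
2 = left, 3 = down-left, 4 = down, 5 = down-right, 6 = right, 7 = up-right`,
which satisfies both anchors. It is documented as the single source of truth
and deliberately not configurable. Moves are clamped at image borders rather
than terminating the episode.

**Reward.** Three terms, each isolatable for ablation:

* *Difference-IoU* `Rd ∈ {−1, 0, +1}`: the sign of
  `IoU(Mcurr, GT) − IoU(Mprev, GT)`, where `Mcurr` is the polygon of all
  points so far and `Mprev` omits the last 5 points (a 5-point interval
  makes the difference large enough to carry signal). When fewer than 6
  points exist, `Mprev` is the first point alone. The comparison is done on
  integer pixel counts by cross-multiplication, so exact ties give 0 without
  floating-point hazards.
* *Edge distance* `Re = ratio · (10 − dist)` for `dist < 10`, else 0, with
  `ratio = 0.05`: a dense attraction toward the true boundary, deliberately
  normalized to [0, 0.5] so `Rd` stays dominant.
* *Point clustering* `Rp = −0.5` when the dispersion of the last 20 points
  falls below 10 px, else 0: a penalty against circling in place. The
  dispersion of 2-D coordinates is not fully specified by its source ("the
  standard deviation of the last 20 edge points coordinates"); we use
  `sqrt(var(rows) + var(cols))` with population variances — zero iff all
  points coincide, monotone in spatial spread, and equal to the RMS distance
  from the centroid. Windows with fewer than 20 points score 0.

The per-step reward is the sum of the enabled terms; with defaults its
attainable range is exactly [−1.5, 1.5], which the test suite verifies by
construction. An F-measure-difference variant of `Rd` exists only so tests
can exercise the comparison; it is not tuned or recommended.

**Termination.** Episodes are capped at `max_steps`. After a step gate
(`reduce_after_step`), approaching within `reduce_distance` of the first
point lowers the skip distance (5 → 3 at full size) for a denser finish, and
within `close_distance` the episode closes. The gate also applies to the
closure check — otherwise the agent could "close" on its second step. The
distance is Euclidean to the *first* point (not to the nearest trajectory
point), matching the stated closure rule. The closing step's reward uses the
standard formula unchanged; as a terminal transition it is not bootstrapped.

### Double DQN

The action-value network is a reduced 18-layer-style residual backbone
(block counts [1,1,1,1]) with global average pooling and a linear 8-way
head. Two copies are kept: the evaluation network, updated every step once
the replay buffer is full, and the target network, overwritten with the
evaluation parameters every `sync_period` updates. Targets use the double-Q
rule — the *evaluation* network chooses `argmax_a Q(s′, a)`, the *target*
network scores it:

```
y = r + γ · Q_targ(s′, argmax_a Q_eval(s′, a))      (y = r at terminals)
```

which curbs the overestimation of the vanilla max target; the tests include
a hand-evaluated case where the two rules disagree. The loss is the mean
squared TD error of the taken actions, with gradients flowing only through
`Q_eval(s, a)`. The replay buffer is a FIFO ring; sampling is uniform
without replacement within a batch; learning starts only when the buffer
holds its full capacity. Exploration is ε-greedy with ε = 0.2 — kept at 0.2
*also at inference*, as the method prescribes; `epsilon = 0` (`--greedy`)
is available because stochastic inference is unusual, but it is not the
default.

### First-point network

A four-stage reduced residual encoder; each stage output is projected by a
3×3 convolution and rectifier, bilinearly resized to half the input
resolution, and concatenated; four 3×3 blocks reduce the fusion to 1/8
resolution and a 1×1 projection gives a single-channel score map. Training
minimizes per-pixel binary cross-entropy against a binary target with a 1 in
every 1/8-scale cell containing a ground-truth contour point (floor
division). Selection takes the argmax cell — log-softmax is monotone, so the
argmax is taken directly on scores; ties break at the smallest column-major
index — and maps it to full resolution at the cell centre (`8·(r−1) + 5` in
1-based coordinates; the offset is not specified by the source, and the cell
centre minimizes worst-case quantization error). The network's 3-channel
input is `[gray, Sobel, gray]`: the probability map does not exist before
this network runs, and the third channel of the described input is not named
— duplicating the grayscale layer is our resolution of that open question.

## Profiles: full-size vs desk

Every hyperparameter lives in a config object; two named profiles ship.

| parameter | full size ("full") | desk | note |
|---|---|---|---|
| image side `W` | 368 | 96 | desk ≈ 1/3.8 scale |
| state side `w` (crop) | 51 (51) | 25 (51) | desk crops 51 px, resizes to 25 |
| skip `n` (initial → reduced) | 5 → 3 | 5 → 3 | kept literally |
| step gate / reduce / close | 100 / 40 px / 20 px | 25 / 12 px / 6 px | distances ÷ ~3.3 |
| max steps | 300 | 100 | ~3 laps (a desk lap is ~35 steps) |
| replay capacity | 21,000 | 2,000 | |
| batch / sync | 256 / 2,000 | 8 / 200 | see below |
| DQN lr | 1e-4 | 1e-3 | small nets tolerate larger steps |
| DQN widths / head pool | 64–512 / 1×1 | 8–24 / 2×2 | see architecture note |
| first-net lr / batch | 1e-5 / 1 | 1e-3 / 1 | |
| γ, ε | 0.9, 0.2 | 0.9, 0.2 | shared |

The full-size profile preserves the published protocol but is GPU-scale;
nothing in the test suite trains it. The desk profile is the package's
stated world for continuous-integration-scale evidence: 96 px phantoms,
narrow backbones (Q-net stages 8/12/16/24; first-net stages 8/16/24/32),
and a batch of 8. Batch size and widths were sized once for the compute
budget of a single CPU — per-update cost scales with batch × width — not
tuned against any acceptance outcome. Two architectural adaptations came
out of failure analysis at this scale: the state's source window is cropped
at 51 px and resized to the 25 px tensor (a raw 25 px window sees only 2.4
skip-moves of context, which produced systematic direction flips), and the
head pools adaptively to 2×2 rather than 1×1 (24 channels cannot carry
direction through a location-blind global average; 512 can). Training runs
~5,000 environment steps: 2,000 random-policy steps to fill the buffer,
then one gradient update per step.

## The synthetic phantom world

`generate_phantom()` draws a star-convex boundary
`r(θ) = R + Σₖ aₖ sin(kθ + φₖ)` minus Gaussian angular notches, densely
sampled into an ordered counterclockwise contour; the mask is its filled
rasterization, and the image is a three-level intensity model (bright blood
pool ≈ 0.85, darker myocardial ring ≈ 0.30, background ≈ 0.10) degraded by
a smooth low-order bias field, Gaussian blur, and additive noise. The
notches mimic papillary muscles and trabeculations — boundary depressions
with myocardium-like intensity. A star-convex radial model is appropriate
because the LV blood pool is, to first order, a round object; that roundness
is exactly the shape prior the probability-map state layers carry.

What the phantoms do *not* emulate: true MR physics (coil profiles beyond a
smooth bias, k-space artifacts), anatomical pathology spectra, multi-slice
or temporal structure, and neighbouring structures (right ventricle, lungs).
A green desk-scale test therefore establishes that the *mechanism* works —
the MDP is well-posed, rewards are informative, the agent's F-measure and
reward improve with training and degrade under ablation — not that the
published real-data accuracy is reproduced. The published ACDC/Sunnybrook
numbers require GPU training on gated clinical data and are out of scope.

## Numerical choices

* **Polygon fill:** even-odd scanline with the `ymin ≤ y < ymax` vertex rule,
  then a union with Bresenham-drawn edges so boundary pixels are always
  included. An axis-aligned square of side `s` fills to `(s+1)²` pixels
  (inclusive raster convention); degenerate (collinear) "polygons" yield
  their line pixels.
* **IoU of two empty masks** is 0 (episode-start degenerate case).
* **Precision of an empty prediction** is 0; F is 0 when P = R = 0.
* **APD** averages, over predicted points, the distance to the nearest
  ground-truth *point* (not segment); generated ground-truth contours are
  ~0.5 px-spaced, making the difference sub-pixel. Traced points enter as-is,
  without resampling.
* **Sobel borders** use edge replication; magnitude is `sqrt(gx² + gy²)`.
* **Coordinates** are 1-based (row, col) in R, row increasing downward; the
  on-disk contour dialect ("x y" per line, x = column) remains 0-based and
  is converted at the I/O boundary.
* **Batch normalization** in the original conv blocks is replaced by He
  initialization + bias: the engine is hand-written (no NN library exists in
  the target stack), a correct BN backward would nearly double its surface,
  and the narrow desk networks train stably without it.
* **Argmax ties** (first point, greedy action) break at the smallest index,
  keeping inference deterministic.
* **Determinism:** the environment's transition function is a point mass;
  all stochasticity (init, ε-greedy, sampling, phantom draws) flows from
  explicit seeds, and the test suite checks bit-identical repeat runs.

## Engine notes

Convolution forward and backward passes are compiled (Rcpp/Armadillo:
im2col gather + GEMM, and a col2im scatter-add for input gradients); the
remaining layers (bilinear resize, pooling, dense) are plain R matrix
algebra. A pure-R conv path was profiled first and was memory-bandwidth
bound on virtualized hardware — an order of magnitude slower. Gradients of
every layer type are verified against central finite differences in the
test suite. Adam is the only optimizer. A practical consequence of Adam on
tabular tests: its terminal oscillation is of order the learning rate, so
the chain-MDP convergence test runs at `lr = 3e-3` to sit safely under its
1e-2 tolerance.

## Known limitations

* Desk-scale training is evidence of *mechanism*, not of accuracy: with
  ~3,000 batch-8 updates the held-out F-measure typically lands between 0.2
  and 0.6 depending on the training seed (the acceptance suite computes and
  reports this), with individual traces reaching 0.8+. The full protocol's
  accuracy requires orders of magnitude more optimization than one CPU
  provides. The training-seed variance is large; the wrong-initial-direction
  failure mode the method itself reports dominates the residual error.
* The desk profile's accuracy ceiling is also set by the 5-px skip and
  ε = 0.2 inference noise; contours are polygonal with ~40 vertices.
* A wrong early turn can trap the agent on the far side of the pool; the
  method itself notes this failure mode, and no recovery heuristic is added.
* Single closed contour only: no holes, no multi-object scenes, no 3-D.
* The pure-R engine is CPU-bound; the full-size profile is declared but not
  practically trainable here.
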