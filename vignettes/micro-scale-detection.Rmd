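---
title: "Detecting dense micro-scale plant targets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dense micro-scale plant targets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microdet)
```

## The problem

Invasive weeds such as giant ragweed (*Ambrosia trifida*) appear in UAV
orthophoto tiles as many small, densely packed, partially occluding green
blobs, typically only 50–450 px² each in a 640×640 tile. Three properties
make this regime hard for a stock single-shot detector:

* most targets fall below the finest default detection grid, so a single
  grid cell must explain several plants;
* the size distribution is broad and uneven, so anchors fitted to the whole
  dataset over-serve the most common size;
* overlapping leaves produce clusters of near-duplicate candidate boxes
  that greedy suppression resolves poorly.

`microdet` implements the corresponding remedies as a tested R library: a
**micro-scale (stride-4) detection head**, **size-stratified anchor
estimation by k-means under the IoU distance**, the **EIoU / Focal-EIoU
bounding-box regression losses**, and **weighted box fusion (WBF)** as an
alternative to NMS, together with the evaluation protocol (greedy IoU-0.5
matching, precision/recall/F1, all-point interpolated AP) and a synthetic
scene generator that emulates the data regime.

## Box geometry

Corner boxes are continuous with half-open extent, so `area = (x2−x1)(y2−y1)`
and IoU is exact under affine rescaling — a property the multi-resolution
fusion path relies on. Boxes touching only along an edge have IoU 0.
Normalized center-format labels (`class cx cy w h`, the LabelImg/YOLO text
dialect) clamp sub-pixel overshoot (≤ 1 px, as produced by tiling remaps)
with a warning and reject anything larger.

## Size-stratified anchors

Ground-truth (w, h) pairs are stratified into 4 groups by the empirical
quantiles of √(w·h) (the paper-of-record for this choice of size measure is
silent on how groups are bounded; quantiles guarantee balanced groups,
which directly addresses the motivating imbalance). Inside each group we
run k-means with the **position-free IoU distance**: both boxes concentric,
`d = 1 − min(w₁,w₂)·min(h₁,h₂) / (w₁h₁ + w₂h₂ − ∩)`. The smallest group's
three centers become the stride-4 anchors, and so on up to stride 32.

Two numerical choices deserve note:

* **Initialization** is k-means++ under the same distance (seeded); plain
  random selection is available via `init = "random"` for fidelity
  checks. Empty clusters re-seed to the worst-fit box.
* **Center updates with a monotonicity guard.** The member mean minimizes
  a squared-Euclidean surrogate, not the IoU objective, and occasionally a
  mean step *raises* the objective. Because a non-increasing objective
  trace is part of this package's contract (and of standard k-means
  intuition), a mean step that would increase a cluster's summed IoU
  distance is rejected and the previous center kept. Accepted updates are
  plain means; in practice the guard fires rarely and the trace is
  provably non-increasing.

The bundled `default_anchor_preset()` carries the stock three-level
anchors; the stride-4 level — for which no published default exists — is
the stride-8 triple halved, (5,7), (8,15), (17,12), preserving the
geometric progression across levels.

## Loss family

For a predicted box `b` and target `b_gt`, with enclosing box width/height
`w_c, h_c` and center distance ρ:

* CIoU: `1 − IoU + ρ²/c² + αν`, `ν = (4/π²)(arctan w/h − arctan w_gt/h_gt)²`,
  `α = ν/((1−IoU)+ν)`. α and ν are not defined in the original text and are
  taken from the CIoU literature it cites — the only self-consistent
  reading.
* EIoU: `(1−IoU) + ρ²/(w_c²+h_c²) + (w−w_gt)²/w_c² + (h−h_gt)²/h_c²`. The
  width/height terms replace the aspect-ratio penalty and directly shrink
  the size mismatch; ρ²(w, w_gt) is read as the squared scalar width
  difference (the ρ symbol is reused in the source without redefinition,
  and its "k_gt" in the height term is an evident typo for h_gt).
* Focal-EIoU: `IoU^γ · EIoU`, implemented literally. γ (default 0.5)
  controls outlier suppression. The literal form gives zero loss *and zero
  gradient* for disjoint pairs — a cold-start pathology — so training warms
  up with plain EIoU for `warmup_iters` steps (default 200).

Every denominator carries an `eps ≤ 1e-6` guard; identical boxes return
exactly 0.

## Fusion

`nms()` is the textbook greedy suppression. `wbf()` clusters boxes greedily
in descending score order against each cluster's *running fused box*
(matching against the seed box is a config toggle), fuses coordinates as
score-weighted means `C = Σ sᵢxᵢ / Σ sᵢ`, and scores as the arithmetic mean
of members — the two-box rule generalized to N members, to which it reduces
exactly at N = 2. A weighted-mean score was deliberately rejected to stay
literal. Defaults: cluster IoU 0.55 (the WBF literature's standard),
score floor 0.001; the source states neither. Fusion is per class.

`fuse_multiresolution()` rescales each resolution's detections into the
target frame (IoU is invariant under this map), concatenates, and applies
WBF with the reference procedure's *corroboration weighting*: after
fusion across `T` passes, each cluster's score is multiplied by
`min(n_members, T)/T`, so a box confirmed by fewer passes ranks lower.
This step matters. Without it, pooled single-threshold AP systematically
favors NMS — surviving NMS duplicates act as extra recall chances ranked
at the tail, while a WBF split-cluster singleton carries its full raw
score and interleaves above merged true positives — even though the
fused boxes localize measurably better. The weighting is applied only in
the multi-pass path (`wbf(n_passes =)`); a plain `wbf()` call keeps the
literal arithmetic-mean score. Whether the original method fuses across
resolutions at inference or only within one image is ambiguous in the
text; both paths are exposed.

A related consequence of mean scoring on single-pass trained-detector
outputs (one strong box plus many weak duplicates per object): the merged
cluster is down-scored relative to NMS's kept maximum. The head-count
ablation below therefore uses the same NMS readout for both arms, keeping
that comparison about the heads, not the fusion rule.

## The detector

`build_detector()` constructs a compact fully-convolutional graph: a
backbone with feature maps at strides 4/8/16/32, a top-down neck
(1×1 lateral reductions, nearest ×2 upsampling, channel concatenation +
3×3 fusion convolution — elementwise addition is a config toggle since the
source sentence is ambiguous), and 1×1 heads with `3·(5+n_classes)` output
channels. With stride 4 requested, the micro-scale path upsamples the
stride-8 neck map to the stride-4 grid, merges it with the stride-4
backbone map, attaches a head there, and downsamples the result back into
the stride-8 path. Per-layer seeded initialization makes shared layers
bit-identical between the 3-head and 4-head variants, so removing the
micro head provably leaves the stride-16/32 computation untouched.

The backbone is *not* a line-by-line CSP replica; fidelity is at the
head/neck topology level, at desk scale (width multiplier 0.125 ≈ 10⁵
parameters). Convolutions are im2col + GEMM in C++ (RcppArmadillo); the
optimizer is Adam (β₁ = the published momentum 0.99 by default; the
desk-scale experiments use 0.9) with decoupled weight decay and
plateau-triggered learning-rate decay by the published factor 0.5. The
published per-resolution hyperparameter table ships verbatim as
`train_preset(100|160|320|640)`; its "Iterations" column is exposed as a
config key (`iterations`, a cap on optimizer steps per epoch) rather than
interpreted, since the table does not say whether it means steps per epoch
or in total.

### Target assignment and the training recipe

The module-level rule (`assign_targets()`) is deliberately simple and
deterministic: each ground truth goes to the (level, anchor) pair with the
highest position-free IoU, at the cell containing its center; occupied
slots fall through to the next-best anchor; best IoU < 0.05 means
unassigned. Decoding follows the standard convention — center
`(cell + σ(t))·stride`, size `anchor·exp(t)` clamped to [1/16, 4]× the
anchor, score `σ(obj)·σ(class)` — so zero logits decode to an anchor-sized
box at the cell center, and encode∘decode round-trips to sub-pixel
accuracy.

The training loss needs more care than the assignment contract suggests,
because with one positive cell per object every *neighboring* cell that
also sees the object becomes a high-scoring stray with an unsupervised
(garbage) box. The recipe that proved necessary and sufficient at this
scale, all of it standard practice:

* **dense per-level positives** — at every level whose best anchor reaches
  IoU ≥ 0.05, each cell whose center falls inside the ground-truth box
  regresses that box (duplicates are later merged by fusion);
* **quality-aware objectness targets** — a positive's objectness target is
  the IoU of its currently decoded box with its target, treated as a
  constant, so cells that cannot localize well learn proportionally lower
  scores and rank below the canonical cell;
* **prediction-aware ignore** — slots whose decoded box already overlaps
  some ground truth at IoU > 0.5 receive no negative pressure;
* **hard-negative mining** — the top-k highest-scoring negatives (k = 3×
  positives) carry half the suppression budget, the rest is uniform;
* **box gradients by central finite differences** of the scalar loss with
  respect to the four raw activations (h = 1e-4). Positives are few, so
  this costs nine cheap closed-form evaluations per target and avoids
  hand-deriving the piecewise EIoU gradient.

Objectness and class use binary cross-entropy (the source discusses only
the box loss; this is an out-of-source but conventional choice).

## Synthetic scenes

`generate_scene()` renders a soil-toned background (low-frequency mottling
plus fine grain) and N multi-lobed green blobs — 2–4 overlapping ellipses
re-sampled until the bounding-box fill ratio reaches 0.6, so labels are
tight by construction. Defaults emulate the stated regime: 640 px tiles,
20–60 objects, 50–450 px² footprints ("footprint" is read as blob *area*;
a `size_mode = "side"` flag switches to box side length for sensitivity
work), overlap probability 0.3 for the partial-occlusion regime. What the
generator does **not** emulate: real leaf morphology, shadows, perspective,
neighboring non-target vegetation, and motion blur beyond what the blur
filter tests inject. Passing tests therefore demonstrate algorithmic
correctness and relative behavior (e.g. the micro-head direction), not
field performance.

The preprocessing mirrors the published pipeline: `tile_image()` (640 px
tiles, boxes keeping < 20 % of their area are dropped and counted),
`laplacian_sharpness()` / `filter_blurred()` (variance of the 3×3 Laplacian;
the threshold is unspecified in the source, so the default is the batch's
25th percentile with an absolute override), the augmentation suite
(rot90/rot180/hflip with exact label maps; brightness gains ×1.3/×0.7 —
magnitudes unstated in the source; salt-and-pepper at density 0.02 — the
source's "pretzel noise" read as the standard term; Gaussian noise σ 0.02),
`resample_multires()` to 100/160/320/640, and `build_dataset()` with the
7:2:1 split. Augmentation proportions are uniform by default and exposed as
configuration, since per-op proportions are not stated.

## The desk-scale studies

Problem sizes were chosen once, as the largest a single CPU handles
comfortably, and are part of the package's study conditions:

* **Overfit capacity** — one 160² scene, 300 iterations, width 0.125;
  AP@0.5 on the training scene should reach 0.9 (2 of 3 seeds).
* **Head-count ablation** (`run_head_ablation()`) — 64 scenes of 320² with
  6–16 px objects; 16 train / 48 held out; 20 epochs of single-image
  batches; 3 seeds per arm; both arms use the default anchor preset
  restricted to their strides and an identical NMS readout. The comparison
  is directional: the 4-head mean AP should not fall below the 3-head
  mean.
* **Fusion comparison** (`run_fusion_comparison()`) — jittered,
  occasionally missing detections of the same ground truths at 160/320/640,
  fused by WBF vs pooled-and-NMS'd; directional again (WBF ≥ NMS).

Absolute AP values at this scale are far below what GPU-scale training on
real imagery reaches and are not comparable to published field numbers;
only the *directions* carry over, which is exactly what the studies assert.

## Known limitations

* The detector is a topology-faithful miniature, not a performance replica;
  no pretrained weights, mosaic augmentation, EMA or mixed precision.
* Focal-EIoU is literal: γ > 0 with a disjoint prediction contributes
  nothing — mitigated, not removed, by the EIoU warmup.
* `assign_targets()` resolves slot collisions greedily in input order;
  pathological inputs (many identical boxes in one cell) spill to
  next-best anchors or go unassigned.
* Fusion is per class but the generator and studies are single-class, so
  multi-class behavior is exercised only by unit tests.
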