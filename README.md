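# microdet

Small-object detection toolkit for dense plant targets in UAV imagery.

Aerial tiles of invasive weeds (the motivating case is giant ragweed,
*Ambrosia trifida*) contain many small, densely packed, partially
overlapping green targets — typically 50–450 px² in a 640×640 tile. A
stock single-shot detector struggles here for three reasons: its finest
grid is coarser than the targets, anchors fitted to the whole dataset
over-serve the most common size, and greedy non-maximum suppression (NMS)
mangles clusters of near-duplicate candidates. `microdet` implements the
corresponding remedies as a tested R package:

* **Geometry** — corner/normalized box types, IoU and the IoU distance
  `d(a,b) = 1 − IoU(a,b)`, YOLO-dialect label IO (`box_iou`,
  `yolo_to_corner`, `read_yolo_labels`, …).
* **Size-stratified anchors** — ground-truth sizes split at the quantiles
  of √(w·h) into 4 groups, k-means under the position-free IoU distance
  inside each group, smallest group → stride 4 (`stratify_by_size`,
  `kmeans_iou`, `build_anchor_preset`, `default_anchor_preset`).
* **Losses** — CIoU `1 − IoU + ρ²/c² + αν`, EIoU
  `(1−IoU) + ρ²/(w_c²+h_c²) + (w−w_gt)²/w_c² + (h−h_gt)²/h_c²`, and the
  focal variant `IoU^γ · L_EIoU` (`ciou_loss`, `eiou_loss`,
  `focal_eiou_loss`).
* **Fusion** — greedy NMS and weighted box fusion, where each overlap
  cluster is replaced by the score-weighted mean box
  `C = Σ sᵢxᵢ / Σ sᵢ` with the arithmetic-mean score, plus fusion across
  multi-resolution inference passes (`nms`, `wbf`,
  `fuse_multiresolution`).
* **Detector** — a compact trainable conv net with a micro-scale
  (stride-4, 160×160 grid at 640 input) detection head that upsamples the
  stride-8 neck map, merges it with the stride-4 backbone map, and feeds
  it back down (`network_spec`, `build_detector`, `train_detector`,
  `detect_image`).
* **Evaluation** — greedy IoU-0.5 matching, `P = TP/(TP+FP)`,
  `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and AP as the area under the
  all-point interpolated precision–recall curve (`match_detections`,
  `precision_recall_f1`, `pr_curve_and_ap`).
* **Synthetic scenes** — a generator for dense multi-lobed green blobs on
  textured soil with tight box labels, plus the preprocessing pipeline:
  640-px tiling, variance-of-Laplacian blur filtering, augmentation
  (rotations, flip, brightness, salt-and-pepper, Gaussian noise) and
  multi-resolution resampling to 100/160/320/640 (`generate_scene`,
  `tile_image`, `laplacian_sharpness`, `augment`, `resample_multires`,
  `build_dataset`).

## Worked example

```r
library(microdet)

# a dense 160-px scene with 6-10 small plants
sc <- generate_scene(scene_spec(image_size = 160, n_objects = c(6L, 10L),
                                object_size = c(8, 20), size_mode = "side",
                                seed = 11))
nrow(sc$labels)
#> [1] 8

# anchors estimated from the scene's own box sizes
wh <- cbind(w = sc$labels$w * 160, h = sc$labels$h * 160)
kmeans_iou(wh, K = 3, seed = 1)$centers
#>       w  h
#> [1,]  9  7
#> [2,] 11 11
#> [3,] 14 13

# train the 4-head detector on that scene and evaluate on it
det <- build_detector(network_spec(input_size = 160, seed = 1))
train_detector(det, list(list(image = sc$image, labels = sc$labels)),
               list(epochs = 300, batch = 1, lr = 0.005, momentum = 0.9,
                    seed = 1, warmup_iters = 200, patience = 10))
raw <- detect_image(det, sc$image, conf_thr = 0.05, fusion = NULL)
kept <- nms(raw, fusion_config(cluster_iou_thr = 0.45, mode = "nms"))
gt <- yolo_to_corner(sc$labels, 160, 160)
pr_curve_and_ap(match_detections(kept, gt))$ap
#> [1] 1
```

An AP of 1 here means the over-fitted detector ranks a correctly
localized box (IoU > 0.5) for every one of the eight plants above every
false alarm — the capacity sanity check for the miniature network. The
k-means centers are the per-cluster mean widths/heights of the scene's
boxes under the IoU distance.

A shell entry point wrapping the same functions ships in
`inst/cli/microdet.R`:

```sh
Rscript inst/cli/microdet.R generate --out scenes --n 20 --size 320 --seed 1
Rscript inst/cli/microdet.R anchors --labels scenes/labels --out anchors.txt
Rscript inst/cli/microdet.R pipeline --out run1 --preset smoke --seed 1
```

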