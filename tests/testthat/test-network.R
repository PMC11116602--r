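fwd <- function(det, x, ...) getFromNamespace("detector_forward", "microdet")(det, x, ...)

test_that("head grid sizes follow the stride arithmetic", {
  s4 <- network_spec(input_size = 640, head_strides = c(4, 8, 16, 32))
  expect_equal(head_grid_sizes(s4), c(160L, 80L, 40L, 20L))
  s3 <- network_spec(input_size = 640, head_strides = c(8, 16, 32))
  expect_equal(head_grid_sizes(s3), c(80L, 40L, 20L))
  s320 <- network_spec(input_size = 320, head_strides = c(4, 8, 16, 32))
  expect_equal(head_grid_sizes(s320), c(80L, 40L, 20L, 10L))
  # grid-size law
  for (sp in list(s4, s3, s320))
    expect_true(all(head_grid_sizes(sp) * sp$head_strides == sp$input_size))
})

test_that("spec validation catches inconsistent configurations", {
  expect_error(network_spec(input_size = 100), "multiple of 32")
  expect_error(network_spec(head_strides = c(3, 8)), "subset")
  expect_error(network_spec(width_mult = 0), "width_mult")
  p8 <- subset_preset(default_anchor_preset(), c(8, 16, 32))
  expect_error(network_spec(head_strides = c(4, 8, 16, 32), anchors = p8),
               "does not cover")
})

test_that("the detector emits one correctly shaped output per head", {
  spec <- network_spec(input_size = 96, head_strides = c(4, 8, 16, 32), seed = 1)
  det <- build_detector(spec)
  x <- array(0, c(96, 96, 3))
  heads <- fwd(det, x)
  expect_named(heads, c("4", "8", "16", "32"))
  for (st in c(4, 8, 16, 32)) {
    d <- dim(heads[[as.character(st)]])
    expect_equal(d[1:2], rep(96 / st, 2))
    expect_equal(d[3], 3 * (5 + 1))  # 3 anchors x (5 + 1 class) = 18
  }
})

test_that("parameter count is independent of input size", {
  d1 <- build_detector(network_spec(input_size = 96, seed = 3))
  d2 <- build_detector(network_spec(input_size = 320, seed = 3))
  expect_equal(n_parameters(d1), n_parameters(d2))
})

test_that("dropping the micro-scale head leaves the coarser graph intact", {
  s4 <- network_spec(input_size = 96, head_strides = c(4, 8, 16, 32), seed = 5)
  s3 <- network_spec(input_size = 96, head_strides = c(8, 16, 32), seed = 5)
  d4 <- build_detector(s4)
  d3 <- build_detector(s3)
  shared <- intersect(names(d3$layers), names(d4$layers))
  for (nm in shared) {
    expect_identical(d4$layers[[nm]]$w, d3$layers[[nm]]$w)
    expect_identical(d4$layers[[nm]]$b, d3$layers[[nm]]$b)
  }
  set.seed(9)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  h4 <- fwd(d4, x)
  h3 <- fwd(d3, x)
  # the micro path feeds back into stride 8, but strides 16/32 are bit-equal
  expect_identical(h4[["16"]], h3[["16"]])
  expect_identical(h4[["32"]], h3[["32"]])
  expect_false(identical(h4[["8"]], h3[["8"]]))
})

test_that("target assignment picks the level whose anchor best fits", {
  spec <- network_spec(input_size = 640, seed = 1)
  # a GT exactly equal to the stride-8 anchor (16, 30), centered in a cell
  gt <- data.frame(x1 = 100 - 8, y1 = 100 - 15, x2 = 100 + 8, y2 = 100 + 15)
  asg <- assign_targets(gt, spec)
  expect_equal(nrow(asg$assigned), 1)
  expect_equal(asg$assigned$stride, 8)
  expect_equal(asg$assigned$iou, 1)
  expect_equal(asg$assigned$col, floor(100 / 8) + 1)

  # 20x20: brute-force over all 12 anchors says stride 8 anchor (16, 30)
  # or (10, 13)? compute it independently
  all_anchors <- do.call(rbind, lapply(spec$anchors$levels, function(l)
    cbind(stride = l$stride, l$anchors)))
  ious <- apply(all_anchors, 1, function(a)
    (min(20, a["w"]) * min(20, a["h"])) /
      (400 + a["w"] * a["h"] - min(20, a["w"]) * min(20, a["h"])))
  best_stride <- all_anchors[which.max(ious), "stride"]
  gt20 <- data.frame(x1 = 300, y1 = 300, x2 = 320, y2 = 320)
  asg20 <- assign_targets(gt20, spec)
  expect_equal(asg20$assigned$stride, unname(best_stride))
  expect_equal(best_stride, c(stride = 8))

  # two GTs in different cells get distinct assignments
  gts <- data.frame(x1 = c(100, 400), y1 = c(100, 400),
                    x2 = c(120, 420), y2 = c(120, 420))
  asg2 <- assign_targets(gts, spec)
  expect_equal(nrow(asg2$assigned), 2)
  expect_equal(anyDuplicated(asg2$assigned[, c("stride", "row", "col", "anchor")]), 0L)
})

test_that("degenerately tiny ground truths are left unassigned", {
  spec <- network_spec(input_size = 640, seed = 1)
  tiny <- data.frame(x1 = 10, y1 = 10, x2 = 10.5, y2 = 10.5)
  asg <- assign_targets(tiny, spec)
  expect_equal(length(asg$unassigned), 1)
})

test_that("decode at zero logits yields anchor-sized boxes at cell centers", {
  spec <- network_spec(input_size = 96, seed = 2)
  det <- build_detector(spec)
  heads <- lapply(fwd(det, array(0, c(96, 96, 3))), function(Y) array(0, dim(Y)))
  dets <- decode_predictions(heads, spec, conf_thr = 0.2)
  # sigmoid(0) = 0.5 everywhere: score 0.25, centers at cell centers
  expect_true(all(abs(dets$score - 0.25) < 1e-12))
  d4 <- dets[abs((dets$x2 - dets$x1) - 5) < 1e-9, ]  # stride-4 anchor (5, 7)
  expect_true(nrow(d4) > 0)
  cx <- (d4$x1 + d4$x2) / 2
  expect_true(all(abs((cx / 4) %% 1 - 0.5) < 1e-9))
  # all -Inf logits produce an empty list at any positive threshold
  neg <- lapply(heads, function(Y) array(-1e9, dim(Y)))
  expect_equal(nrow(decode_predictions(neg, spec, conf_thr = 1e-6)), 0)
  expect_error(decode_predictions(list(`4` = heads[["4"]]), spec, 0.1), "missing head")
})

test_that("decode inverts encode to sub-pixel accuracy", {
  spec <- network_spec(input_size = 320, seed = 3)
  encode_slot <- getFromNamespace("encode_slot", "microdet")
  decode_slot <- getFromNamespace("decode_slot", "microdet")
  set.seed(12)
  for (i in 1:100) {
    gt <- data.frame(x1 = runif(1, 10, 280), y1 = runif(1, 10, 280))
    gt$x2 <- gt$x1 + runif(1, 5, 35); gt$y2 <- gt$y1 + runif(1, 5, 35)
    asg <- assign_targets(gt, spec)
    if (nrow(asg$assigned) == 0) next
    a <- asg$assigned[1, ]
    li <- match(a$stride, spec$head_strides)
    anc <- spec$anchors$levels[[li]]$anchors[a$anchor, ]
    t4 <- encode_slot(as.numeric(gt[1, 1:4]), a$stride, a$row, a$col, anc)
    back <- decode_slot(t4, a$stride, a$row, a$col, anc)
    expect_lt(max(abs(back - as.numeric(gt[1, 1:4]))), 0.5)
  }
})

test_that("training presets carry the published per-resolution settings", {
  p640 <- train_preset(640)
  expect_equal(p640$batch, 8L)
  expect_equal(p640$lr, 0.0025)
  expect_equal(p640$epochs, 300L)
  expect_equal(p640$iterations, 400L)
  expect_equal(p640$momentum, 0.99)
  expect_equal(p640$decay_factor, 0.5)
  expect_equal(p640$decay_weight, 1e-4)
  expect_equal(train_preset(100)[c("batch", "iterations", "lr")],
               list(batch = 64L, iterations = 50L, lr = 0.02))
  expect_equal(train_preset(160)[c("batch", "lr")], list(batch = 32L, lr = 0.01))
  expect_equal(train_preset(320)[c("batch", "lr")], list(batch = 16L, lr = 0.005))
  expect_error(train_preset(500), "no preset")
})

test_that("training reduces the loss and is seed-deterministic", {
  sc <- tiny_scene(21, size = 96, n = c(4L, 6L), obj = c(8, 16))
  spec <- network_spec(input_size = 96, seed = 7)
  det <- build_detector(spec)
  dataset <- list(list(image = sc$image, labels = sc$labels))
  expect_error(train_detector(det, list()), "empty dataset")
  log <- train_detector(det, dataset,
                        list(epochs = 50, batch = 1, lr = 0.005, momentum = 0.9,
                             seed = 1, warmup_iters = 40))
  expect_equal(nrow(log), 50)
  expect_lt(log$loss[50], log$loss[1])
  det_a <- build_detector(network_spec(input_size = 96, seed = 7))
  log_a <- train_detector(det_a, dataset,
                          list(epochs = 3, batch = 1, lr = 0.005, seed = 2))
  det_b <- build_detector(network_spec(input_size = 96, seed = 7))
  log_b <- train_detector(det_b, dataset,
                          list(epochs = 3, batch = 1, lr = 0.005, seed = 2))
  expect_equal(log_a$loss, log_b$loss, tolerance = 1e-6)
})

test_that("checkpoints round-trip through save/load", {
  sc <- tiny_scene(22, size = 96, n = c(3L, 4L), obj = c(8, 14))
  det <- build_detector(network_spec(input_size = 96, seed = 4))
  train_detector(det, list(list(image = sc$image, labels = sc$labels)),
                 list(epochs = 2, batch = 1, lr = 0.005, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_detector(det, f)
  det2 <- load_detector(f)
  h1 <- fwd(det, sc$image)
  h2 <- fwd(det2, sc$image)
  expect_identical(h1, h2)
})

test_that("a tiny detector overfits one scene to high AP", {
  # desk-scale capacity check: train on one scene, evaluate on that scene;
  # expect AP@0.5 >= 0.9 for at least 2 of 3 seeds
  passes <- 0L
  for (seed in 1:3) {
    sc <- tiny_scene(11, size = 160)
    det <- build_detector(network_spec(input_size = 160, seed = seed))
    train_detector(det, list(list(image = sc$image, labels = sc$labels)),
                   list(epochs = 300, batch = 1, lr = 0.005, momentum = 0.9,
                        seed = seed, warmup_iters = 200, patience = 10))
    raw <- detect_image(det, sc$image, conf_thr = 0.05, fusion = NULL)
    d <- nms(raw, fusion_config(cluster_iou_thr = 0.45, mode = "nms"))
    gt <- yolo_to_corner(sc$labels, 160, 160)
    ap <- pr_curve_and_ap(match_detections(d, gt))$ap
    if (ap >= 0.9) passes <- passes + 1L
  }
  expect_gte(passes, 2L)
})
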