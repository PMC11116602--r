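# ---------------------------------------------------------------------------
# The compact detector: a declarative NetworkSpec, a hand-wired
# backbone/neck/head graph with an optional micro-scale (stride-4) head,
# target assignment, prediction decoding, and a desk-scale training loop.
#
# The micro-scale path follows the published topology: the stride-8 neck
# map is upsampled 2x, merged with the stride-4 backbone map (a head
# attaches there), and then downsampled back into the stride-8 path so the
# finer spatial evidence also reaches the coarser heads.
# ---------------------------------------------------------------------------

#' Detector network specification
#'
#' @param input_size Square input edge in pixels; must be a multiple of 32.
#' @param width_mult Channel multiplier in (0, 1]; 0.125 gives a desk-scale
#'   network.
#' @param n_classes Number of object classes (>= 1).
#' @param head_strides Ordered subset of `c(4, 8, 16, 32)`; including 4
#'   adds the micro-scale detection layer (a 160x160 grid at 640 input).
#' @param anchors An `anchor_preset`; must cover exactly `head_strides`
#'   (a superset preset is subset automatically).
#' @param merge `"concat"` (default: channel concatenation + fusion
#'   convolution) or `"add"` (elementwise addition) for neck merges.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(input_size = 640L, width_mult = 0.125, n_classes = 1L,
                         head_strides = c(4L, 8L, 16L, 32L),
                         anchors = default_anchor_preset(),
                         merge = c("concat", "add"), seed = 0L) {
  merge <- match.arg(merge)
  if (input_size %% 32 != 0) stop("input_size must be a multiple of 32")
  if (width_mult <= 0 || width_mult > 1) stop("width_mult must be in (0, 1]")
  if (n_classes < 1) stop("n_classes must be >= 1")
  head_strides <- as.integer(sort(head_strides))
  if (length(head_strides) == 0L || !all(head_strides %in% c(4L, 8L, 16L, 32L)))
    stop("head_strides must be a non-empty subset of {4, 8, 16, 32}")
  preset_strides <- vapply(anchors$levels, `[[`, integer(1), "stride")
  if (!all(head_strides %in% preset_strides))
    stop("anchor preset does not cover head strides ",
         paste(setdiff(head_strides, preset_strides), collapse = ", "))
  anchors <- subset_preset(anchors, head_strides)
  structure(list(input_size = as.integer(input_size), width_mult = width_mult,
                 n_classes = as.integer(n_classes), head_strides = head_strides,
                 anchors = anchors, merge = merge, seed = as.integer(seed)),
            class = "network_spec")
}

#' Spatial grid size of each detection head
#'
#' Each head predicts on a grid of `input_size / stride` cells per side:
#' at 640 input the stride-8/16/32 heads give 80x80, 40x40 and 20x20 grids,
#' and the micro-scale stride-4 head gives 160x160.
#'
#' @param spec A [network_spec()].
#' @return Integer vector of grid sizes, in `head_strides` order.
#' @export
head_grid_sizes <- function(spec) {
  as.integer(spec$input_size / spec$head_strides)
}

spec_channels <- function(spec) {
  base <- c(stem = 32, c2 = 64, c3 = 128, c4 = 256, c5 = 512)
  ch <- pmax(round(base * spec$width_mult), 4L)
  c(ch, nc = unname(ch["c3"]))
}

#' Build a trainable detector from a specification
#'
#' Constructs the backbone (feature maps at strides 4/8/16/32), a top-down
#' neck with upsampling merges, the optional micro-scale path (when stride
#' 4 is requested), and one 1x1 prediction head per stride with
#' `anchors_per_level * (5 + n_classes)` output channels. Weights are
#' He-normal, seeded per layer so that graphs sharing layers initialize
#' them identically regardless of which heads are present.
#'
#' @param spec A [network_spec()].
#' @return A detector handle (an environment of class `detector`).
#' @export
build_detector <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- spec_channels(spec)
  nc <- ch[["nc"]]
  two <- if (spec$merge == "concat") 2L else 1L
  det <- new.env(parent = emptyenv())
  det$spec <- spec
  det$t <- 0L
  s <- spec$seed
  L <- list()
  add <- function(name, cin, cout, k, stride, act = "leaky")
    L[[name]] <<- new_conv(name, cin, cout, k, stride, act, s)
  add("stem", 3L, ch[["stem"]], 3L, 2L)
  add("b2a", ch[["stem"]], ch[["c2"]], 3L, 2L); add("b2b", ch[["c2"]], ch[["c2"]], 3L, 1L)
  add("b3a", ch[["c2"]], ch[["c3"]], 3L, 2L);  add("b3b", ch[["c3"]], ch[["c3"]], 3L, 1L)
  add("b4a", ch[["c3"]], ch[["c4"]], 3L, 2L);  add("b4b", ch[["c4"]], ch[["c4"]], 3L, 1L)
  add("b5a", ch[["c4"]], ch[["c5"]], 3L, 2L);  add("b5b", ch[["c5"]], ch[["c5"]], 3L, 1L)
  add("r5", ch[["c5"]], nc, 1L, 1L); add("n5", nc, nc, 3L, 1L)
  add("r4", ch[["c4"]], nc, 1L, 1L); add("n4", two * nc, nc, 3L, 1L)
  add("r3", ch[["c3"]], nc, 1L, 1L); add("n3", two * nc, nc, 3L, 1L)
  if (4L %in% spec$head_strides) {
    add("r2", ch[["c2"]], nc, 1L, 1L); add("n2", two * nc, nc, 3L, 1L)
    add("down3", nc, nc, 3L, 2L); add("n3b", two * nc, nc, 3L, 1L)
  }
  n_out <- anchors_per_level(spec) * (5L + spec$n_classes)
  for (st in spec$head_strides)
    add(paste0("h", st), nc, n_out, 1L, 1L, act = "linear")
  det$layers <- L
  class(det) <- "detector"
  det
}

anchors_per_level <- function(spec) nrow(spec$anchors$levels[[1]]$anchors)

#' Number of trainable parameters of a detector
#' @param det A detector handle.
#' @return Integer parameter count.
#' @export
n_parameters <- function(det)
  sum(vapply(det$layers, function(l) length(l$w) + length(l$b), numeric(1)))

# forward pass; returns list(heads = named by stride, cache) when
# with_cache, else just heads
detector_forward <- function(det, x, with_cache = FALSE) {
  spec <- det$spec
  cache <- new.env(parent = emptyenv())
  cf <- function(name, input) conv_forward(det, name, input, cache)
  merge2 <- function(a, b) if (spec$merge == "concat") concat_c(a, b) else a + b
  c1 <- cf("stem", x)
  c2 <- cf("b2b", cf("b2a", c1))
  c3 <- cf("b3b", cf("b3a", c2))
  c4 <- cf("b4b", cf("b4a", c3))
  c5 <- cf("b5b", cf("b5a", c4))
  m5 <- cf("n5", cf("r5", c5))
  m4 <- cf("n4", merge2(upsample2_fwd(m5), cf("r4", c4)))
  m3 <- cf("n3", merge2(upsample2_fwd(m4), cf("r3", c3)))
  micro <- 4L %in% spec$head_strides
  if (micro) {
    m2 <- cf("n2", merge2(upsample2_fwd(m3), cf("r2", c2)))
    m3h <- cf("n3b", merge2(cf("down3", m2), m3))
  } else m3h <- m3
  feats <- list(`4` = if (micro) m2 else NULL, `8` = m3h, `16` = m4, `32` = m5)
  heads <- list()
  for (st in spec$head_strides)
    heads[[as.character(st)]] <- cf(paste0("h", st), feats[[as.character(st)]])
  if (!with_cache) return(heads)
  list(heads = heads, cache = cache)
}

# backward pass from per-head gradients; accumulates parameter grads
detector_backward <- function(det, dheads, cache, grads) {
  spec <- det$spec
  nc <- spec_channels(spec)[["nc"]]
  cb <- function(name, d) conv_backward(det, name, d, cache, grads)
  zero_like <- function(name) array(0, dim(cache[[name]]$y))
  dmerge <- function(d) {
    if (spec$merge == "concat") split_c(d, dim(d)[3] %/% 2L) else list(d, d)
  }
  micro <- 4L %in% spec$head_strides
  dfeat <- list(`4` = NULL, `8` = NULL, `16` = NULL, `32` = NULL)
  for (st in spec$head_strides) {
    key <- as.character(st)
    d <- cb(paste0("h", st), dheads[[key]])
    dfeat[[key]] <- d
  }
  or_zero <- function(d, name) if (is.null(d)) zero_like(name) else d
  if (micro) {
    parts <- dmerge(cb("n3b", or_zero(dfeat[["8"]], "n3b")))
    dm2 <- cb("down3", parts[[1]])
    dm3_extra <- parts[[2]]
    if (!is.null(dfeat[["4"]])) dm2 <- dm2 + dfeat[["4"]]
    parts2 <- dmerge(cb("n2", dm2))
    dm3 <- upsample2_bwd(parts2[[1]]) + dm3_extra
    dr2 <- parts2[[2]]
    dc2_extra <- cb("r2", dr2)
  } else {
    dm3 <- or_zero(dfeat[["8"]], "n3")
    dc2_extra <- 0
  }
  parts3 <- dmerge(cb("n3", dm3))
  dm4 <- upsample2_bwd(parts3[[1]]) + or_zero(dfeat[["16"]], "n4")
  dc3_extra <- cb("r3", parts3[[2]])
  parts4 <- dmerge(cb("n4", dm4))
  dm5 <- upsample2_bwd(parts4[[1]]) + or_zero(dfeat[["32"]], "n5")
  dc4_extra <- cb("r4", parts4[[2]])
  dc5 <- cb("r5", cb("n5", dm5))
  dc4 <- cb("b5a", cb("b5b", dc5)) + dc4_extra
  dc3 <- cb("b4a", cb("b4b", dc4)) + dc3_extra
  dc2 <- cb("b3a", cb("b3b", dc3)) + dc2_extra
  dc1 <- cb("b2a", cb("b2b", dc2))
  cb("stem", dc1)
  invisible(grads)
}

# ---------------------------------------------------------------------------
# Target assignment, encoding and decoding
# ---------------------------------------------------------------------------

#' Assign ground-truth boxes to (level, cell, anchor) slots
#'
#' Each ground truth is assigned to the (level, anchor) pair whose anchor
#' has the smallest position-free IoU distance to the box's (w, h), at the
#' grid cell containing the box center. Slots already taken fall through to
#' the next-best anchor; boxes whose best anchor IoU is below 0.05 are left
#' unassigned.
#'
#' @param gts Data frame of ground-truth corner boxes (pixels, within image
#'   bounds).
#' @param spec A [network_spec()].
#' @return An object of class `target_assignment`: data frame
#'   `assigned` (columns `gt, stride, row, col, anchor, iou`) and integer
#'   vector `unassigned` (indices into `gts`).
#' @export
assign_targets <- function(gts, spec) {
  gts <- as_box_matrix(gts)
  n <- nrow(gts)
  cand <- list()
  for (li in seq_along(spec$anchors$levels)) {
    lvl <- spec$anchors$levels[[li]]
    cand[[li]] <- cbind(stride = lvl$stride,
                        anchor = seq_len(nrow(lvl$anchors)),
                        lvl$anchors)
  }
  cand <- do.call(rbind, cand)  # stride, anchor, w, h
  taken <- character(0)
  assigned <- NULL
  unassigned <- integer(0)
  for (i in seq_len(n)) {
    wh <- c(gts[i, 3] - gts[i, 1], gts[i, 4] - gts[i, 2])
    ious <- as.vector(wh_iou(matrix(wh, 1), cand[, c("w", "h")]))
    ord <- order(-ious)
    placed <- FALSE
    for (j in ord) {
      if (ious[j] < 0.05) break
      stride <- cand[j, "stride"]
      grid <- spec$input_size / stride
      col <- min(max(floor((gts[i, 1] + gts[i, 3]) / 2 / stride) + 1, 1), grid)
      row <- min(max(floor((gts[i, 2] + gts[i, 4]) / 2 / stride) + 1, 1), grid)
      key <- paste(stride, row, col, cand[j, "anchor"])
      if (key %in% taken) next
      taken <- c(taken, key)
      assigned <- rbind(assigned,
                        data.frame(gt = i, stride = stride, row = row, col = col,
                                   anchor = cand[j, "anchor"], iou = ious[j]))
      placed <- TRUE
      break
    }
    if (!placed) unassigned <- c(unassigned, i)
  }
  structure(list(assigned = assigned, unassigned = unassigned),
            class = "target_assignment")
}

# raw (tx, ty, tw, th) for a gt box at a given slot
encode_slot <- function(box, stride, row, col, anchor_wh) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  fx <- pmin(pmax(cx / stride - (col - 1), 1e-4), 1 - 1e-4)
  fy <- pmin(pmax(cy / stride - (row - 1), 1e-4), 1 - 1e-4)
  rw <- pmin(pmax((box[3] - box[1]) / anchor_wh[1], 1e-3), 4 - 1e-6)
  rh <- pmin(pmax((box[4] - box[2]) / anchor_wh[2], 1e-3), 4 - 1e-6)
  c(log(fx / (1 - fx)), log(fy / (1 - fy)), log(rw), log(rh))
}

decode_slot <- function(t4, stride, row, col, anchor_wh) {
  cx <- (col - 1 + sigmoid(t4[1])) * stride
  cy <- (row - 1 + sigmoid(t4[2])) * stride
  w <- anchor_wh[1] * min(max(exp(t4[3]), 1 / 16), 4)
  h <- anchor_wh[2] * min(max(exp(t4[4]), 1 / 16), 4)
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Decode raw head outputs into scored detections
#'
#' Standard YOLO decode: per anchor and cell the center is
#' `(cell + sigmoid(offset)) * stride`, the size is
#' `anchor * exp(size logit)` clamped at 4x the anchor, and the score is
#' `sigmoid(objectness) * sigmoid(class logit)` (max over classes).
#'
#' @param heads Named list (by stride) of `[H, W, A*(5+n_classes)]` arrays
#'   as produced by the detector forward pass.
#' @param spec The [network_spec()].
#' @param conf_thr Minimum score for a detection to be returned.
#' @return Data frame of detections (`x1, y1, x2, y2, score, class_id`).
#' @export
decode_predictions <- function(heads, spec, conf_thr = 0.1) {
  A <- anchors_per_level(spec)
  C <- 5L + spec$n_classes
  out <- list()
  for (li in seq_along(spec$head_strides)) {
    st <- spec$head_strides[li]
    Y <- heads[[as.character(st)]]
    if (is.null(Y)) stop("missing head output for stride ", st)
    G <- spec$input_size / st
    if (dim(Y)[1] != G || dim(Y)[2] != G || dim(Y)[3] != A * C)
      stop("head output shape mismatch at stride ", st)
    anc <- spec$anchors$levels[[li]]$anchors
    rows <- matrix(rep(seq_len(G), G), G, G)       # row index = y cell
    cols <- matrix(rep(seq_len(G), each = G), G, G)
    for (a in seq_len(A)) {
      off <- (a - 1L) * C
      obj <- sigmoid(Y[, , off + 5L])
      cls <- array(sigmoid(Y[, , off + 5L + seq_len(spec$n_classes)]),
                   c(G, G, spec$n_classes))
      best <- apply(cls, c(1, 2), which.max)
      bestp <- apply(cls, c(1, 2), max)
      score <- obj * bestp
      keep <- which(score >= conf_thr)
      if (length(keep) == 0L) next
      cx <- (cols[keep] - 1 + sigmoid(Y[, , off + 1L][keep])) * st
      cy <- (rows[keep] - 1 + sigmoid(Y[, , off + 2L][keep])) * st
      w <- anc[a, 1] * pmin(pmax(exp(Y[, , off + 3L][keep]), 1 / 16), 4)
      h <- anc[a, 2] * pmin(pmax(exp(Y[, , off + 4L][keep]), 1 / 16), 4)
      out[[length(out) + 1L]] <- data.frame(
        x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
        score = score[keep], class_id = best[keep] - 1L)
    }
  }
  if (length(out) == 0L) return(empty_detections())
  d <- do.call(rbind, out)
  d[det_order(d), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Loss and training
# ---------------------------------------------------------------------------

# loss + head gradients for one image; box-loss gradients use central
# finite differences of the (few) per-target scalar losses
image_loss_grads <- function(det, heads, gt_boxes, loss_cfg, use_focal,
                             lambda = c(box = 2, obj = 1, cls = 0.5),
                             hard_frac = 0.5) {
  spec <- det$spec
  A <- anchors_per_level(spec)
  C <- 5L + spec$n_classes
  dheads <- lapply(heads, function(Y) array(0, dim(Y)))
  gtm0 <- as_box_matrix(gt_boxes)
  # dense per-level positives: at every level whose best anchor plausibly
  # matches the ground truth (position-free IoU >= 0.05), each cell whose
  # center falls inside the box regresses that box with that anchor. Cells
  # that "see" object pixels thus learn accurate boxes at every level (the
  # duplicates merge in NMS/WBF) and each anchor channel receives
  # consistent targets for objects of its size class.
  pos <- NULL
  if (nrow(gtm0) > 0L) {
    taken <- character(0)
    for (gi in seq_len(nrow(gtm0))) {
      b <- gtm0[gi, ]
      wh <- matrix(c(b[3] - b[1], b[4] - b[2]), 1)
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      for (li in seq_along(spec$head_strides)) {
        st <- spec$head_strides[li]
        G <- spec$input_size / st
        ious <- as.vector(wh_iou(wh, spec$anchors$levels[[li]]$anchors))
        best_a <- which.max(ious)
        if (ious[best_a] < 0.05) next
        ccol0 <- min(max(floor(cx / st) + 1, 1), G)
        crow0 <- min(max(floor(cy / st) + 1, 1), G)
        ccols <- max(1, floor(b[1] / st) + 1):min(G, ceiling(b[3] / st))
        crows <- max(1, floor(b[2] / st) + 1):min(G, ceiling(b[4] / st))
        for (cc in unique(c(ccol0, ccols))) for (rr in unique(c(crow0, crows))) {
          ctr <- (c(cc, rr) - 0.5) * st
          in_box <- ctr[1] >= b[1] && ctr[1] <= b[3] && ctr[2] >= b[2] && ctr[2] <= b[4]
          if (!in_box && !(cc == ccol0 && rr == crow0)) next
          key <- paste(st, rr, cc, best_a)
          if (key %in% taken) next
          taken <- c(taken, key)
          pos <- rbind(pos, data.frame(gt = gi, stride = st, row = rr,
                                       col = cc, anchor = best_a))
        }
      }
    }
  }
  n_pos <- if (is.null(pos)) 0L else nrow(pos)
  # objectness targets: soft (IoU) at positives, NA (= no gradient) at
  # slots whose decoded box already overlaps some ground truth with IoU >
  # 0.5 -- those predictions point at a real object and must not be forced
  # to 0; every other slot is a true negative and is suppressed
  tobj <- lapply(heads, function(Y) array(0, c(dim(Y)[1], dim(Y)[2], A)))
  if (nrow(gtm0) > 0L) {
    for (li in seq_along(spec$head_strides)) {
      st <- spec$head_strides[li]
      key <- as.character(st)
      G <- spec$input_size / st
      Y <- heads[[key]]
      anc <- spec$anchors$levels[[li]]$anchors
      rows <- matrix(rep(seq_len(G), G), G, G)
      cols <- matrix(rep(seq_len(G), each = G), G, G)
      for (a in seq_len(A)) {
        off <- (a - 1L) * C
        cx <- (cols - 1 + sigmoid(Y[, , off + 1L])) * st
        cy <- (rows - 1 + sigmoid(Y[, , off + 2L])) * st
        w <- anc[a, 1] * pmin(pmax(exp(Y[, , off + 3L]), 1 / 16), 4)
        h <- anc[a, 2] * pmin(pmax(exp(Y[, , off + 4L]), 1 / 16), 4)
        dec <- cbind(x1 = as.vector(cx - w / 2), y1 = as.vector(cy - h / 2),
                     x2 = as.vector(cx + w / 2), y2 = as.vector(cy + h / 2))
        best <- apply(iou_matrix(dec, gtm0), 1, max)
        slice <- tobj[[key]][, , a]
        slice[best > 0.5] <- NA
        tobj[[key]][, , a] <- slice
      }
    }
  }
  loss_obj <- 0; loss_cls <- 0; loss_box <- 0
  box_fn <- if (use_focal) function(p, g) focal_eiou_loss(p, g, loss_cfg)
            else function(p, g) eiou_loss(p, g, eps = loss_cfg$eps)
  if (n_pos > 0L) {
    for (r in seq_len(n_pos)) {
      a <- pos[r, ]
      key <- as.character(a$stride)
      li <- match(a$stride, spec$head_strides)
      anc <- spec$anchors$levels[[li]]$anchors[a$anchor, ]
      off <- (a$anchor - 1L) * C
      # class binary cross-entropy (target class = gts class, here single)
      ci <- off + 5L + 1L
      pc <- sigmoid(det_head_val(heads[[key]], a$row, a$col, ci))
      loss_cls <- loss_cls + (-log(pmax(pc, 1e-12))) / n_pos
      dheads[[key]][a$row, a$col, ci] <- dheads[[key]][a$row, a$col, ci] +
        lambda["cls"] * (pc - 1) / n_pos
      # box regression via finite differences on the 4 raw values
      t4 <- vapply(1:4, function(d) det_head_val(heads[[key]], a$row, a$col, off + d),
                   numeric(1))
      gt_box <- gtm0[a$gt, ]
      f <- function(tv) box_fn(decode_slot(tv, a$stride, a$row, a$col, anc), gt_box)
      loss_box <- loss_box + f(t4) / n_pos
      h <- 1e-4
      for (d in 1:4) {
        tp <- t4; tp[d] <- tp[d] + h
        tm <- t4; tm[d] <- tm[d] - h
        g <- (f(tp) - f(tm)) / (2 * h)
        dheads[[key]][a$row, a$col, off + d] <-
          dheads[[key]][a$row, a$col, off + d] + lambda["box"] * g / n_pos
      }
      # the objectness target at a positive is the quality of its current
      # decoded box (IoU with its ground truth, treated as a constant), so
      # cells that cannot localize well learn proportionally lower scores
      # and rank below the canonical cell at inference
      tobj[[key]][a$row, a$col, a$anchor] <-
        box_iou(decode_slot(t4, a$stride, a$row, a$col, anc), gt_box)
    }
  }
  n_neg <- sum(vapply(tobj, function(t) sum(!is.na(t) & t == 0), numeric(1)))
  # hard-negative mining: the top-k highest-scoring negatives carry most of
  # the suppression budget (k = 3 x positives), the rest share a small
  # uniform background pressure
  k_hard <- max(3L * n_pos, 32L)
  neg_p <- unlist(lapply(names(heads), function(key) {
    obj_idx <- (seq_len(A) - 1L) * C + 5L
    p <- sigmoid(heads[[key]][, , obj_idx, drop = FALSE])
    t3 <- array(tobj[[key]], dim(p))
    p[!is.na(t3) & t3 == 0]
  }))
  hard_thr <- if (length(neg_p) > k_hard)
    sort(neg_p, decreasing = TRUE)[k_hard] else -Inf
  k_eff <- max(1L, sum(neg_p >= hard_thr))
  for (key in names(heads)) {
    Y <- heads[[key]]
    t <- tobj[[key]]
    obj_idx <- (seq_len(A) - 1L) * C + 5L
    p <- sigmoid(Y[, , obj_idx, drop = FALSE])
    t3 <- array(t, dim(p))
    is_neg <- !is.na(t3) & t3 == 0
    wgt <- array(0, dim(p))
    wgt[!is.na(t3) & t3 > 0] <- 1 / max(1, n_pos)
    wgt[is_neg] <- (1 - hard_frac) / max(1, n_neg)
    wgt[is_neg & p >= hard_thr] <- wgt[is_neg & p >= hard_thr] + hard_frac / k_eff
    t3[is.na(t3)] <- 0
    loss_obj <- loss_obj +
      sum(-(t3 * log(pmax(p, 1e-12)) + (1 - t3) * log(pmax(1 - p, 1e-12))) * wgt)
    dheads[[key]][, , obj_idx] <- dheads[[key]][, , obj_idx, drop = FALSE] +
      lambda["obj"] * (p - t3) * wgt
  }
  list(loss = lambda["box"] * loss_box + lambda["obj"] * loss_obj +
         lambda["cls"] * loss_cls,
       box = loss_box, obj = loss_obj, cls = loss_cls, dheads = dheads,
       n_pos = n_pos)
}

det_head_val <- function(Y, row, col, ch) Y[row, col, ch]

#' Verbatim training presets per input resolution
#'
#' The published hyperparameter table: batch size, epochs, iterations,
#' momentum 0.99, per-resolution learning rate, decay factor 0.5, decay
#' weight 1e-4.
#'
#' @param resolution One of 100, 160, 320, 640.
#' @return Named list of training hyperparameters.
#' @export
train_preset <- function(resolution) {
  presets <- list(
    `100` = list(batch = 64L, epochs = 300L, iterations = 50L, lr = 0.02),
    `160` = list(batch = 32L, epochs = 300L, iterations = 100L, lr = 0.01),
    `320` = list(batch = 16L, epochs = 300L, iterations = 200L, lr = 0.005),
    `640` = list(batch = 8L, epochs = 300L, iterations = 400L, lr = 0.0025))
  p <- presets[[as.character(resolution)]]
  if (is.null(p)) stop("no preset for resolution ", resolution)
  c(p, list(momentum = 0.99, decay_factor = 0.5, decay_weight = 1e-4))
}

#' Train a detector on a dataset of (image, labels) pairs
#'
#' Optimizes the bounding-box regression loss (EIoU family) plus balanced
#' binary cross-entropy for objectness and class, with Adam (beta1 =
#' `momentum`), decoupled weight decay, and learning-rate decay by
#' `decay_factor` when the epoch loss plateaus. The focal reweighting is
#' disabled for the first `warmup_iters` optimizer steps (plain EIoU), since
#' the literal `IoU^gamma` weight has zero gradient for disjoint pairs.
#' Fully seeded: equal seeds give identical loss traces.
#'
#' @param det A detector handle from [build_detector()] (modified in
#'   place).
#' @param dataset List of `list(image =, labels =)` pairs; labels are
#'   YOLO-dialect data frames.
#' @param cfg List of training options: `epochs`, `batch`, `lr`, `momentum`,
#'   `decay_factor`, `decay_weight`, `patience`, `iterations` (optional cap
#'   on steps per epoch), `loss` (a [loss_config()]), `loss_kind`
#'   (`"focal_eiou"`, `"eiou"` or `"ciou"`), `warmup_iters`, `seed`.
#' @return A data frame training log (one row per epoch: losses and
#'   learning rate), invisibly; the detector is updated in place.
#' @export
train_detector <- function(det, dataset, cfg = list()) {
  if (length(dataset) == 0L) stop("empty dataset")
  defaults <- list(epochs = 10L, batch = 4L, lr = 0.005, momentum = 0.99,
                   decay_factor = 0.5, decay_weight = 1e-4, patience = 3L,
                   iterations = NULL, loss = loss_config(),
                   loss_kind = "focal_eiou", warmup_iters = 200L,
                   hard_frac = 0.5, seed = 0L)
  cfg <- utils::modifyList(defaults, cfg)
  spec <- det$spec
  N <- spec$input_size
  log_rows <- list()
  lr <- cfg$lr
  best <- Inf; stall <- 0L
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(dataset))
      if (!is.null(cfg$iterations))
        ord <- ord[seq_len(min(length(ord), cfg$iterations * cfg$batch))]
      ep_loss <- 0; ep_box <- 0; ep_obj <- 0; ep_cls <- 0; n_img <- 0L
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch))
      for (b in batches) {
        gcol <- new.env(parent = emptyenv())
        for (i in b) {
          item <- dataset[[i]]
          fw <- detector_forward(det, item$image, with_cache = TRUE)
          gt_boxes <- if (nrow(item$labels) > 0)
            yolo_to_corner(item$labels, N, N) else
            data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
          use_focal <- cfg$loss_kind == "focal_eiou" && step >= cfg$warmup_iters
          lg <- image_loss_grads(det, fw$heads, gt_boxes, cfg$loss, use_focal,
                                 hard_frac = cfg$hard_frac)
          ep_loss <- ep_loss + lg$loss; ep_box <- ep_box + lg$box
          ep_obj <- ep_obj + lg$obj; ep_cls <- ep_cls + lg$cls
          n_img <- n_img + 1L
          detector_backward(det, lg$dheads, fw$cache, gcol)
        }
        adam_step(det, as.list(gcol), lr = lr, beta1 = cfg$momentum,
                  weight_decay = cfg$decay_weight)
        step <- step + 1L
      }
      mloss <- ep_loss / max(1L, n_img)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, loss = mloss, box = ep_box / max(1L, n_img),
        obj = ep_obj / max(1L, n_img), cls = ep_cls / max(1L, n_img), lr = lr)
      if (mloss < best * (1 - 1e-3)) { best <- mloss; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall >= cfg$patience) { lr <- lr * cfg$decay_factor; stall <- 0L }
      }
    }
  })
  log <- do.call(rbind, log_rows)
  det$log <- log
  invisible(log)
}

#' Run the detector on one image and return fused detections
#'
#' @param det A trained detector handle.
#' @param image `[H, W, 3]` array matching the spec's input size.
#' @param conf_thr Decode confidence threshold (default 0.05).
#' @param fusion A [fusion_config()] (default WBF) applied to the decoded
#'   boxes; `NULL` skips fusion.
#' @return Data frame of detections.
#' @export
detect_image <- function(det, image, conf_thr = 0.05, fusion = fusion_config()) {
  heads <- detector_forward(det, image)
  dets <- decode_predictions(heads, det$spec, conf_thr)
  if (is.null(fusion)) return(dets)
  if (fusion$mode == "nms") nms(dets, fusion) else wbf(dets, fusion)
}

#' Save a detector checkpoint
#'
#' The checkpoint is self-describing: it stores the network specification
#' (including its anchor preset) together with the weights.
#'
#' @param det A detector handle.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_detector <- function(det, path) {
  saveRDS(list(spec = det$spec,
               weights = lapply(det$layers, function(l) list(w = l$w, b = l$b)),
               t = det$t, log = det$log),
          path)
  invisible(path)
}

#' Load a detector checkpoint
#'
#' @param path Path written by [save_detector()].
#' @return A detector handle.
#' @export
load_detector <- function(path) {
  ck <- readRDS(path)
  det <- build_detector(ck$spec)
  for (nm in names(ck$weights)) {
    det$layers[[nm]]$w <- ck$weights[[nm]]$w
    det$layers[[nm]]$b <- ck$weights[[nm]]$b
  }
  det$t <- ck$t
  det$log <- ck$log
  det
}
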