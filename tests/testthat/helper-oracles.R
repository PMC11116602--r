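# Independent oracles used to cross-check the implementation, plus small
# seeded generators. Oracles deliberately use brute force / enumeration,
# never the code paths they check.

# pixel-rasterization IoU for integer-coordinate boxes on a finite canvas
raster_iou <- function(a, b, canvas = 64L) {
  grid_a <- matrix(FALSE, canvas, canvas)
  grid_b <- matrix(FALSE, canvas, canvas)
  # half-open boxes: pixel (i, j) covered iff x1 <= j-1 < x2 etc.
  fill <- function(g, box) {
    xs <- seq_len(canvas) - 1L
    g[xs >= box[2] & xs < box[4], ] <- TRUE  # rows = y
    g[, !(xs >= box[1] & xs < box[3])] <- FALSE
    g
  }
  ga <- fill(grid_a, a); gb <- fill(grid_b, b)
  inter <- sum(ga & gb); un <- sum(ga | gb)
  if (un == 0) 0 else inter / un
}

# random integer-coordinate box within [0, lim] with sides in [1, max_side]
rand_int_box <- function(lim = 50L, max_side = 50L) {
  w <- sample.int(min(max_side, lim), 1)
  h <- sample.int(min(max_side, lim), 1)
  x1 <- sample.int(lim - w + 1L, 1) - 1L
  y1 <- sample.int(lim - h + 1L, 1) - 1L
  c(x1, y1, x1 + w, y1 + h)
}

rand_float_box <- function(lim = 100) {
  x1 <- runif(1, 0, lim - 2); y1 <- runif(1, 0, lim - 2)
  c(x1, y1, x1 + runif(1, 0.5, lim - x1), y1 + runif(1, 0.5, lim - y1))
}

# O(n^2) reference NMS: keep a box iff no higher-ranked kept box overlaps it
brute_nms <- function(dets, thr) {
  ord <- order(-dets$score, dets$x1, dets$y1, dets$x2, dets$y2)
  d <- dets[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in kept) {
      if (box_iou(as.numeric(d[j, c("x1", "y1", "x2", "y2")]),
                  as.numeric(d[i, c("x1", "y1", "x2", "y2")])) >= thr) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  d[kept, , drop = FALSE]
}

# brute-force AP: sweep every threshold between consecutive ranked items,
# compute (R, P) points, apply the precision envelope by direct max-scan
ap_oracle <- function(tp_flags, n_gt) {
  n <- length(tp_flags)
  pts <- t(vapply(seq_len(n), function(k) {
    tp <- sum(tp_flags[seq_len(k)])
    c(r = tp / n_gt, p = tp / k)
  }, numeric(2)))
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n)) {
    r <- pts[k, "r"]
    if (r > prev_r) {
      p_env <- max(pts[pts[, "r"] >= r, "p"])
      ap <- ap + (r - prev_r) * p_env
      prev_r <- r
    }
  }
  unname(ap)
}

# exhaustive k-means oracle: best objective over all partitions of wh into
# K non-empty clusters with mean centers (only viable for tiny n)
kmeans_exhaustive <- function(wh, K) {
  n <- nrow(wh)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- Inf; best_asg <- NULL
  for (r in seq_len(nrow(assignments))) {
    asg <- assignments[r, ]
    if (length(unique(asg)) < K) next
    obj <- 0
    for (k in unique(asg)) {
      members <- wh[asg == k, , drop = FALSE]
      ctr <- colMeans(members)
      obj <- obj + sum(1 - wh_iou(members, matrix(ctr, 1)))
    }
    if (obj < best) { best <- obj; best_asg <- asg }
  }
  list(objective = best, assignment = best_asg)
}

# tiny scene helpers shared by network / pipeline tests
tiny_scene <- function(seed, size = 160L, n = c(6L, 10L), obj = c(8, 20)) {
  sp <- scene_spec(image_size = size, n_objects = n, object_size = obj,
                   size_mode = "side", seed = seed)
  generate_scene(sp)
}
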