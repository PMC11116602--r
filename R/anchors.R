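# ---------------------------------------------------------------------------
# Size-stratified anchor estimation.
#
# Ground-truth (w, h) pairs are split into size groups by quantiles of
# sqrt(w * h), and k-means is run inside each group under the position-free
# IoU distance (both boxes placed concentric, so only width and height
# matter). Each group feeds the anchors of one detection level, the smallest
# sizes going to the finest stride.
# ---------------------------------------------------------------------------

#' Position-free IoU between (width, height) pairs
#'
#' Both boxes are placed concentric, so the intersection is
#' `min(w1, w2) * min(h1, h2)`. Used as the clustering similarity for anchor
#' estimation.
#'
#' @param wh Matrix or data frame with columns `w, h` (one box per row).
#' @param centers Matrix or data frame with columns `w, h`.
#' @return A `nrow(wh)` by `nrow(centers)` IoU matrix.
#' @export
wh_iou <- function(wh, centers) {
  wh <- as_wh_matrix(wh); centers <- as_wh_matrix(centers)
  inter <- outer(wh[, 1], centers[, 1], pmin) * outer(wh[, 2], centers[, 2], pmin)
  un <- outer(wh[, 1] * wh[, 2], centers[, 1] * centers[, 2], `+`) - inter
  inter / un
}

as_wh_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("w", "h")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  colnames(x) <- c("w", "h")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("invalid geometry: widths and heights must be finite and positive")
  storage.mode(x) <- "double"
  x
}

#' Split boxes into size groups by quantiles of sqrt(w * h)
#'
#' Small, dense targets are unevenly represented across sizes; stratifying
#' by size before anchor clustering gives each size range its own anchors.
#' Boundaries are the empirical `i/n_groups` quantiles (order statistics) of
#' the size measure `sqrt(w * h)`; with distinct sizes the groups are
#' balanced to within one box.
#'
#' @param wh Matrix or data frame of box widths/heights in pixels.
#' @param n_groups Number of size groups (default 4).
#' @return An object of class `size_groups`: list with `groups` (list of
#'   `w, h` matrices ordered by ascending size) and `boundaries` (the
#'   `n_groups - 1` size thresholds).
#' @export
stratify_by_size <- function(wh, n_groups = 4L) {
  wh <- as_wh_matrix(wh)
  n <- nrow(wh)
  if (n < n_groups)
    stop("need at least ", n_groups, " boxes to form ", n_groups, " size groups")
  size <- sqrt(wh[, 1] * wh[, 2])
  if (n_groups == 1L) {
    out <- list(groups = list(wh[order(size), , drop = FALSE]),
                boundaries = numeric(0))
    class(out) <- "size_groups"
    return(out)
  }
  boundaries <- unname(quantile(size, probs = seq_len(n_groups - 1L) / n_groups,
                                type = 1))
  g <- findInterval(size, boundaries, left.open = TRUE) + 1L
  counts <- tabulate(g, nbins = n_groups)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L)[1L]
    tie <- if (empty > 1L) boundaries[empty - 1L] else boundaries[1L]
    stop("size group ", empty, " is empty: tied size value ", format(tie),
         " collapses the quantile boundaries")
  }
  groups <- lapply(seq_len(n_groups), function(i) {
    m <- wh[g == i, , drop = FALSE]
    m[order(sqrt(m[, 1] * m[, 2])), , drop = FALSE]
  })
  out <- list(groups = groups, boundaries = boundaries)
  class(out) <- "size_groups"
  out
}

#' k-means clustering of box sizes under the IoU distance
#'
#' Clusters (w, h) pairs with the distance `1 - IoU` of concentric boxes.
#' Centers are updated as the per-cluster means of member widths and
#' heights; iteration stops when no center moves by more than `tol` or
#' `max_iter` is reached. An empty cluster is re-seeded to the box farthest
#' from its current center.
#'
#' @param wh Matrix or data frame of box widths/heights (pixels).
#' @param K Number of clusters; must not exceed the number of distinct
#'   (w, h) pairs.
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum iterations (default 300).
#' @param tol Convergence tolerance on center movement (default 1e-6).
#' @param init `"kmeanspp"` (default) for k-means++ seeding or `"random"`
#'   for plain random selection of K boxes.
#' @return List with `centers` (K x 2 matrix, rows sorted by area),
#'   `assignment` (integer vector), `objective` (sum of IoU distances of
#'   boxes to their centers), `trace` (objective after each assignment
#'   step) and `iterations`.
#' @export
kmeans_iou <- function(wh, K, seed = 0L, max_iter = 300L, tol = 1e-6,
                       init = c("kmeanspp", "random")) {
  wh <- as_wh_matrix(wh)
  init <- match.arg(init)
  n <- nrow(wh)
  n_distinct <- nrow(unique(wh))
  if (K > n_distinct)
    stop("K = ", K, " exceeds the number of distinct (w, h) pairs (", n_distinct, ")")
  centers <- with_seed(seed, init_centers(wh, K, init))
  trace <- numeric(0)
  assignment <- rep(1L, n)
  for (iter in seq_len(max_iter)) {
    d <- 1 - wh_iou(wh, centers)
    assignment <- max.col(-d, ties.method = "first")
    # re-seed any empty cluster to the box farthest from its current center
    repeat {
      empty <- which(tabulate(assignment, nbins = K) == 0L)
      if (length(empty) == 0L) break
      k <- empty[1L]
      far <- which.max(d[cbind(seq_len(n), assignment)])
      message("kmeans_iou: re-seeding empty cluster ", k, " to box ", far)
      centers[k, ] <- wh[far, ]
      d <- 1 - wh_iou(wh, centers)
      assignment <- max.col(-d, ties.method = "first")
      assignment[far] <- k
    }
    trace <- c(trace, sum(d[cbind(seq_len(n), assignment)]))
    # mean update with a monotonicity guard: the member mean minimizes the
    # squared-Euclidean surrogate, not the IoU objective itself, so a mean
    # step that would raise a cluster's summed IoU distance is rejected
    # (keeping the previous center); this keeps the objective trace
    # non-increasing while the accepted updates remain plain means
    new_centers <- centers
    for (k in seq_len(K)) {
      members <- wh[assignment == k, , drop = FALSE]
      if (nrow(members) == 0L) next
      cand <- colMeans(members)
      old_cost <- sum(1 - wh_iou(members, centers[k, , drop = FALSE]))
      new_cost <- sum(1 - wh_iou(members, matrix(cand, 1)))
      if (new_cost <= old_cost) new_centers[k, ] <- cand
    }
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < tol) break
  }
  d <- 1 - wh_iou(wh, centers)
  assignment <- max.col(-d, ties.method = "first")
  objective <- sum(d[cbind(seq_len(n), assignment)])
  ord <- order(centers[, 1] * centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  assignment <- match(assignment, ord)
  list(centers = centers, assignment = assignment, objective = objective,
       trace = trace, iterations = iter)
}

init_centers <- function(wh, K, init) {
  n <- nrow(wh)
  if (init == "random") {
    idx <- sample.int(n, K)
    # resample until the seed boxes are distinct (guaranteed possible)
    while (nrow(unique(wh[idx, , drop = FALSE])) < K) idx <- sample.int(n, K)
    return(wh[idx, , drop = FALSE])
  }
  # k-means++ under the IoU distance
  idx <- sample.int(n, 1L)
  centers <- wh[idx, , drop = FALSE]
  while (nrow(centers) < K) {
    d <- 1 - wh_iou(wh, centers)
    dmin <- apply(d, 1, min)
    if (all(dmin <= 0)) {
      cand <- which(!duplicated(rbind(centers, wh))[-seq_len(nrow(centers))])
      nxt <- cand[sample.int(length(cand), 1L)]
    } else {
      nxt <- sample.int(n, 1L, prob = dmin^2)
    }
    centers <- rbind(centers, wh[nxt, , drop = FALSE])
  }
  centers
}

#' Build a stratified anchor preset from size groups
#'
#' Runs [kmeans_iou()] with `K = anchors_per_level` inside each size group;
#' the smallest group's anchors attach to the finest stride. With four
#' groups the strides are 4, 8, 16, 32 -- the stride-4 level is the
#' micro-scale detection head aimed at very small objects.
#'
#' @param groups A `size_groups` object from [stratify_by_size()].
#' @param anchors_per_level Anchors per detection level (default 3).
#' @param seed Integer seed for the per-group clustering.
#' @return An `anchor_preset` object.
#' @export
build_anchor_preset <- function(groups, anchors_per_level = 3L, seed = 0L) {
  stopifnot(inherits(groups, "size_groups"))
  n_groups <- length(groups$groups)
  strides <- utils::tail(c(4L, 8L, 16L, 32L), n_groups)
  levels <- lapply(seq_len(n_groups), function(i) {
    km <- kmeans_iou(groups$groups[[i]], K = anchors_per_level,
                     seed = seed + i - 1L)
    list(stride = strides[i], anchors = km$centers, objective = km$objective)
  })
  anchor_preset(levels, provenance = "kmeans")
}

#' Construct an anchor preset
#'
#' @param levels List of `list(stride =, anchors =)` entries; anchors are
#'   `w, h` matrices. Strides must be strictly increasing and drawn from
#'   4, 8, 16, 32.
#' @param provenance `"default"` or `"kmeans"`.
#' @return An object of class `anchor_preset`.
#' @export
anchor_preset <- function(levels, provenance = c("default", "kmeans")) {
  provenance <- match.arg(provenance)
  strides <- vapply(levels, function(l) as.integer(l$stride), integer(1))
  if (length(strides) == 0L || any(diff(strides) <= 0) ||
      !all(strides %in% c(4L, 8L, 16L, 32L)))
    stop("anchor preset strides must be strictly increasing values from {4, 8, 16, 32}")
  levels <- lapply(levels, function(l) {
    a <- as_wh_matrix(l$anchors)
    if (nrow(a) < 1L) stop("each level needs at least one anchor")
    l$anchors <- a[order(a[, 1] * a[, 2]), , drop = FALSE]
    l$stride <- as.integer(l$stride)
    l
  })
  structure(list(levels = levels, provenance = provenance),
            class = "anchor_preset")
}

#' The bundled default anchor preset
#'
#' The stock three-level anchors -- stride 8: (10,13), (16,30), (33,23);
#' stride 16: (30,61), (62,45), (59,119); stride 32: (116,90), (156,198),
#' (373,326) -- extended with a stride-4 micro-scale level obtained by
#' halving the stride-8 triple: (5,7), (8,15), (17,12). This preserves the
#' geometric progression of anchor sizes across levels.
#'
#' @return An `anchor_preset` with provenance `"default"`.
#' @export
default_anchor_preset <- function() {
  lv <- function(s, ...) list(stride = s, anchors = matrix(c(...), ncol = 2, byrow = TRUE))
  anchor_preset(list(
    lv(4, 5, 7, 8, 15, 17, 12),
    lv(8, 10, 13, 16, 30, 33, 23),
    lv(16, 30, 61, 62, 45, 59, 119),
    lv(32, 116, 90, 156, 198, 373, 326)), provenance = "default")
}

#' Restrict an anchor preset to a subset of strides
#'
#' @param preset An `anchor_preset`.
#' @param strides Integer strides to keep.
#' @return An `anchor_preset` with only the requested levels.
#' @export
subset_preset <- function(preset, strides) {
  keep <- Filter(function(l) l$stride %in% strides, preset$levels)
  if (length(keep) != length(strides))
    stop("preset does not cover strides ", paste(strides, collapse = ", "))
  anchor_preset(keep, provenance = preset$provenance)
}

#' @export
print.anchor_preset <- function(x, ...) {
  cat("anchor preset (", x$provenance, ")\n", sep = "")
  for (l in x$levels)
    cat(sprintf("  stride %2d: %s\n", l$stride,
                paste(sprintf("(%.4g,%.4g)", l$anchors[, 1], l$anchors[, 2]),
                      collapse = " ")))
  invisible(x)
}

#' Write an anchor preset to a plain-text file
#'
#' One line per level: `stride: w1,h1 w2,h2 ...`.
#'
#' @param preset An `anchor_preset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_file <- function(preset, path) {
  lines <- vapply(preset$levels, function(l) {
    sprintf("%d: %s", l$stride,
            paste(sprintf("%g,%g", l$anchors[, 1], l$anchors[, 2]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an anchor preset written by [write_anchor_file()]
#'
#' @param path Path to the anchor file.
#' @param provenance Provenance tag to attach (default `"kmeans"`).
#' @return An `anchor_preset`.
#' @export
read_anchor_file <- function(path, provenance = "kmeans") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  levels <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":")[[1]]
    pairs <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    wh <- do.call(rbind, lapply(strsplit(pairs, ","), as.numeric))
    list(stride = as.integer(parts[1]), anchors = wh)
  })
  anchor_preset(levels, provenance = provenance)
}
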