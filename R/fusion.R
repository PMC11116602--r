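# ---------------------------------------------------------------------------
# Detection post-processing: greedy NMS and weighted box fusion (WBF).
#
# NMS keeps the locally highest-scoring box and discards overlapping rivals;
# WBF instead replaces each overlap cluster with the confidence-weighted
# mean box, which keeps localization evidence from every member -- valuable
# for dense, partially occluded targets. Fusion is per class.
# ---------------------------------------------------------------------------

#' Fusion configuration
#'
#' @param cluster_iou_thr IoU threshold for grouping boxes, in (0, 1);
#'   default 0.55, the customary WBF setting.
#' @param score_thr Minimum confidence for a detection to enter fusion;
#'   default 0.001.
#' @param mode `"wbf"` or `"nms"`.
#' @param match_to_seed If `TRUE`, WBF cluster membership is tested against
#'   the cluster's seed box instead of its running fused box (sensitivity
#'   toggle; default `FALSE`).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(cluster_iou_thr = 0.55, score_thr = 0.001,
                          mode = c("wbf", "nms"), match_to_seed = FALSE) {
  mode <- match.arg(mode)
  if (cluster_iou_thr <= 0 || cluster_iou_thr >= 1)
    stop("cluster_iou_thr must be in (0, 1)")
  if (score_thr < 0 || score_thr >= 1) stop("score_thr must be in [0, 1)")
  structure(list(cluster_iou_thr = cluster_iou_thr, score_thr = score_thr,
                 mode = mode, match_to_seed = isTRUE(match_to_seed)),
            class = "fusion_config")
}

empty_detections <- function() {
  data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             score = numeric(), class_id = integer())
}

as_detections <- function(dets) {
  if (is.null(dets) || nrow(dets) == 0L) return(empty_detections())
  if (is.null(dets$class_id)) dets$class_id <- 0L
  stopifnot(all(c("x1", "y1", "x2", "y2", "score") %in% names(dets)))
  if (any(dets$score < 0 | dets$score > 1)) stop("scores must be in [0, 1]")
  dets
}

# deterministic order: score descending, then lexicographic coordinates
det_order <- function(dets)
  order(-dets$score, dets$x1, dets$y1, dets$x2, dets$y2)

# IoU of one box against the rows of a box matrix (hot path, no dispatch)
iou_vec <- function(b, x1, y1, x2, y2, area) {
  iw <- pmin(b[3], x2) - pmax(b[1], x1)
  ih <- pmin(b[4], y2) - pmax(b[2], y1)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / ((b[3] - b[1]) * (b[4] - b[2]) + area - inter)
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-score remaining box and discards every other
#' box overlapping it with IoU at or above `cfg$cluster_iou_thr`. Ties are
#' broken by lexicographic coordinates, so the result is independent of
#' input order.
#'
#' @param dets Data frame of detections with columns
#'   `x1, y1, x2, y2, score, class_id`.
#' @param cfg A [fusion_config()].
#' @return The kept detections, sorted by score descending.
#' @export
nms <- function(dets, cfg = fusion_config(mode = "nms")) {
  dets <- as_detections(dets)
  dets <- dets[dets$score >= cfg$score_thr, , drop = FALSE]
  if (nrow(dets) == 0L) return(empty_detections())
  out <- lapply(split(dets, dets$class_id), function(d) {
    d <- d[det_order(d), , drop = FALSE]
    B <- as_box_matrix(d)
    n <- nrow(B)
    keep <- logical(n)
    alive <- rep(TRUE, n)
    area <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
    for (i in seq_len(n)) {
      if (!alive[i]) next
      keep[i] <- TRUE
      rest <- which(alive)
      ious <- iou_vec(B[i, ], B[rest, 1], B[rest, 2], B[rest, 3], B[rest, 4],
                      area[rest])
      alive[rest[ious >= cfg$cluster_iou_thr]] <- FALSE
    }
    d[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[det_order(out), , drop = FALSE]
}

#' Weighted box fusion
#'
#' Boxes are clustered greedily in descending score order: a box joins the
#' first existing cluster whose current fused box overlaps it with IoU at or
#' above `cfg$cluster_iou_thr`, otherwise it starts a new cluster. Each
#' cluster's fused coordinates are the score-weighted means of its members'
#' corners (`C = sum(s_i x_i) / sum(s_i)`), so the fused box is biased
#' towards higher-confidence members; the fused score is the arithmetic
#' mean of member scores.
#'
#' @inheritParams nms
#' @param n_passes Number of inference passes that produced `dets` (e.g.
#'   resolutions in multi-pass fusion). When given, each cluster's fused
#'   score is additionally rescaled by `min(n_members, n_passes) /
#'   n_passes`, the reference procedure's corroboration weighting: a box
#'   confirmed by fewer passes ranks lower. `NULL` (default) disables the
#'   rescale; the fused score is then the plain arithmetic mean.
#' @return The fused detections, sorted by score descending.
#' @export
wbf <- function(dets, cfg = fusion_config(), n_passes = NULL) {
  dets <- as_detections(dets)
  dets <- dets[dets$score >= cfg$score_thr, , drop = FALSE]
  if (nrow(dets) == 0L) return(empty_detections())
  out <- lapply(split(dets, dets$class_id), function(d) {
    d <- d[det_order(d), , drop = FALSE]
    B <- as_box_matrix(d)
    s <- d$score
    n <- nrow(B)
    # running state: ref (match target: fused or seed), weighted corner sums,
    # score sums/counts, all grown geometrically to avoid per-box copies
    cap <- 64L
    ref <- matrix(0, cap, 4); wsum <- matrix(0, cap, 4)
    ssum <- numeric(cap); cnt <- integer(cap)
    k <- 0L
    for (i in seq_len(n)) {
      j <- 0L
      if (k > 0L) {
        ks <- seq_len(k)
        ious <- iou_vec(B[i, ], ref[ks, 1], ref[ks, 2], ref[ks, 3], ref[ks, 4],
                        (ref[ks, 3] - ref[ks, 1]) * (ref[ks, 4] - ref[ks, 2]))
        hit <- which(ious >= cfg$cluster_iou_thr)
        if (length(hit) > 0L) j <- hit[1L]  # first existing cluster wins
      }
      if (j > 0L) {
        wsum[j, ] <- wsum[j, ] + s[i] * B[i, ]
        ssum[j] <- ssum[j] + s[i]
        cnt[j] <- cnt[j] + 1L
        if (!cfg$match_to_seed) ref[j, ] <- wsum[j, ] / ssum[j]
      } else {
        k <- k + 1L
        if (k > cap) {
          cap <- cap * 2L
          ref <- rbind(ref, matrix(0, cap / 2L, 4))
          wsum <- rbind(wsum, matrix(0, cap / 2L, 4))
          ssum <- c(ssum, numeric(cap / 2L)); cnt <- c(cnt, integer(cap / 2L))
        }
        ref[k, ] <- B[i, ]; wsum[k, ] <- s[i] * B[i, ]
        ssum[k] <- s[i]; cnt[k] <- 1L
      }
    }
    ks <- seq_len(k)
    fused <- wsum[ks, , drop = FALSE] / ssum[ks]
    score <- ssum[ks] / cnt[ks]
    if (!is.null(n_passes))
      score <- score * pmin(cnt[ks], n_passes) / n_passes
    data.frame(x1 = fused[, 1], y1 = fused[, 2], x2 = fused[, 3], y2 = fused[, 4],
               score = score, class_id = d$class_id[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[det_order(out), , drop = FALSE]
}

#' Fuse detections from multiple inference resolutions
#'
#' Each entry's box coordinates live in its own resolution's pixel frame;
#' they are rescaled affinely to the target frame (factor
#' `target_size / resolution` on both axes), concatenated, and fused with
#' [wbf()]. Because IoU is invariant under this rescaling, detections of the
#' same object at different resolutions cluster together and their fused box
#' averages out per-resolution localization jitter.
#'
#' @param per_res_dets List of `list(resolution =, dets =)` entries.
#' @param target_size Edge length (pixels) of the target frame.
#' @param cfg A [fusion_config()].
#' @return Fused detections in the target frame.
#' @export
fuse_multiresolution <- function(per_res_dets, target_size, cfg = fusion_config()) {
  scaled <- lapply(per_res_dets, function(e) {
    if (is.null(e$resolution) || !is.finite(e$resolution) || e$resolution <= 0)
      stop("unknown or non-positive resolution in multi-resolution input")
    d <- as_detections(e$dets)
    f <- target_size / e$resolution
    d[, c("x1", "y1", "x2", "y2")] <- d[, c("x1", "y1", "x2", "y2")] * f
    d
  })
  wbf(do.call(rbind, scaled), cfg, n_passes = length(per_res_dets))
}

#' Read a detection CSV (`image_id,x1,y1,x2,y2,score,class_id`)
#'
#' @param path CSV path.
#' @return Data frame of detections with an `image_id` column.
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x1", "y1", "x2", "y2", "score", "class_id")
  if (!all(need %in% names(d)))
    stop("detection CSV must have columns ", paste(need, collapse = ","))
  d
}

#' Write a detection CSV
#'
#' @param dets Data frame with columns
#'   `image_id, x1, y1, x2, y2, score, class_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  utils::write.csv(dets[, c("image_id", "x1", "y1", "x2", "y2", "score", "class_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
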