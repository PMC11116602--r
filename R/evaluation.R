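# ---------------------------------------------------------------------------
# Detection metrics: greedy IoU matching, precision / recall / F1, and
# average precision from the all-point interpolated PR curve.
# ---------------------------------------------------------------------------

#' Match detections to ground truth on one image
#'
#' Detections are processed in descending score order (ties broken by
#' lexicographic coordinates); each is matched greedily to the not yet
#' matched ground-truth box with the highest IoU and counted as a true
#' positive iff that IoU exceeds `iou_thr` (strictly). Every ground-truth
#' box is credited to at most one detection; unmatched ground truths are
#' false negatives.
#'
#' @param dets Data frame of detections (`x1, y1, x2, y2, score`).
#' @param gts Data frame or matrix of ground-truth corner boxes.
#' @param iou_thr IoU threshold (default 0.5).
#' @return An object of class `match_result`: list with `tp` (logical flags
#'   in descending-score order), `scores` (the corresponding scores),
#'   `n_gt` and `n_fn`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  dets <- as_detections(dets)
  gts <- as_box_matrix(if (is.null(gts)) matrix(numeric(0), 0, 4) else gts)
  if (nrow(dets) > 0L) dets <- dets[det_order(dets), , drop = FALSE]
  n_gt <- nrow(gts)
  tp <- logical(nrow(dets))
  if (nrow(dets) > 0L && n_gt > 0L) {
    M <- iou_matrix(dets, gts)
    taken <- logical(n_gt)
    for (i in seq_len(nrow(dets))) {
      free <- which(!taken)
      if (length(free) == 0L) break
      j <- free[which.max(M[i, free])]
      if (M[i, j] > iou_thr) {
        tp[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  structure(list(tp = tp, scores = dets$score, n_gt = n_gt,
                 n_fn = n_gt - sum(tp)),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R) = 2TP / (2TP + FN + FP)`. Empty-case conventions:
#' `P = 1` with no detections, `R = 1` with no ground truth, `F1 = 0` when
#' `P + R = 0`.
#'
#' @param m A `match_result` (or a list of them, pooled).
#' @return Named numeric vector `c(P =, R =, F1 =)`.
#' @export
precision_recall_f1 <- function(m) {
  if (!inherits(m, "match_result")) {
    tp <- sum(vapply(m, function(x) sum(x$tp), numeric(1)))
    nd <- sum(vapply(m, function(x) length(x$tp), numeric(1)))
    fn <- sum(vapply(m, function(x) x$n_fn, numeric(1)))
  } else {
    tp <- sum(m$tp); nd <- length(m$tp); fn <- m$n_fn
  }
  fp <- nd - tp
  P <- if (nd == 0L) 1 else tp / nd
  R <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F1 = F1)
}

#' Precision-recall curve and average precision
#'
#' Pools matched detections over a dataset, sweeps the score threshold over
#' all distinct scores, and integrates the precision envelope over recall
#' (all-point interpolation: the precision at each recall level is the
#' maximum precision attained at any greater-or-equal recall), giving
#' `AP = integral of P(R) dR` in `[0, 1]`.
#'
#' @param matches A `match_result` or list of `match_result`s (one per
#'   image).
#' @return An object of class `pr_curve`: list with `recall`, `precision`
#'   (raw curve points at each distinct score threshold) and `ap`.
#' @export
pr_curve_and_ap <- function(matches) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  tp <- unlist(lapply(matches, `[[`, "tp"))
  scores <- unlist(lapply(matches, `[[`, "scores"))
  n_gt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
  if (n_gt == 0L) stop("AP is undefined with zero ground-truth boxes")
  ord <- order(-scores)
  tp <- tp[ord]; scores <- scores[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  # one PR point per distinct score threshold (last index at each score)
  last <- which(!duplicated(scores, fromLast = TRUE))
  recall <- cum_tp[last] / n_gt
  precision <- cum_tp[last] / (cum_tp[last] + cum_fp[last])
  if (length(recall) == 0L) {
    out <- list(recall = numeric(0), precision = numeric(0), ap = 0)
    class(out) <- "pr_curve"
    return(out)
  }
  # precision envelope: max precision at any recall >= r
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  structure(list(recall = recall, precision = precision, ap = ap),
            class = "pr_curve")
}

#' Evaluate detections against ground truth over a set of images
#'
#' Convenience wrapper: matches per image at `iou_thr`, then reports pooled
#' precision/recall/F1 (over all detections) and AP from the PR curve.
#'
#' @param dets_by_image Named list of detection data frames.
#' @param gts_by_image Named list of ground-truth corner-box data frames
#'   (same names).
#' @param iou_thr IoU matching threshold (default 0.5).
#' @return List with `P`, `R`, `F1`, `ap`, and the `pr_curve`.
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image, iou_thr = 0.5) {
  ids <- union(names(dets_by_image), names(gts_by_image))
  matches <- lapply(ids, function(id)
    match_detections(dets_by_image[[id]], gts_by_image[[id]], iou_thr))
  prf <- precision_recall_f1(matches)
  pr <- pr_curve_and_ap(matches)
  list(P = unname(prf["P"]), R = unname(prf["R"]), F1 = unname(prf["F1"]),
       ap = pr$ap, pr_curve = pr)
}
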