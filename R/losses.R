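# ---------------------------------------------------------------------------
# Bounding-box regression losses.
#
# CIoU penalizes center distance plus an aspect-ratio term; EIoU replaces
# the aspect term with direct width and height differences (normalized by
# the enclosing box), which converges faster for small boxes; Focal-EIoU
# reweights EIoU by IoU^gamma so well-overlapping (high-quality) pairs
# dominate the gradient.
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param gamma Outlier-suppression exponent of the focal reweighting
#'   (`IoU^gamma`); `gamma = 0` disables it. Default 0.5.
#' @param eps Small positive stabilizer guarding denominators; must be in
#'   `(0, 1e-6]`.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(gamma = 0.5, eps = 1e-9) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (eps <= 0 || eps > 1e-6) stop("eps must be in (0, 1e-6]")
  structure(list(gamma = gamma, eps = eps), class = "loss_config")
}

box_wh <- function(b) c(b[[3]] - b[[1]], b[[4]] - b[[2]])

#' CIoU bounding-box regression loss
#'
#' `1 - IoU + rho^2 / c^2 + alpha * nu`, where `rho^2` is the squared center
#' distance, `c` the diagonal of the smallest enclosing box,
#' `nu = (4 / pi^2) (arctan(w/h) - arctan(w_gt/h_gt))^2` the aspect-ratio
#' penalty and `alpha = nu / ((1 - IoU) + nu)` its trade-off weight.
#'
#' @param pred,gt Corner boxes (`c(x1, y1, x2, y2)`).
#' @param eps Denominator stabilizer.
#' @return A non-negative number; 0 iff the boxes are identical.
#' @export
ciou_loss <- function(pred, gt, eps = 1e-9) {
  validate_corner_box(pred); validate_corner_box(gt)
  iou <- box_iou(pred, gt)
  enc <- enclosing_box(pred, gt)
  ewh <- box_wh(enc)
  c2 <- ewh[1]^2 + ewh[2]^2
  rho2 <- center_dist_sq(pred, gt)
  pwh <- box_wh(pred); gwh <- box_wh(gt)
  nu <- (4 / pi^2) * (atan(pwh[1] / pwh[2]) - atan(gwh[1] / gwh[2]))^2
  alpha <- if (nu == 0) 0 else nu / ((1 - iou) + nu + eps)
  (1 - iou) + rho2 / (c2 + eps) + alpha * nu
}

#' EIoU bounding-box regression loss
#'
#' `(1 - IoU) + rho^2(b, b_gt) / (w_c^2 + h_c^2) + (w - w_gt)^2 / w_c^2 +
#' (h - h_gt)^2 / h_c^2`, with `w_c, h_c` the enclosing box's width and
#' height. The width/height terms directly minimize the size mismatch
#' instead of the aspect ratio.
#'
#' @inheritParams ciou_loss
#' @return A non-negative number; 0 iff the boxes are identical.
#' @export
eiou_loss <- function(pred, gt, eps = 1e-9) {
  validate_corner_box(pred); validate_corner_box(gt)
  iou <- box_iou(pred, gt)
  ewh <- box_wh(enclosing_box(pred, gt))
  rho2 <- center_dist_sq(pred, gt)
  pwh <- box_wh(pred); gwh <- box_wh(gt)
  (1 - iou) +
    rho2 / (ewh[1]^2 + ewh[2]^2 + eps) +
    (pwh[1] - gwh[1])^2 / (ewh[1]^2 + eps) +
    (pwh[2] - gwh[2])^2 / (ewh[2]^2 + eps)
}

#' Focal-EIoU bounding-box regression loss
#'
#' `IoU^gamma * EIoU(pred, gt)`, implemented literally. With `gamma = 0` it
#' reduces exactly to EIoU. Note the literal form gives zero loss (and zero
#' gradient) for fully disjoint pairs, so training warms up with plain EIoU
#' for a configurable number of iterations (see [train_detector()]).
#'
#' @inheritParams ciou_loss
#' @param cfg A [loss_config()] supplying `gamma` and `eps`.
#' @return A non-negative number.
#' @export
focal_eiou_loss <- function(pred, gt, cfg = loss_config()) {
  iou <- box_iou(pred, gt)
  e <- eiou_loss(pred, gt, eps = cfg$eps)
  if (cfg$gamma == 0) return(e)
  iou^cfg$gamma * e
}
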