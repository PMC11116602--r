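#' @useDynLib microdet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile runif rnorm setNames median
#' @importFrom utils read.table write.table head
NULL

# ---------------------------------------------------------------------------
# Box representations.
#
# A corner box is a numeric vector c(x1, y1, x2, y2) in pixels, origin at the
# image top-left, x to the right and y down, with half-open [x1, x2) extent so
# that area = (x2 - x1) * (y2 - y1) and IoU is exact under affine rescaling.
# Collections of boxes are data frames with those columns (detections add
# `score` and `class_id`).
# ---------------------------------------------------------------------------

#' Construct a corner-coordinate box
#'
#' @param x1,y1,x2,y2 Box corners in pixels (top-left origin, y down). The
#'   box spans the half-open rectangle `[x1, x2) x [y1, y2)`.
#' @return A named numeric vector of class `corner_box`.
#' @export
corner_box <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_corner_box(b)
  class(b) <- "corner_box"
  b
}

validate_corner_box <- function(b) {
  if (length(b) < 4L || !all(is.finite(b[1:4])))
    stop("invalid geometry: box coordinates must be four finite numbers")
  if (b[[3]] <= b[[1]] || b[[4]] <= b[[2]])
    stop("invalid geometry: degenerate box (x2 <= x1 or y2 <= y1)")
  invisible(b)
}

box_area <- function(b) (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])

#' Intersection over union of two boxes
#'
#' IoU is the area of the intersection divided by the area of the union of
#' the two rectangles; boxes that touch only along an edge have intersection
#' area zero and therefore IoU 0.
#'
#' @param a,b Corner boxes (`c(x1, y1, x2, y2)`).
#' @return A number in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  validate_corner_box(a); validate_corner_box(b)
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' IoU distance between two boxes
#'
#' The clustering metric `d(a, b) = 1 - IoU(a, b)`: 0 for identical boxes,
#' 1 for disjoint ones.
#'
#' @inheritParams box_iou
#' @return A number in `[0, 1]`.
#' @export
iou_distance <- function(a, b) 1 - box_iou(a, b)

#' Pairwise IoU matrix between two sets of boxes
#'
#' @param A,B Matrices or data frames with columns `x1, y1, x2, y2` (one box
#'   per row).
#' @return A `nrow(A)` by `nrow(B)` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- as_box_matrix(A); B <- as_box_matrix(B)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- outer(A[, 1], B[, 1], pmax)
  iy1 <- outer(A[, 2], B[, 2], pmax)
  ix2 <- outer(A[, 3], B[, 3], pmin)
  iy2 <- outer(A[, 4], B[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  un <- outer(areaA, areaB, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

as_box_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x1", "y1", "x2", "y2")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 4,
                                   dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  storage.mode(x) <- "double"
  x
}

#' Smallest enclosing box of two boxes
#'
#' @inheritParams box_iou
#' @return A `corner_box` containing both inputs.
#' @export
enclosing_box <- function(a, b) {
  validate_corner_box(a); validate_corner_box(b)
  corner_box(min(a[[1]], b[[1]]), min(a[[2]], b[[2]]),
             max(a[[3]], b[[3]]), max(a[[4]], b[[4]]))
}

#' Squared distance between box centers
#'
#' @inheritParams box_iou
#' @return Squared Euclidean distance between the two box centers (pixels^2).
#' @export
center_dist_sq <- function(a, b) {
  validate_corner_box(a); validate_corner_box(b)
  dx <- (a[[1]] + a[[3]]) / 2 - (b[[1]] + b[[3]]) / 2
  dy <- (a[[2]] + a[[4]]) / 2 - (b[[2]] + b[[4]]) / 2
  dx * dx + dy * dy
}

# ---------------------------------------------------------------------------
# Normalized (YOLO-dialect) labels: data frames with columns
# class_id, cx, cy, w, h -- all fractions of the image width/height.
# ---------------------------------------------------------------------------

#' Convert a normalized center-format label to pixel corner coordinates
#'
#' @param y A numeric vector `c(class_id, cx, cy, w, h)` or a data frame of
#'   such rows; `cx, cy, w, h` are fractions of the image size.
#' @param img_w,img_h Image width and height in pixels.
#' @return A `corner_box` (or a data frame of corner boxes with `class_id`).
#' @export
yolo_to_corner <- function(y, img_w, img_h) {
  stopifnot(img_w > 0, img_h > 0)
  if (is.data.frame(y)) {
    out <- data.frame(
      x1 = (y$cx - y$w / 2) * img_w, y1 = (y$cy - y$h / 2) * img_h,
      x2 = (y$cx + y$w / 2) * img_w, y2 = (y$cy + y$h / 2) * img_h,
      class_id = y$class_id)
    bad <- out$x2 <= out$x1 | out$y2 <= out$y1
    if (any(bad)) stop("invalid geometry: zero-size box after conversion")
    return(out)
  }
  cx <- y[[2]] * img_w; cy <- y[[3]] * img_h
  w <- y[[4]] * img_w; h <- y[[5]] * img_h
  if (w <= 0 || h <= 0) stop("invalid geometry: zero-size box after conversion")
  corner_box(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Convert pixel corner coordinates to a normalized center-format label
#'
#' Boxes that overshoot the image bounds by at most one pixel (a common
#' artifact of tiling remaps) are clamped back into `[0, 1]` with a warning;
#' larger violations are an error.
#'
#' @param box A corner box or data frame of corner boxes.
#' @param img_w,img_h Image width and height in pixels.
#' @param class_id Integer class id attached to the label (default 0), used
#'   when `box` carries none.
#' @return A data frame with columns `class_id, cx, cy, w, h`.
#' @export
corner_to_yolo <- function(box, img_w, img_h, class_id = 0L) {
  stopifnot(img_w > 0, img_h > 0)
  if (!is.data.frame(box))
    box <- data.frame(x1 = box[[1]], y1 = box[[2]], x2 = box[[3]], y2 = box[[4]],
                      class_id = class_id)
  if (is.null(box$class_id)) box$class_id <- class_id
  over <- pmax(0, -box$x1, -box$y1, box$x2 - img_w, box$y2 - img_h)
  if (any(over > 1))
    stop("invalid geometry: box exceeds image bounds by more than 1 px")
  if (any(over > 0)) {
    warning("clamping ", sum(over > 0), " box(es) overshooting image bounds by <= 1 px")
    box$x1 <- pmax(box$x1, 0); box$y1 <- pmax(box$y1, 0)
    box$x2 <- pmin(box$x2, img_w); box$y2 <- pmin(box$y2, img_h)
  }
  if (any(box$x2 <= box$x1 | box$y2 <= box$y1))
    stop("invalid geometry: degenerate box after clamping")
  data.frame(class_id = as.integer(box$class_id),
             cx = (box$x1 + box$x2) / 2 / img_w,
             cy = (box$y1 + box$y2) / 2 / img_h,
             w = (box$x2 - box$x1) / img_w,
             h = (box$y2 - box$y1) / img_h)
}

#' Read a YOLO-dialect label file
#'
#' One line per object: `class_id cx cy w h`, space-separated, normalized
#' coordinates. Blank lines and trailing whitespace are tolerated.
#'
#' @param path Path to a `.txt` label file.
#' @return A data frame with columns `class_id, cx, cy, w, h` (zero rows if
#'   the file is empty).
#' @export
read_yolo_labels <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  empty <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  if (length(lines) == 0L) return(empty)
  fields <- do.call(rbind, lapply(strsplit(lines, "[[:space:]]+"), as.numeric))
  if (ncol(fields) != 5L) stop("malformed label file: ", path)
  out <- data.frame(class_id = as.integer(fields[, 1]), cx = fields[, 2],
                    cy = fields[, 3], w = fields[, 4], h = fields[, 5])
  if (any(out$w <= 0 | out$h <= 0 | out$w > 1 | out$h > 1))
    stop("invalid geometry: label width/height outside (0, 1] in ", path)
  out
}

#' Write a YOLO-dialect label file
#'
#' @param labels Data frame with columns `class_id, cx, cy, w, h`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", as.integer(labels$class_id),
                   labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

# run an expression with a temporarily seeded RNG, restoring prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
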