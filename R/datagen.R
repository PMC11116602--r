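# ---------------------------------------------------------------------------
# Synthetic dense-small-target scene generation and preprocessing.
#
# Scenes emulate UAV tiles of field vegetation: a textured soil/vegetation
# background with many small, irregular, multi-lobed green blobs (the
# targets), optionally overlapping, with tight bounding-box labels. Images
# are [H, W, 3] arrays in [0, 1] (row = y, col = x).
# ---------------------------------------------------------------------------

#' Scene specification for the synthetic generator
#'
#' @param image_size Square image edge in pixels (default 640).
#' @param n_objects Integer range `c(min, max)` of targets per scene
#'   (default 20--60, a dense tile).
#' @param object_size Range of the per-object size draw; with
#'   `size_mode = "area"` (default) it is the blob footprint in pixels^2
#'   (default 50--450), with `"side"` it is the bounding-box side length in
#'   pixels.
#' @param overlap_prob Probability that an object is deliberately placed
#'   overlapping an existing one (default 0.3).
#' @param background List with `base` (RGB triple of the mean soil tone)
#'   and `noise_scale` (amplitude of the low-frequency texture).
#' @param seed Integer seed; scenes are bit-reproducible given the spec.
#' @param size_mode `"area"` or `"side"` (see `object_size`).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 640L, n_objects = c(20L, 60L),
                       object_size = c(50, 450), overlap_prob = 0.3,
                       background = list(base = c(0.35, 0.32, 0.22),
                                         noise_scale = 0.08),
                       seed = 0L, size_mode = c("area", "side")) {
  size_mode <- match.arg(size_mode)
  n_objects <- as.integer(rep(n_objects, length.out = 2))
  if (image_size < 16) stop("image_size too small")
  if (any(n_objects < 1) || n_objects[2] < n_objects[1]) stop("bad n_objects range")
  if (any(object_size <= 0) || object_size[2] < object_size[1]) stop("bad object_size range")
  if (overlap_prob < 0 || overlap_prob > 1) stop("overlap_prob must be in [0, 1]")
  structure(list(image_size = as.integer(image_size), n_objects = n_objects,
                 object_size = object_size, overlap_prob = overlap_prob,
                 background = background, seed = as.integer(seed),
                 size_mode = size_mode),
            class = "scene_spec")
}

# low-frequency value noise: white noise blurred to the requested scale
value_noise <- function(n, blur_sigma) {
  z <- matrix(rnorm(n * n), n, n)
  as.matrix(EBImage::gblur(EBImage::Image(z), sigma = blur_sigma))
}

# rasterize one multi-lobed blob mask on a local canvas of side `side`;
# lobes are ellipses clustered near the canvas center so the union stays
# compact (bounding-box fill ratio >= ~0.6)
render_blob_mask <- function(side) {
  cx <- side / 2; cy <- side / 2
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)  # col = x
  ys <- matrix(rep(seq_len(side) - 0.5, side), side, side)          # row = y
  for (attempt in 1:8) {
    n_lobes <- sample(2:4, 1)
    mask <- matrix(FALSE, side, side)
    for (l in seq_len(n_lobes)) {
      a <- side * runif(1, 0.28, 0.46)
      b <- a * runif(1, 0.55, 1.0)
      th <- runif(1, 0, pi)
      ox <- cx + side * runif(1, -0.12, 0.12)
      oy <- cy + side * runif(1, -0.12, 0.12)
      u <- (xs - ox) * cos(th) + (ys - oy) * sin(th)
      v <- -(xs - ox) * sin(th) + (ys - oy) * cos(th)
      mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
    }
    if (!any(mask)) next
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    fill <- sum(mask[rows[1]:rows[2], cols[1]:cols[2]]) /
      ((rows[2] - rows[1] + 1) * (cols[2] - cols[1] + 1))
    if (fill >= 0.6) return(mask)
  }
  # fall back to a compact single ellipse (fill ratio ~ pi/4)
  ((xs - cx) / (side * 0.42))^2 + ((ys - cy) / (side * 0.34))^2 <= 1
}

#' Generate one synthetic dense-target scene
#'
#' Renders `n_objects` irregular multi-lobed green blobs, distinct in hue
#' and texture from the soil-toned background, at sizes sampled from the
#' spec's range; labels are the tight bounding boxes of the rendered blobs
#' in normalized center format. Bit-reproducible given `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (`[H, W, 3]` array in `[0, 1]`), `labels`
#'   (YOLO-dialect data frame) and `masks` (list of per-object pixel-index
#'   matrices, for diagnostics).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    N <- spec$image_size
    # background: soil tone + low-frequency mottling + fine grain
    base <- spec$background$base
    lowf <- value_noise(N, blur_sigma = N / 24)
    lowf <- lowf / max(abs(lowf), 1e-9) * spec$background$noise_scale
    img <- array(0, c(N, N, 3))
    for (c in 1:3)
      img[, , c] <- base[c] + lowf * (1 + 0.3 * c) +
        matrix(rnorm(N * N, sd = 0.015), N, N)
    n_obj <- if (spec$n_objects[1] == spec$n_objects[2]) spec$n_objects[1]
             else sample(spec$n_objects[1]:spec$n_objects[2], 1)
    labels <- NULL
    masks <- vector("list", n_obj)
    placed <- matrix(numeric(0), 0, 4)  # corner boxes of placed objects
    for (k in seq_len(n_obj)) {
      side <- blob_side(spec)
      if (side > N - 2) stop("objects cannot be placed: image too small for object size")
      mask <- render_blob_mask(side)
      rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
      bw <- cols[2] - cols[1] + 1; bh <- rows[2] - rows[1] + 1
      # choose a placement for the mask's top-left corner
      if (nrow(placed) > 0 && runif(1) < spec$overlap_prob) {
        j <- sample.int(nrow(placed), 1)
        ox <- round(runif(1, placed[j, 1] - bw / 2, placed[j, 3] - bw / 2))
        oy <- round(runif(1, placed[j, 2] - bh / 2, placed[j, 4] - bh / 2))
      } else {
        ox <- sample.int(max(1, N - side), 1) - 1L
        oy <- sample.int(max(1, N - side), 1) - 1L
      }
      ox <- min(max(ox, 1 - cols[1]), N - cols[2])
      oy <- min(max(oy, 1 - rows[1]), N - rows[2])
      idx <- which(mask, arr.ind = TRUE)
      py <- idx[, 1] + oy; px <- idx[, 2] + ox
      # leaf colour: green hue, per-plant brightness, per-pixel texture
      g <- runif(1, 0.45, 0.75)
      col_rgb <- c(g * runif(1, 0.35, 0.55), g, g * runif(1, 0.15, 0.35))
      tex <- rnorm(length(py), sd = 0.05)
      for (c in 1:3)
        img[cbind(py, px, c)] <- pmin(pmax(col_rgb[c] + tex, 0), 1)
      box <- c(ox + cols[1] - 1, oy + rows[1] - 1, ox + cols[2], oy + rows[2])
      placed <- rbind(placed, box)
      masks[[k]] <- cbind(y = py, x = px)
      labels <- rbind(labels, corner_to_yolo(corner_box(box[1], box[2], box[3], box[4]),
                                             N, N, class_id = 0L))
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, labels = labels, masks = masks)
  })
}

blob_side <- function(spec) {
  s <- runif(1, spec$object_size[1], spec$object_size[2])
  if (spec$size_mode == "area") max(4L, round(sqrt(s / 0.6)))
  else max(4L, round(s))
}

#' Cut an image into a regular grid of tiles, remapping labels
#'
#' Boxes are clipped to each tile; a clipped box retaining less than 20% of
#' its original area is dropped (the count of dropped boxes is attached as
#' attribute `n_dropped` and reported via `message`).
#'
#' @param image `[H, W, 3]` array.
#' @param labels YOLO-dialect label data frame (normalized to the full
#'   image).
#' @param tile Tile edge in pixels (default 640).
#' @param overlap Overlap between adjacent tiles in pixels (default 0).
#' @return List of `list(image =, labels =, origin = c(x, y))` tiles, with
#'   attribute `n_dropped`.
#' @export
tile_image <- function(image, labels, tile = 640L, overlap = 0L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (tile > H || tile > W) stop("tile size exceeds image dimensions")
  step <- tile - overlap
  xs <- seq(0, W - tile, by = step)
  ys <- seq(0, H - tile, by = step)
  boxes <- if (nrow(labels) > 0) yolo_to_corner(labels, W, H) else NULL
  dropped <- 0L
  tiles <- list()
  for (oy in ys) for (ox in xs) {
    timg <- image[(oy + 1):(oy + tile), (ox + 1):(ox + tile), , drop = FALSE]
    tlab <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric())
    if (!is.null(boxes) && nrow(boxes) > 0) {
      cx1 <- pmax(boxes$x1 - ox, 0); cy1 <- pmax(boxes$y1 - oy, 0)
      cx2 <- pmin(boxes$x2 - ox, tile); cy2 <- pmin(boxes$y2 - oy, tile)
      keep_geom <- cx2 > cx1 & cy2 > cy1
      orig_area <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)
      frac <- ifelse(keep_geom, pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0) / orig_area, 0)
      keep <- frac >= 0.2
      dropped <- dropped + sum(keep_geom & !keep)
      if (any(keep)) {
        tlab <- corner_to_yolo(data.frame(x1 = cx1[keep], y1 = cy1[keep],
                                          x2 = cx2[keep], y2 = cy2[keep],
                                          class_id = boxes$class_id[keep]),
                               tile, tile)
      }
    }
    tiles[[length(tiles) + 1L]] <- list(image = timg, labels = tlab,
                                        origin = c(x = ox, y = oy))
  }
  if (dropped > 0) message("tile_image: dropped ", dropped,
                           " box(es) retaining < 20% of their area")
  attr(tiles, "n_dropped") <- dropped
  tiles
}

#' Variance-of-Laplacian sharpness score
#'
#' Applies the 3x3 Laplacian kernel to the grayscale image and returns the
#' variance of the interior response. Low values indicate motion or defocus
#' blur.
#'
#' @param image `[H, W, 3]` or `[H, W]` array in `[0, 1]`.
#' @return A non-negative number.
#' @export
laplacian_sharpness <- function(image) {
  g <- if (length(dim(image)) == 3L) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
       else image
  H <- nrow(g); W <- ncol(g)
  if (is.null(H) || H < 3 || W < 3) stop("image too small for Laplacian response")
  core <- g[2:(H - 1), 2:(W - 1)]
  lap <- g[1:(H - 2), 2:(W - 1)] + g[3:H, 2:(W - 1)] +
    g[2:(H - 1), 1:(W - 2)] + g[2:(H - 1), 3:W] - 4 * core
  stats::var(as.vector(lap))
}

#' Filter out blurred images by Laplacian sharpness
#'
#' @param images List of image arrays.
#' @param thr Absolute sharpness threshold; if `NULL` (default) the 25th
#'   percentile of the batch's sharpness values is used.
#' @return The kept images, with attributes `sharpness` (all scores) and
#'   `kept` (logical).
#' @export
filter_blurred <- function(images, thr = NULL) {
  s <- vapply(images, laplacian_sharpness, numeric(1))
  if (is.null(thr)) thr <- unname(quantile(s, 0.25))
  kept <- s >= thr
  message("filter_blurred: kept ", sum(kept), "/", length(kept),
          " images at threshold ", format(thr))
  out <- images[kept]
  attr(out, "sharpness") <- s
  attr(out, "kept") <- kept
  out
}

#' An augmentation operation
#'
#' @param kind One of `"rot90"`, `"rot180"`, `"hflip"`, `"brighten"`,
#'   `"darken"`, `"salt_pepper"`, `"gaussian_noise"`.
#' @param magnitude Operation parameter: gain for brighten/darken (defaults
#'   1.3 / 0.7), pixel-corruption density for salt-and-pepper (default
#'   0.02), noise standard deviation for Gaussian noise (default 0.02);
#'   ignored by geometric ops.
#' @return A list of class `augment_op`.
#' @export
augment_op <- function(kind, magnitude = NULL) {
  kinds <- c("rot90", "rot180", "hflip", "brighten", "darken",
             "salt_pepper", "gaussian_noise")
  if (!kind %in% kinds) stop("unknown augmentation kind: ", kind)
  if (is.null(magnitude))
    magnitude <- switch(kind, brighten = 1.3, darken = 0.7,
                        salt_pepper = 0.02, gaussian_noise = 0.02, 0)
  if (kind == "salt_pepper" && (magnitude < 0 || magnitude > 1))
    stop("salt_pepper density must be in [0, 1]")
  if (kind %in% c("brighten", "darken") && magnitude <= 0)
    stop("brightness gain must be positive")
  structure(list(kind = kind, magnitude = magnitude), class = "augment_op")
}

#' Apply an augmentation to an image and its labels
#'
#' Geometric ops transform the labels consistently (90-degree rotation maps
#' `(cx, cy, w, h)` to `(cy, 1 - cx, h, w)`; 180-degree to
#' `(1 - cx, 1 - cy, w, h)`; horizontal flip to `(1 - cx, cy, w, h)`);
#' photometric ops leave labels untouched. Noise ops draw from a seeded
#' RNG.
#'
#' @param image `[H, W, 3]` array.
#' @param labels YOLO-dialect label data frame.
#' @param op An [augment_op()] (or a kind string).
#' @param seed Integer seed used by noise ops.
#' @return List with transformed `image` and `labels`.
#' @export
augment <- function(image, labels, op, seed = 0L) {
  if (is.character(op)) op <- augment_op(op)
  stopifnot(inherits(op, "augment_op"))
  H <- dim(image)[1]; W <- dim(image)[2]
  out_lab <- labels
  out_img <- switch(op$kind,
    rot90 = {
      # point map (x, y) -> (y, 1 - x); a [H, W] image becomes [W, H]
      new <- array(0, c(W, H, dim(image)[3]))
      for (c in seq_len(dim(image)[3]))
        new[, , c] <- t(image[, W:1, c])
      new
    },
    rot180 = image[H:1, W:1, , drop = FALSE],
    hflip = image[, W:1, , drop = FALSE],
    brighten = pmin(image * op$magnitude, 1),
    darken = pmin(image * op$magnitude, 1),
    salt_pepper = with_seed(seed, {
      n <- round(op$magnitude * H * W)
      img <- image
      if (n > 0) {
        ij <- cbind(sample.int(H, n, replace = TRUE), sample.int(W, n, replace = TRUE))
        v <- sample(c(0, 1), n, replace = TRUE)
        for (c in seq_len(dim(image)[3])) img[cbind(ij, c)] <- v
      }
      img
    }),
    gaussian_noise = with_seed(seed,
      pmin(pmax(image + array(rnorm(length(image), sd = op$magnitude),
                              dim(image)), 0), 1)),
    stop("unknown augmentation kind: ", op$kind))
  if (nrow(labels) > 0 && op$kind %in% c("rot90", "rot180", "hflip")) {
    out_lab <- switch(op$kind,
      rot90 = data.frame(class_id = labels$class_id, cx = labels$cy,
                         cy = 1 - labels$cx, w = labels$h, h = labels$w),
      rot180 = data.frame(class_id = labels$class_id, cx = 1 - labels$cx,
                          cy = 1 - labels$cy, w = labels$w, h = labels$h),
      hflip = data.frame(class_id = labels$class_id, cx = 1 - labels$cx,
                         cy = labels$cy, w = labels$w, h = labels$h))
  }
  list(image = out_img, labels = out_lab)
}

#' Resample an image to multiple resolutions
#'
#' Bilinear resize to each requested size; normalized labels are
#' resolution-invariant and pass through unchanged. Each record carries its
#' resolution tag for stratified evaluation.
#'
#' @param image `[H, W, 3]` array.
#' @param labels YOLO-dialect label data frame.
#' @param sizes Target edge lengths (default `c(100, 160, 320, 640)`).
#' @return List of `list(size =, image =, labels =)` records.
#' @export
resample_multires <- function(image, labels, sizes = c(100, 160, 320, 640)) {
  stopifnot(all(sizes > 0))
  lapply(sizes, function(s) {
    im <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    rs <- EBImage::resize(im, w = s, h = s)
    list(size = s, image = aperm(as.array(rs), c(2, 1, 3)), labels = labels)
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Generates `n_images` scenes (per-image seeds derived from `seed`),
#' optionally applies one randomly chosen augmentation per image, writes
#' `images/*.png` and `labels/*.txt`, and a `manifest.json` recording split
#' membership, seeds and the scene spec. Splits follow the given
#' proportions (rounded), are disjoint, and cover all images.
#'
#' @param spec A [scene_spec()] (its `seed` field is overridden per image).
#' @param n_images Number of scenes (at least 10 under the default split).
#' @param split Train/validation/test proportions summing to 1 (default
#'   `c(0.7, 0.2, 0.1)`).
#' @param seed Master seed.
#' @param dir Output directory.
#' @param augment_kinds Augmentation kinds sampled uniformly per image, or
#'   `NULL` to disable.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
build_dataset <- function(spec, n_images, split = c(0.7, 0.2, 0.1), seed = 0L,
                          dir = tempfile("scenes"), augment_kinds = NULL) {
  stopifnot(abs(sum(split) - 1) < 1e-9)
  sizes <- round(split * n_images)
  sizes[1] <- n_images - sum(sizes[-1])
  if (any(sizes < 1)) stop("n_images too small for the requested split (need >= 10)")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  membership <- rep(c("train", "val", "test"), times = sizes)
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec; sp$seed <- seed * 10000L + i
    sc <- generate_scene(sp)
    img <- sc$image; lab <- sc$labels
    aug <- NA_character_
    if (!is.null(augment_kinds)) {
      aug <- with_seed(sp$seed + 1L, sample(augment_kinds, 1))
      a <- augment(img, lab, aug, seed = sp$seed + 2L)
      img <- a$image; lab <- a$labels
    }
    id <- sprintf("scene_%04d", i)
    png::writePNG(img, file.path(dir, "images", paste0(id, ".png")))
    write_yolo_labels(lab, file.path(dir, "labels", paste0(id, ".txt")))
    entries[[i]] <- list(id = id, split = membership[i], seed = sp$seed,
                         n_objects = nrow(lab), augment = aug,
                         resolution = spec$image_size)
  }
  manifest <- list(spec = unclass(spec), seed = seed, n_images = n_images,
                   split = split, entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$dir <- dir
  invisible(manifest)
}
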