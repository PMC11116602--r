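test_that("scene generation is deterministic and labels are tight", {
  sp <- scene_spec(image_size = 128, n_objects = c(5L, 5L),
                   object_size = c(8, 16), size_mode = "side", seed = 7)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_equal(nrow(a$labels), 5)
  expect_true(all(a$image >= 0 & a$image <= 1))
  boxes <- yolo_to_corner(a$labels, 128, 128)
  for (k in seq_len(5)) {
    px <- a$masks[[k]]
    centroid <- colMeans(px)  # (y, x)
    expect_gte(centroid["x"], boxes$x1[k]); expect_lte(centroid["x"], boxes$x2[k])
    expect_gte(centroid["y"], boxes$y1[k]); expect_lte(centroid["y"], boxes$y2[k])
    # tightness: blob pixels fill at least 60% of the label box
    box_area <- (boxes$x2[k] - boxes$x1[k]) * (boxes$y2[k] - boxes$y1[k])
    expect_gte(nrow(px) / box_area, 0.6 - 1e-9)
  }
})

test_that("scene generation rejects impossible placements", {
  sp <- scene_spec(image_size = 16, n_objects = c(1L, 1L),
                   object_size = c(400, 450), size_mode = "side", seed = 1)
  expect_error(generate_scene(sp), "too small")
  expect_error(scene_spec(overlap_prob = 2), "overlap_prob")
})

test_that("tiling remaps labels and drops sub-20% fragments", {
  sp <- scene_spec(image_size = 256, n_objects = c(12L, 12L),
                   object_size = c(10, 20), size_mode = "side", seed = 13)
  sc <- generate_scene(sp)
  tiles <- suppressMessages(tile_image(sc$image, sc$labels, tile = 128))
  expect_length(tiles, 4)
  expect_equal(dim(tiles[[1]]$image), c(128, 128, 3))
  # count conservation: every original box appears in tiles unless clipped
  # below the retention rule
  n_in_tiles <- sum(vapply(tiles, function(t) nrow(t$labels), integer(1)))
  boxes <- yolo_to_corner(sc$labels, 256, 256)
  expected <- 0L
  for (i in seq_len(nrow(boxes))) {
    for (t in tiles) {
      ox <- t$origin["x"]; oy <- t$origin["y"]
      ix <- max(0, min(boxes$x2[i], ox + 128) - max(boxes$x1[i], ox))
      iy <- max(0, min(boxes$y2[i], oy + 128) - max(boxes$y1[i], oy))
      frac <- ix * iy / ((boxes$x2[i] - boxes$x1[i]) * (boxes$y2[i] - boxes$y1[i]))
      if (frac >= 0.2) expected <- expected + 1L
    }
  }
  expect_equal(n_in_tiles, expected)
  expect_error(tile_image(sc$image, sc$labels, tile = 512), "exceeds")
})

test_that("a box fully inside one tile lands in exactly that tile, shifted", {
  img <- array(0.5, c(200, 200, 3))
  lab <- corner_to_yolo(data.frame(x1 = 110, y1 = 120, x2 = 130, y2 = 140), 200, 200)
  tiles <- tile_image(img, lab, tile = 100)
  counts <- vapply(tiles, function(t) nrow(t$labels), integer(1))
  expect_equal(sum(counts), 1)
  hit <- tiles[[which(counts == 1)]]
  expect_equal(hit$origin, c(x = 100, y = 100))
  back <- yolo_to_corner(hit$labels, 100, 100)
  expect_equal(as.numeric(back[1, 1:4]), c(10, 20, 30, 40))
})

test_that("a box straddling two tiles appears clipped in both", {
  img <- array(0.5, c(100, 200, 3))
  lab <- corner_to_yolo(data.frame(x1 = 80, y1 = 40, x2 = 120, y2 = 60), 200, 100)
  tiles <- tile_image(img, lab, tile = 100)
  expect_length(tiles, 2)
  expect_equal(vapply(tiles, function(t) nrow(t$labels), integer(1)), c(1L, 1L))
  left <- yolo_to_corner(tiles[[1]]$labels, 100, 100)
  expect_equal(as.numeric(left[1, 1:4]), c(80, 40, 100, 60))
})

test_that("Laplacian sharpness ranks blur correctly", {
  expect_equal(laplacian_sharpness(array(0.5, c(32, 32, 3))), 0)
  checker <- array(rep(c(0, 1), length.out = 32 * 32), c(32, 32, 1))[, , 1]
  gray <- matrix(0.5, 32, 32)
  expect_gt(laplacian_sharpness(checker), laplacian_sharpness(gray))
  for (seed in 1:5) {
    sc <- tiny_scene(seed, size = 96)
    blurred <- aperm(as.array(EBImage::gblur(
      EBImage::Image(aperm(sc$image, c(2, 1, 3)), colormode = "Color"),
      sigma = 2)), c(2, 1, 3))
    expect_lt(laplacian_sharpness(blurred), laplacian_sharpness(sc$image))
  }
  expect_error(laplacian_sharpness(matrix(0, 1, 1)), "too small")
})

test_that("blur filtering keeps sharp images at the default quantile", {
  imgs <- lapply(1:8, function(s) tiny_scene(s, size = 64)$image)
  blurred <- lapply(imgs[1:2], function(im)
    aperm(as.array(EBImage::gblur(EBImage::Image(aperm(im, c(2, 1, 3)),
                                                 colormode = "Color"),
                                  sigma = 3)), c(2, 1, 3)))
  batch <- c(blurred, imgs[3:8])
  kept <- suppressMessages(filter_blurred(batch))
  expect_false(any(attr(kept, "kept")[1:2]))
  expect_length(kept, 6)
  kept2 <- suppressMessages(filter_blurred(batch, thr = 0))
  expect_length(kept2, 8)
})

test_that("geometric augmentations transform labels consistently", {
  sc <- tiny_scene(3, size = 96)
  r90 <- augment(sc$image, sc$labels, "rot90")
  expect_equal(r90$labels$cx, sc$labels$cy)
  expect_equal(r90$labels$cy, 1 - sc$labels$cx)
  expect_equal(r90$labels$w, sc$labels$h)
  # four quarter-turns are the identity on image and labels
  cur <- list(image = sc$image, labels = sc$labels)
  for (i in 1:4) cur <- augment(cur$image, cur$labels, "rot90")
  expect_equal(cur$image, sc$image)
  expect_equal(cur$labels, sc$labels, tolerance = 1e-9)
  # rot180 equals rot90 twice
  twice <- augment(r90$image, r90$labels, "rot90")
  once <- augment(sc$image, sc$labels, "rot180")
  expect_equal(twice$image, once$image)
  expect_equal(twice$labels, once$labels, tolerance = 1e-12)
  hf <- augment(sc$image, sc$labels, "hflip")
  expect_equal(hf$labels$cx, 1 - sc$labels$cx)
  expect_equal(hf$labels$cy, sc$labels$cy)
  # box areas preserved under all geometric ops
  for (op in c("rot90", "rot180", "hflip")) {
    out <- augment(sc$image, sc$labels, op)
    expect_equal(sort(out$labels$w * out$labels$h),
                 sort(sc$labels$w * sc$labels$h), tolerance = 1e-12)
    expect_true(all(out$labels$cx >= 0 & out$labels$cx <= 1))
  }
})

test_that("photometric augmentations leave labels untouched and are seeded", {
  sc <- tiny_scene(5, size = 64)
  for (op in c("brighten", "darken", "salt_pepper", "gaussian_noise")) {
    out <- augment(sc$image, sc$labels, op, seed = 9)
    expect_identical(out$labels, sc$labels)
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
  a <- augment(sc$image, sc$labels, "gaussian_noise", seed = 4)
  b <- augment(sc$image, sc$labels, "gaussian_noise", seed = 4)
  expect_identical(a$image, b$image)
  expect_error(augment(sc$image, sc$labels, "sharpen"), "unknown")
  bright <- augment(sc$image, sc$labels, "brighten")
  dark <- augment(sc$image, sc$labels, "darken")
  expect_gte(mean(bright$image), mean(sc$image))
  expect_lte(mean(dark$image), mean(sc$image))
})

test_that("multi-resolution resampling tags sizes and keeps labels", {
  sc <- tiny_scene(6, size = 64)
  out <- resample_multires(sc$image, sc$labels, sizes = c(100, 160, 320, 640))
  expect_equal(vapply(out, `[[`, numeric(1), "size"), c(100, 160, 320, 640))
  for (rec in out) {
    expect_identical(rec$labels, sc$labels)
    expect_equal(dim(rec$image)[1:2], c(rec$size, rec$size))
  }
  # corner boxes at 320 are exactly half the 640-frame boxes
  b640 <- yolo_to_corner(out[[4]]$labels, 640, 640)
  b320 <- yolo_to_corner(out[[3]]$labels, 320, 320)
  expect_equal(as.matrix(b320[, 1:4]), as.matrix(b640[, 1:4]) / 2,
               ignore_attr = TRUE)
})

test_that("dataset building writes a reproducible 7:2:1 split", {
  dir1 <- withr::local_tempdir()
  sp <- scene_spec(image_size = 64, n_objects = c(3L, 5L),
                   object_size = c(6, 12), size_mode = "side", seed = 0)
  man <- build_dataset(sp, n_images = 10, seed = 5, dir = dir1)
  splits <- vapply(man$entries, `[[`, character(1), "split")
  expect_equal(unname(table(splits)[c("train", "val", "test")]),
               c(7L, 2L, 1L), ignore_attr = TRUE)
  ids <- vapply(man$entries, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(list.files(file.path(dir1, "images")), 10)
  expect_length(list.files(file.path(dir1, "labels")), 10)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # same seed reproduces membership and content
  dir2 <- withr::local_tempdir()
  man2 <- build_dataset(sp, n_images = 10, seed = 5, dir = dir2)
  expect_equal(vapply(man2$entries, `[[`, character(1), "split"), splits)
  img1 <- png::readPNG(file.path(dir1, "images", "scene_0001.png"))
  img2 <- png::readPNG(file.path(dir2, "images", "scene_0001.png"))
  expect_identical(img1, img2)
  expect_error(build_dataset(sp, n_images = 5, seed = 1,
                             dir = withr::local_tempdir()), "split")
})
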