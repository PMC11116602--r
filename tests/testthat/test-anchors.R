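make_wh <- function(n, wmin = 5, wmax = 50, seed = 1) {
  with_seed <- get("with_seed", asNamespace("microdet"))
  with_seed(seed, cbind(w = runif(n, wmin, wmax), h = runif(n, wmin, wmax)))
}

test_that("size stratification splits by sqrt(w*h) quantiles", {
  wh <- cbind(w = c(1, 2, 3, 4), h = c(1, 2, 3, 4))  # sizes 1..4
  g <- stratify_by_size(wh, 4)
  expect_length(g$groups, 4)
  expect_equal(vapply(g$groups, nrow, integer(1)), rep(1L, 4))
  expect_equal(unname(g$groups[[1]][1, "w"]), 1)
  expect_equal(unname(g$groups[[4]][1, "h"]), 4)

  set.seed(2)
  s <- runif(100, 5, 50)
  wh <- cbind(w = s, h = s)  # sqrt(w*h) = s
  g <- stratify_by_size(wh, 4)
  # sort-and-split oracle: boundaries are the 25/50/75 empirical quantiles
  expect_equal(g$boundaries, unname(quantile(s, c(0.25, 0.5, 0.75), type = 1)))
  expect_equal(vapply(g$groups, nrow, integer(1)), rep(25L, 4))
  sizes <- lapply(g$groups, function(m) sqrt(m[, "w"] * m[, "h"]))
  expect_lte(max(sizes[[1]]), min(sizes[[2]]))
  expect_lte(max(sizes[[2]]), min(sizes[[3]]))
  expect_lte(max(sizes[[3]]), min(sizes[[4]]))
})

test_that("stratification edge cases: single group, too few boxes, ties", {
  wh <- make_wh(10)
  g1 <- stratify_by_size(wh, 1)
  expect_length(g1$groups, 1)
  expect_equal(nrow(g1$groups[[1]]), 10)
  expect_length(g1$boundaries, 0)
  expect_error(stratify_by_size(wh[1:3, ], 4), "at least 4")
  tied <- cbind(w = rep(7, 20), h = rep(7, 20))
  expect_error(stratify_by_size(tied, 4), "tied size value 7")
})

test_that("stratification is invariant to input order", {
  wh <- make_wh(53, seed = 9)
  g1 <- stratify_by_size(wh, 4)
  g2 <- stratify_by_size(wh[rev(seq_len(nrow(wh))), ], 4)
  expect_equal(g1$boundaries, g2$boundaries)
  for (i in 1:4) expect_equal(g1$groups[[i]], g2$groups[[i]])
})

test_that("IoU k-means: trivial optima and two-mode recovery", {
  km <- kmeans_iou(cbind(w = 12, h = 20), K = 1, seed = 1)
  expect_equal(unname(km$centers[1, ]), c(12, 20))
  expect_equal(km$objective, 0)

  wh <- make_wh(5, seed = 4)
  km <- kmeans_iou(wh, K = 5, seed = 2)
  expect_equal(km$objective, 0, tolerance = 1e-12)

  two <- rbind(matrix(10, 5, 2), matrix(100, 5, 2))
  colnames(two) <- c("w", "h")
  km <- kmeans_iou(two, K = 2, seed = 3)
  expect_equal(km$objective, 0)
  expect_equal(unname(km$centers), rbind(c(10, 10), c(100, 100)))
  # exhaustive enumeration of all 2-partitions confirms the global optimum
  oracle <- kmeans_exhaustive(unique(two), 2)
  expect_equal(km$objective, oracle$objective, tolerance = 1e-12)
})

test_that("IoU k-means objective is non-increasing and locally optimal", {
  for (seed in 1:10) {
    wh <- make_wh(40, seed = 100 + seed)
    km <- kmeans_iou(wh, K = 3, seed = seed)
    expect_true(all(diff(km$trace) <= 1e-9))
    # no single-box reassignment lowers the objective
    d <- 1 - wh_iou(wh, km$centers)
    own <- d[cbind(seq_len(nrow(wh)), km$assignment)]
    expect_true(all(own <= apply(d, 1, min) + 1e-9))
  }
})

test_that("K exceeding the number of distinct pairs errors", {
  wh <- rbind(c(10, 10), c(10, 10), c(20, 20))
  colnames(wh) <- c("w", "h")
  expect_error(kmeans_iou(wh, K = 3, seed = 1), "distinct")
})

test_that("IoU k-means agrees with Euclidean k-means when aspect is fixed", {
  # all boxes square: IoU distance is monotone in |log size| difference, so
  # the optimal two-cluster split matches the Euclidean one on a separated
  # dataset
  set.seed(8)
  s <- c(runif(15, 8, 12), runif(15, 60, 80))
  wh <- cbind(w = s, h = s)
  km <- kmeans_iou(wh, K = 2, seed = 1)
  ek <- kmeans(cbind(s, s), centers = 2, nstart = 5)
  split_iou <- split(seq_along(s), km$assignment)
  split_euc <- split(seq_along(s), ek$cluster)
  norm <- function(sp) unname(sp[order(vapply(sp, min, numeric(1)))])
  expect_equal(norm(split_iou), norm(split_euc))
})

test_that("random and k-means++ initialization both converge, seeded", {
  wh <- make_wh(30, seed = 21)
  a <- kmeans_iou(wh, K = 3, seed = 5, init = "random")
  b <- kmeans_iou(wh, K = 3, seed = 5, init = "random")
  expect_identical(a$centers, b$centers)
  c1 <- kmeans_iou(wh, K = 3, seed = 5, init = "kmeanspp")
  expect_true(all(diff(c1$trace) <= 1e-9))
})

test_that("stratified preset maps small sizes to fine strides", {
  # 4 groups of 3 distinct boxes each: K = N reproduces the boxes
  wh <- cbind(w = c(4, 5, 6, 14, 15, 16, 40, 42, 44, 90, 95, 100),
              h = c(4, 5, 6, 14, 15, 16, 40, 42, 44, 90, 95, 100))
  g <- stratify_by_size(wh, 4)
  p <- build_anchor_preset(g, anchors_per_level = 3, seed = 1)
  expect_equal(vapply(p$levels, `[[`, integer(1), "stride"), c(4L, 8L, 16L, 32L))
  expect_equal(p$provenance, "kmeans")
  expect_equal(unname(p$levels[[1]]$anchors[, 1]), c(4, 5, 6))
  expect_equal(unname(p$levels[[4]]$anchors[, 2]), c(90, 95, 100))
  # deterministic given (groups, seed)
  p2 <- build_anchor_preset(g, anchors_per_level = 3, seed = 1)
  expect_identical(p, p2)
})

test_that("anchors recover the modes of separated log-normal size groups", {
  set.seed(31)
  modes <- c(6, 16, 40, 100)
  wh <- do.call(rbind, lapply(modes, function(m) {
    s <- m * exp(rnorm(60, sd = 0.08))
    cbind(w = s, h = s * exp(rnorm(60, sd = 0.05)))
  }))
  p <- build_anchor_preset(stratify_by_size(wh, 4), anchors_per_level = 3, seed = 2)
  for (i in 1:4) {
    mean_size <- mean(sqrt(p$levels[[i]]$anchors[, 1] * p$levels[[i]]$anchors[, 2]))
    expect_lt(abs(mean_size - modes[i]) / modes[i], 0.10)
  }
})

test_that("the default preset reproduces the stock anchors", {
  p <- default_anchor_preset()
  expect_equal(p$provenance, "default")
  strides <- vapply(p$levels, `[[`, integer(1), "stride")
  expect_equal(strides, c(4L, 8L, 16L, 32L))
  by_stride <- function(s) unname(p$levels[[match(s, strides)]]$anchors)
  expect_equal(by_stride(8), rbind(c(10, 13), c(16, 30), c(33, 23)))
  expect_equal(by_stride(16), rbind(c(30, 61), c(62, 45), c(59, 119)))
  expect_equal(by_stride(32), rbind(c(116, 90), c(156, 198), c(373, 326)))
  expect_true(all(vapply(p$levels, function(l) nrow(l$anchors), integer(1)) == 3L))
})

test_that("anchor files round-trip", {
  p <- default_anchor_preset()
  f <- withr::local_tempfile(fileext = ".txt")
  write_anchor_file(p, f)
  q <- read_anchor_file(f, provenance = "default")
  expect_equal(q$levels, p$levels, tolerance = 1e-12)
  expect_error(subset_preset(p, c(8, 64)), "does not cover")
  s <- subset_preset(p, c(8, 16, 32))
  expect_length(s$levels, 3)
})
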