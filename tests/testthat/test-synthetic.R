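test_that("shape generators satisfy their analytic surface identities", {
  # sphere at zero jitter: every point at radius 1
  s <- make_shape(shape_spec("sphere", n = 200, sigma = 0, seed = 1))
  expect_equal(sqrt(rowSums(s$coords^2)), rep(1, 200), tolerance = 1e-12)
  expect_identical(s$cloud_label, 0L)
  # cube: every point's max |coordinate| equals the half-side
  cu <- make_shape(shape_spec("cube", n = 200, sigma = 0, seed = 2))
  expect_equal(apply(abs(cu$coords), 1, max), rep(1 / sqrt(3), 200),
               tolerance = 1e-12)
  # torus: tube-center distance equals the minor radius
  to <- make_shape(shape_spec("torus", n = 200, sigma = 0, seed = 3))
  rho <- sqrt(to$coords[, 1]^2 + to$coords[, 2]^2)
  expect_equal(sqrt((rho - 0.75)^2 + to$coords[, 3]^2), rep(0.25, 200),
               tolerance = 1e-12)
  # all families fit inside the unit sphere before jitter
  for (f in c("sphere", "cube", "torus", "cylinder", "cone")) {
    x <- make_shape(shape_spec(f, n = 100, sigma = 0, seed = 4))
    expect_lte(max(rowSums(x$coords^2)), 1 + 1e-12)
  }
  expect_error(shape_spec("dodecahedron"), "unknown family")
})

test_that("shape generation is a pure function of the seed", {
  a <- make_shape(shape_spec("cylinder", n = 64, sigma = 0.01, seed = 42))
  b <- make_shape(shape_spec("cylinder", n = 64, sigma = 0.01, seed = 42))
  expect_identical(a, b)
  c <- make_shape(shape_spec("cylinder", n = 64, sigma = 0.01, seed = 43))
  expect_false(identical(a$coords, c$coords))
})

test_that("part labels separate at the analytic boundaries", {
  cy <- make_part_labeled_shape(shape_spec("cylinder", n = 300, sigma = 0,
                                           seed = 5))
  h <- sqrt(3) / 2
  expect_true(all(abs(cy$coords[cy$point_labels == 0L, 3]) < h))
  expect_equal(cy$coords[cy$point_labels == 1L, 3],
               rep(h, sum(cy$point_labels == 1L)))
  expect_equal(cy$coords[cy$point_labels == 2L, 3],
               rep(-h, sum(cy$point_labels == 2L)))
  co <- make_part_labeled_shape(shape_spec("cone", n = 300, sigma = 0,
                                           seed = 6))
  expect_equal(co$coords[co$point_labels == 1L, 3],
               rep(-0.8, sum(co$point_labels == 1L)))
  # self-comparison scores a perfect mIoU
  r <- part_miou(cy$point_labels, cy$point_labels, categories = 0L,
                 part_sets = shape_part_sets())
  expect_equal(r$instance_miou, 100)
  expect_error(make_part_labeled_shape(shape_spec("sphere")),
               "no part decomposition")
})

test_that("volume sampling returns exactly n density-weighted points", {
  # single blob: the sample mean stays within 3 sigma / sqrt(n) of the center
  ctr <- c(0.2, -0.1, 0)
  width <- 0.15
  n <- 2000
  tol <- 3 * width / sqrt(n)
  for (seed in 1:10) {
    sp <- volume_spec(matrix(ctr, 1), widths = width, n = n, seed = seed)
    pc <- sample_volume(sp)
    expect_identical(n_points(pc), as.integer(n))
    expect_true(all(abs(colMeans(pc$coords) - ctr) < tol))
  }
  # two far-separated equal blobs: per-blob counts within binomial 99% bounds
  sp2 <- volume_spec(rbind(c(-0.6, 0, 0), c(0.6, 0, 0)), widths = 0.1,
                     n = 1000, seed = 77)
  pc2 <- sample_volume(sp2)
  n_left <- sum(pc2$coords[, 1] < 0)
  expect_gte(n_left, qbinom(0.005, 1000, 0.5))
  expect_lte(n_left, qbinom(0.995, 1000, 0.5))
  # degenerate density is rejected
  expect_error(volume_spec(matrix(c(5, 5, 5), 1), widths = 1e-4, n = 10),
               "zero total mass")
  expect_error(volume_spec(matrix(0, 1, 3), widths = 0.1, weights = -1),
               "non-negative")
})

test_that("dataset generation is stratified, disjoint and reproducible", {
  ds <- make_dataset(3, 10, split = 0.8, seed = 7, n = 32)
  expect_length(ds$train, 24)
  expect_length(ds$test, 6)
  expect_equal(as.numeric(table(pointattn:::.cloud_labels(ds$train))),
               rep(8, 3))
  expect_equal(as.numeric(table(pointattn:::.cloud_labels(ds$test))),
               rep(2, 3))
  ds2 <- make_dataset(3, 10, split = 0.8, seed = 7, n = 32)
  expect_identical(ds, ds2)
  expect_error(make_dataset(3, 10, split = 1.2, seed = 1), "split")
  expect_error(make_dataset(3, 1, split = 0.8, seed = 1), "at least 2")
  expect_error(make_dataset(9, 4, seed = 1), "shape classes")
  # volume mode carries labels and fixed-size clouds
  dv <- make_dataset(2, 4, split = 0.5, seed = 8, mode = "volumes", n = 64,
                     dims = 16)
  expect_length(dv$train, 4)
  expect_setequal(pointattn:::.cloud_labels(dv$train), 0:1)
  expect_true(all(vapply(dv$test, n_points, integer(1)) == 64L))
})

test_that("class-conditional geometry is separable by a nearest-centroid baseline", {
  ds <- make_dataset(4, 20, split = 0.5, seed = 9, n = 128)
  descr <- function(p) {
    r <- sqrt(rowSums(p$coords^2))
    c(mean(r), stats::sd(r), apply(abs(p$coords), 2, max),
      stats::sd(p$coords[, 3]))
  }
  tr <- t(vapply(ds$train, descr, numeric(6)))
  te <- t(vapply(ds$test, descr, numeric(6)))
  ytr <- pointattn:::.cloud_labels(ds$train)
  yte <- pointattn:::.cloud_labels(ds$test)
  cents <- apply(tr, 2, tapply, ytr, mean)
  pred <- apply(te, 1, function(v)
    as.integer(rownames(cents)[which.min(rowSums((cents - matrix(v, nrow(cents), ncol(cents), byrow = TRUE))^2))]))
  acc <- mean(pred == yte)
  expect_gt(acc, 0.5)  # far above the 0.25 chance level
})
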