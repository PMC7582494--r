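test_that("kNN grouping matches the brute-force oracle on random clouds", {
  set.seed(11)
  for (i in 1:30) {
    N <- sample(4:48, 1)
    k <- sample(seq_len(min(N, 12)), 1)
    X <- random_cloud(N)
    expect_identical(knn_group(X, k)$indices, brute_knn(X, k))
  }
})

test_that("kNN grouping handles the worked examples", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
  expect_identical(knn_group(pts, 2)$indices,
                   matrix(c(1L, 2L, 3L, 2L, 1L, 2L), 3, 2))
  # k = 1: each group is the center alone
  X <- random_cloud(7, seed = 1)
  expect_identical(knn_group(X, 1)$indices, matrix(1:7, 7, 1))
  # unit-square corners, k = 3: edge-adjacent corners, diagonal excluded
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  idx <- knn_group(sq, 3)$indices
  expect_identical(idx[, 1], 1:4)
  expect_identical(sort(idx[1, 2:3]), c(2L, 4L))  # corner 1: not corner 3
  expect_identical(sort(idx[2, 2:3]), c(1L, 3L))
  expect_identical(sort(idx[3, 2:3]), c(2L, 4L))
  expect_identical(sort(idx[4, 2:3]), c(1L, 3L))
})

test_that("kNN grouping validates its inputs", {
  X <- random_cloud(5, seed = 2)
  expect_error(knn_group(X, 6), "group size exceeds point count")
  X[2, 1] <- NA
  expect_error(knn_group(X, 2), "finite")
})

test_that("kNN grouping is permutation-equivariant and similarity-invariant", {
  set.seed(21)
  for (i in 1:10) {
    N <- sample(8:40, 1)
    k <- sample(2:6, 1)
    X <- random_cloud(N)
    idx <- knn_group(X, k)$indices
    # permuting the points permutes groups and relabels indices consistently
    perm <- sample(N)
    idx_p <- knn_group(X[perm, ], k)$indices
    relabel <- match(seq_len(N), perm)
    expect_identical(idx_p, matrix(relabel[idx[perm, ]], N, k))
    # global translation and uniform positive scaling keep the neighbor sets
    expect_identical(knn_group(X * 2.5, k)$indices, idx)
    shift <- matrix(c(3, -1, 7), N, 3, byrow = TRUE)
    expect_identical(knn_group(X + shift, k)$indices, idx)
  }
})

test_that("edge features stack (x_j - x_i, x_i) with a zero self-entry", {
  X <- random_cloud(12, seed = 3)
  nbr <- knn_group(X, 4)
  ef <- edge_features(X, nbr)
  expect_equal(dim(ef$values), c(12, 4, 6))
  # self entry: difference half zero, absolute half = x_i
  expect_equal(max(abs(ef$values[, 1, 1:3])), 0)
  expect_equal(ef$values[, 1, 4:6], X, ignore_attr = TRUE)
  # entry (i, j): matches manual construction
  i <- 5; j <- 3
  xj <- X[nbr$indices[i, j], ]
  expect_equal(as.numeric(ef$values[i, j, ]), c(xj - X[i, ], X[i, ]))
  # translation moves only the absolute half
  shift <- matrix(c(1, 2, -3), 12, 3, byrow = TRUE)
  ef2 <- edge_features(X + shift, knn_group(X + shift, 4))
  expect_equal(ef2$values[, , 1:3], ef$values[, , 1:3])
  exp_abs <- ef$values[, , 4:6]
  for (j in 1:4) exp_abs[, j, ] <- exp_abs[, j, ] + shift
  expect_equal(ef2$values[, , 4:6], exp_abs)
})

test_that("geometric descriptor carries 10 channels including the distance", {
  X <- random_cloud(10, seed = 4)
  nbr <- knn_group(X, 3)
  gd <- geometric_descriptor(X, nbr)
  expect_equal(dim(gd$values)[3], 10)
  # self entry: x_i = x_j, zero difference and zero distance
  expect_equal(gd$values[, 1, 1:3], gd$values[, 1, 4:6])
  expect_equal(max(abs(gd$values[, 1, 7:10])), 0)
  # 3-4-5 triangle distance
  Y <- matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE)
  gd2 <- geometric_descriptor(Y, knn_group(Y, 2))
  expect_equal(gd2$values[1, 2, 10], 5)
  expect_error(geometric_descriptor(cbind(X, 0), nbr), "3-D")
})

test_that("spatial descriptor is the geometric descriptor minus distance", {
  X <- random_cloud(9, seed = 5)
  nbr <- knn_group(X, 4)
  sd9 <- spatial_descriptor(X, nbr)
  gd <- geometric_descriptor(X, nbr)
  expect_equal(dim(sd9$values)[3], 9)
  expect_equal(sd9$values, gd$values[, , 1:9])
  expect_equal(max(abs(sd9$values[, 1, 7:9])), 0)
})
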