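test_that("channel gate scalars live in (0,1) and gate per channel", {
  set.seed(31)
  X <- matrix(rnorm(20 * 6), 20, 6)
  g <- channel_gate(6, dims = "point", seed = 1)
  out <- se_gate(X, g)
  s <- attr(out, "gate_scalars")
  expect_true(all(s > 0 & s < 1))
  # the output/input ratio per channel is constant across positions
  ratio <- out / X
  expect_equal(apply(ratio, 2, max), apply(ratio, 2, min))
  expect_equal(ratio[1, ], s, ignore_attr = TRUE)
  # zero input stays zero
  expect_equal(se_gate(matrix(0, 5, 6), g), matrix(0, 5, 6),
               ignore_attr = TRUE)
  expect_error(se_gate(matrix(0, 5, 4), g), "channel mismatch")
})

test_that("zeroed excitation gives exactly half-gating", {
  X <- matrix(rnorm(8 * 3 * 5), 24, 5)
  gf <- pointattn:::.grouped_feature(pointattn:::.flat_to_array(X, 8, 3))
  g0 <- channel_gate(5, init = "zero")
  out <- se_gate(gf, g0)
  expect_equal(attr(out, "gate_scalars"), rep(0.5, 5))
  expect_equal(out$values, gf$values / 2)
})

test_that("channel-weighted edge convolution with identity gate equals the plain edge-convolution oracle", {
  set.seed(32)
  for (i in 1:10) {
    N <- sample(6:20, 1)
    k <- sample(seq_len(min(N, 6)), 1)
    C <- sample(2:5, 1)
    X <- random_cloud(N)
    p <- layer_params(3, C, use_se = FALSE)
    got <- cw_edgeconv(X, p, k)
    want <- naive_edgeconv(X, p$dense$W, p$bn$gamma, p$bn$beta, k)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("channel-weighted edge convolution is permutation-equivariant", {
  set.seed(33)
  X <- random_cloud(15)
  p <- layer_params(3, 4, seed = 2)
  out <- cw_edgeconv(X, p, 5)
  perm <- sample(15)
  expect_equal(cw_edgeconv(X[perm, ], p, 5), out[perm, ], tolerance = 1e-12)
})

test_that("first-layer variant returns the shared 10-channel descriptor", {
  X <- random_cloud(12, seed = 6)
  p <- layer_params(3, 4, seed = 3)
  res <- cw_edgeconv_pp(X, p, 4)
  expect_equal(dim(res$descriptor$values)[3], 10)
  expect_equal(res$features, cw_edgeconv(X, p, 4, nbr = res$nbr))
  expect_identical(res$nbr$indices, knn_group(X, 4)$indices)
})

test_that("global feature concatenates layer outputs and half-gates under zeroed excitation", {
  set.seed(34)
  outs <- list(matrix(rnorm(10 * 4), 10, 4), matrix(rnorm(10 * 6), 10, 6))
  gp <- global_params(10, 8, seed = 4)
  g <- global_feature(outs, gp)
  expect_equal(dim(g), c(10L, 8L))
  gp0 <- gp
  gp0$se$W1[] <- 0; gp0$se$b1[] <- 0; gp0$se$W2[] <- 0; gp0$se$b2[] <- 0
  gp_no <- gp; gp_no$se <- NULL
  expect_equal(global_feature(outs, gp0), global_feature(outs, gp_no) / 2)
  expect_error(global_feature(list(outs[[1]], outs[[2]][1:5, ]), gp),
               "disagree")
  expect_error(global_feature(outs[[1]], gp), "channels")
})

test_that("soft attention mask lies strictly in (0,1) and is group-symmetric", {
  set.seed(35)
  X <- random_cloud(20)
  nbr <- knn_group(X, 5)
  desc <- geometric_descriptor(X, nbr)
  mp <- mask_params(hidden = 8, seed = 5)
  m <- global_attention_mask(desc, mp)
  expect_s3_class(m, "attention_mask")
  expect_identical(m$mode, "soft")
  expect_true(all(m$weights > 0 & m$weights < 1))
  # permuting the k entries within each group leaves the weights unchanged
  desc_p <- desc
  desc_p$values <- desc_p$values[, c(3, 1, 5, 2, 4), ]
  expect_equal(global_attention_mask(desc_p, mp)$weights, m$weights)
  # zeroed final stage: every response is sigmoid(0) = 0.5 exactly
  mp0 <- mask_params(hidden = 8, zero_final = TRUE, seed = 5)
  expect_equal(global_attention_mask(desc, mp0)$weights, rep(0.5, 20))
  expect_error(global_attention_mask(spatial_descriptor(X, nbr), mp),
               "channels")
})

test_that("hard attention mask thresholds inclusively at 0.5 and is monotone in the final bias", {
  set.seed(36)
  X <- random_cloud(18)
  desc <- geometric_descriptor(X, knn_group(X, 4))
  # zeroed final stage: mean response exactly 0.5 -> all ones (inclusive)
  mp0 <- mask_params(hidden = 8, zero_final = TRUE, seed = 6)
  h0 <- hard_attention_mask(desc, mp0)
  expect_identical(h0$mode, "hard")
  expect_equal(h0$weights, rep(1, 18))
  mp <- mask_params(hidden = 8, seed = 6)
  w <- hard_attention_mask(desc, mp)$weights
  expect_true(all(w %in% c(0, 1)))
  # raising the final bias never flips a kept point to dropped
  for (db in c(0.3, 1, 3)) {
    mp2 <- mp
    mp2$d2$b <- mp$d2$b + db
    w2 <- hard_attention_mask(desc, mp2)$weights
    expect_true(all(w2 >= w))
  }
})

test_that("spatial-attention edge convolution contracts a plain edge convolution", {
  set.seed(37)
  X <- random_cloud(16)
  sp <- sa_params(3, 5, hidden = 8, seed = 7)
  out <- spatial_attention_edgeconv(X, X, sp, 4)
  w <- attr(out, "mask")
  expect_true(all(w > 0 & w < 1))
  # the mask branch consumes the 9-channel distance-free descriptor
  expect_identical(sp$mask$in_channels, 9L)
  # saturating the mask sigmoid recovers the plain edge convolution, which
  # the identity-gate layer oracle reproduces
  sp_sat <- sp
  sp_sat$mask$d2$W[] <- 0
  sp_sat$mask$d2$b <- 1e4
  ec <- naive_edgeconv(X, sp$dense$W, sp$bn$gamma, sp$bn$beta, 4)
  expect_equal(spatial_attention_edgeconv(X, X, sp_sat, 4), ec,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(out, ec * w, ignore_attr = TRUE)
  expect_true(all(abs(out) <= abs(ec) + 1e-12))
})

test_that("mask application broadcasts, zeroes dropped points and clips negatives", {
  g <- matrix(c(1, -2, 3, 4, -5, 6), 3, 2)
  m <- structure(list(weights = c(1, 0, 1), mode = "hard"),
                 class = "attention_mask")
  gm <- apply_mask(g, m)
  expect_equal(gm[2, ], c(0, 0))
  expect_equal(gm[1, ], c(1, 4))
  expect_equal(gm[3, ], c(3, 6))
  # non-negative feature with an all-ones mask is unchanged
  gp <- abs(g)
  expect_equal(apply_mask(gp, rep(1, 3)), gp)
  # a negative entry under mask weight 1 is clipped by the ReLU
  expect_equal(apply_mask(g, rep(1, 3))[2, 1], 0)
  expect_error(apply_mask(g, c(1, 1)), "does not match")
})
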