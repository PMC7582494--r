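test_that("default classifier matches the reference dimensions", {
  cfg <- classifier_config(n_classes = 40)
  expect_identical(cfg$layers, c(64L, 64L, 128L, 256L))
  expect_identical(cfg$k, 20L)
  model <- init_classifier(cfg, seed = 1)
  # pooled max&avg vector is 2 * 1024 = 2048 wide at defaults
  expect_identical(nrow(model$params$head$hidden[[1]]$dense$W), 2048L)
  # global feature consumes the 512-wide trunk concatenation
  expect_identical(dim(model$params$global$dense$W), c(512L, 1024L))
  # architecture determinism: the parameter count does not depend on the seed
  expect_identical(n_parameters(model),
                   n_parameters(init_classifier(cfg, seed = 99)))
  # same seed, same weights
  expect_identical(pointattn:::.flatten_params(model$params),
                   pointattn:::.flatten_params(init_classifier(cfg, seed = 1)$params))
})

test_that("an untrained classifier returns finite scores for every class", {
  model <- tiny_classifier(n_classes = 5)
  cloud <- point_cloud(random_cloud(30, seed = 8))
  scores <- classify_forward(cloud, model)
  expect_length(scores, 5)
  expect_true(all(is.finite(scores)))
  expect_error(classify_forward(point_cloud(random_cloud(3)), model),
               "group size exceeds point count")
})

test_that("classification is invariant and segmentation equivariant under point permutation", {
  set.seed(41)
  model <- tiny_classifier()
  seg <- tiny_segmenter()
  X <- random_cloud(24)
  scores <- classify_forward(X, model)
  oh <- c(1, 0)
  pts <- segment_forward(X, oh, seg)
  for (i in 1:3) {
    perm <- sample(24)
    expect_equal(classify_forward(X[perm, ], model), scores,
                 tolerance = 1e-8)
    expect_equal(segment_forward(X[perm, ], oh, seg), pts[perm, ],
                 tolerance = 1e-8)
  }
})

test_that("segmentation head handles the 16-category / 50-part configuration", {
  cfg <- segmenter_config(n_parts = 50, n_categories = 16,
                          layers = c(8L, 8L), k = 4L, global_width = 16L,
                          mask_hidden = 8L, seg_head = c(16L, 16L, 8L))
  model <- init_segmenter(cfg, seed = 2)
  X <- random_cloud(20, seed = 9)
  oh <- numeric(16); oh[3] <- 1
  out <- segment_forward(X, oh, model)
  expect_equal(dim(out), c(20L, 50L))
  expect_true(all(is.finite(out)))
  expect_error(segment_forward(X, rep(1, 16), model), "one-hot malformed")
  expect_error(segment_forward(X, oh[-1], model), "one-hot malformed")
})

test_that("disabling both attention mechanisms reduces the trunk to stacked plain edge convolutions", {
  set.seed(42)
  cfg <- classifier_config(n_classes = 3, layers = c(5L, 6L), k = 4L,
                           global_width = 8L, head = c(8L, 8L), dropout = 0,
                           use_se = FALSE, use_mask = FALSE,
                           graph = "features")
  model <- init_classifier(cfg, seed = 3)
  X <- random_cloud(14)
  tr <- pointattn:::.trunk_fw(model$params, cfg, X, 1L, 14L, training = TRUE)
  # layer-by-layer agreement with the independently coded oracle, the graph
  # recomputed in each layer's feature space
  p1 <- model$params$layers[[1]]
  x1 <- naive_edgeconv(X, p1$dense$W, p1$bn$gamma, p1$bn$beta, 4)
  p2 <- model$params$layers[[2]]
  x2 <- naive_edgeconv(x1, p2$dense$W, p2$bn$gamma, p2$bn$beta, 4)
  expect_equal(tr$cache$outs[[1]], x1, tolerance = 1e-10)
  expect_equal(tr$cache$outs[[2]], x2, tolerance = 1e-10)
  # the mask is identically one
  expect_equal(tr$w, rep(1, 14))
})

test_that("attention export is deterministic, in (0,1), and orientation-sensitive", {
  model <- tiny_classifier(seed = 11)
  cloud <- make_shape(shape_spec("cube", n = 40, sigma = 0, seed = 5))
  w <- export_attention(cloud, model)
  expect_length(w, 40)
  expect_true(all(w > 0 & w < 1))
  expect_identical(export_attention(cloud, model), w)
  rot <- perturb_cloud(cloud, "rotate", angle = 30, axis = "z")
  expect_false(isTRUE(all.equal(export_attention(rot, model), w)))
  m2 <- tiny_classifier(use_mask = FALSE)
  expect_error(export_attention(cloud, m2), "without the attention mask")
})

test_that("model checkpoints round-trip bit-exactly", {
  model <- tiny_classifier(seed = 13)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back, model)
  expect_identical(pointattn:::.flatten_params(back$params),
                   pointattn:::.flatten_params(model$params))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), "not a pointattn checkpoint")
})
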