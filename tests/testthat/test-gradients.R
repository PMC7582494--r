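# Central-difference validation of the hand-written backward passes.

test_that("classification gradients agree with central differences for every tensor", {
  set.seed(51)
  model <- tiny_classifier(dropout = 0)
  X <- rbind(random_cloud(8), random_cloud(8))
  labels <- c(0L, 2L)
  lossfun <- function(m)
    pointattn:::.class_loss_grads(m, X, 2L, 8L, labels, training = TRUE)$loss
  lg <- pointattn:::.class_loss_grads(model, X, 2L, 8L, labels,
                                      training = TRUE)
  worst <- fd_check(model, lossfun, lg$grads, max_per_tensor = 6)
  expect_lt(worst, 1e-4)
})

test_that("segmentation gradients agree with central differences", {
  set.seed(52)
  model <- tiny_segmenter()
  X <- rbind(random_cloud(8), random_cloud(8))
  oh <- diag(2)
  pl <- sample(0:4, 16, replace = TRUE)
  lossfun <- function(m)
    pointattn:::.seg_loss_grads(m, X, 2L, 8L, oh, pl, training = TRUE)$loss
  lg <- pointattn:::.seg_loss_grads(model, X, 2L, 8L, oh, pl,
                                    training = TRUE)
  worst <- fd_check(model, lossfun, lg$grads, max_per_tensor = 4)
  expect_lt(worst, 1e-4)
})

test_that("edge-convolution variants and pooling modes keep exact gradients", {
  set.seed(53)
  # plain ReLU, max-only pooling, no channel gates, dynamic-feature graph
  cfg <- classifier_config(n_classes = 3, layers = c(5L, 5L), k = 3L,
                           global_width = 8L, mask_hidden = 6L,
                           head = c(6L, 6L), dropout = 0, pooling = "max",
                           activation = "relu", use_se = FALSE,
                           graph = "coords", global_from = "last")
  model <- init_classifier(cfg, seed = 21)
  # four clouds: with fewer, the two-row head batch-norm pins its outputs
  # near +-1 and the trunk gradients sink below finite-difference resolution
  X <- do.call(rbind, lapply(1:4, function(i) random_cloud(7)))
  labels <- c(1L, 0L, 2L, 1L)
  lossfun <- function(m)
    pointattn:::.class_loss_grads(m, X, 4L, 7L, labels, training = TRUE)$loss
  lg <- pointattn:::.class_loss_grads(model, X, 4L, 7L, labels,
                                      training = TRUE)
  worst <- fd_check(model, lossfun, lg$grads, max_per_tensor = 6)
  expect_lt(worst, 1e-4)
})
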