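test_that("cosine schedule matches its closed form and is non-increasing", {
  E <- 30
  expect_equal(cosine_lr(0, E), 0.03)
  expect_equal(cosine_lr(E / 2, E), 0.015)
  expect_equal(cosine_lr(E, E), 0)
  trace <- cosine_lr(0:E, E)
  expect_true(all(diff(trace) <= 0))
  expect_equal(trace, 0.015 * (1 + cos(pi * (0:E) / E)))
})

test_that("augmentation translates within bounds, scales anisotropically and shuffles", {
  set.seed(61)
  cloud <- make_shape(shape_spec("sphere", n = 64, sigma = 0))
  # translation bound: with the scale range collapsed to 1 the centroid
  # moves by exactly the drawn offset, which must lie in [-0.2, 0.2]
  cfg1 <- train_config(scale_range = c(1, 1))
  for (i in 1:100) {
    a <- augment_cloud(cloud, cfg1)
    shift <- colMeans(a$coords) - colMeans(cloud$coords)
    expect_true(all(abs(shift) <= 0.2 + 1e-12))
  }
  # zero-width ranges: identity up to point order
  cfg0 <- train_config(translate_range = 0, scale_range = c(1, 1))
  a0 <- augment_cloud(cloud, cfg0)
  expect_equal(a0$coords[order(a0$coords[, 1]), ],
               cloud$coords[order(cloud$coords[, 1]), ])
  # shuffle preserves the point multiset exactly, labels follow their points
  lab <- make_part_labeled_shape(shape_spec("cylinder", n = 64, sigma = 0,
                                            seed = 3))
  al <- augment_cloud(lab, cfg0)
  o1 <- order(al$coords[, 1], al$coords[, 2])
  o2 <- order(lab$coords[, 1], lab$coords[, 2])
  expect_identical(al$point_labels[o1], lab$point_labels[o2])
})

test_that("perturbations implement the robustness protocols", {
  set.seed(62)
  cloud <- make_shape(shape_spec("torus", n = 50, sigma = 0))
  # zero-angle rotation is the identity
  expect_equal(perturb_cloud(cloud, "rotate", angle = 0)$coords, cloud$coords)
  # rotation is rigid: norms preserved
  r <- perturb_cloud(cloud, "rotate", angle = 25, axis = "z")
  expect_equal(rowSums(r$coords^2), rowSums(cloud$coords^2))
  expect_equal(r$coords[, 3], cloud$coords[, 3])
  # full-size dropout is the identity up to order
  d <- perturb_cloud(cloud, "dropout", n_keep = 50)
  expect_equal(d$coords[order(d$coords[, 1]), ],
               cloud$coords[order(cloud$coords[, 1]), ])
  expect_equal(n_points(perturb_cloud(cloud, "dropout", n_keep = 13)), 13)
  expect_error(perturb_cloud(cloud, "dropout", n_keep = 0), "positive")
  # translation adds the offset exactly
  t <- perturb_cloud(cloud, "translate", offset = c(0.1, -0.2, 0.05))
  expect_equal(t$coords - cloud$coords,
               matrix(c(0.1, -0.2, 0.05), 50, 3, byrow = TRUE))
})

test_that("accuracy report matches brute-force counting and flags absent classes", {
  set.seed(63)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    n <- sample(5:40, 1)
    labels <- sample(0:(m - 1), n, replace = TRUE)
    preds <- sample(0:(m - 1), n, replace = TRUE)
    got <- suppressWarnings(pointattn:::.accuracy_report(labels, preds, m))
    want <- naive_accuracy(labels, preds, m)
    expect_equal(got$oa, want$oa)
    expect_equal(got$mean_class_accuracy, want$mca)
  }
  # worked example: sizes 90/10, one class fully right, one fully wrong
  labels <- c(rep(0, 90), rep(1, 10))
  preds <- rep(0, 100)
  r <- pointattn:::.accuracy_report(labels, preds, 2)
  expect_equal(r$oa, 90)
  expect_equal(r$mean_class_accuracy, 50)
  # absent class excluded with a warning
  expect_warning(pointattn:::.accuracy_report(c(0, 0, 1), c(0, 0, 1), 3),
                 "absent")
})

test_that("evaluation through the model is invariant to dataset order", {
  model <- tiny_classifier(n_classes = 2)
  set.seed(64)
  ds <- c(lapply(1:4, function(i) point_cloud(random_cloud(16),
                                              cloud_label = 0L)),
          lapply(1:4, function(i) point_cloud(random_cloud(16),
                                              cloud_label = 1L)))
  r1 <- evaluate_model(ds, model)
  r2 <- evaluate_model(rev(ds), model)
  expect_equal(r1$oa, r2$oa)
  expect_equal(r1$mean_class_accuracy, r2$mean_class_accuracy)
})

test_that("part mIoU matches set counting, the worked 1/3 case and the absent-part convention", {
  # perfect prediction
  parts <- shape_part_sets()
  gt <- c(0L, 0L, 1L, 1L)
  r <- part_miou(gt, gt, categories = 1L, part_sets = parts)
  expect_equal(r$instance_miou, 100)
  expect_equal(r$class_miou, 100)
  # 2-part shape, half of each part swapped: per-part IoU 1/3, shape 33.3%
  pred <- c(0L, 1L, 0L, 1L)
  r2 <- part_miou(pred, gt, categories = 1L, part_sets = parts)
  expect_equal(r2$instance_miou, 100 / 3, tolerance = 1e-12)
  # a part absent from both pred and gt contributes IoU 1
  gt3 <- c(0L, 0L, 1L, 1L)   # cylinder category: parts {0,1,2}, 2 absent
  r3 <- part_miou(gt3, gt3, categories = 0L, part_sets = parts)
  expect_equal(r3$instance_miou, 100)
  pred3 <- c(0L, 1L, 1L, 1L)
  r4 <- part_miou(pred3, gt3, categories = 0L, part_sets = parts)
  expect_equal(r4$per_shape, 100 * mean(c(1 / 2, 2 / 3, 1)))
  # random tiny sets against the naive oracle, multi-shape averaging
  set.seed(65)
  for (i in 1:10) {
    cats <- sample(0:1, 3, replace = TRUE)
    gts <- lapply(cats, function(cc) sample(parts[[cc + 1]], 6, replace = TRUE))
    prs <- lapply(cats, function(cc) sample(parts[[cc + 1]], 6, replace = TRUE))
    got <- part_miou(prs, gts, cats, parts)
    ious <- mapply(function(p, g, cc) naive_shape_iou(p, g, parts[[cc + 1]]),
                   prs, gts, cats)
    expect_equal(got$instance_miou, 100 * mean(ious))
    expect_equal(got$class_miou,
                 100 * mean(tapply(ious, cats, mean)))
  }
  expect_error(part_miou(c(0L, 5L), c(0L, 1L), 1L, parts),
               "outside category's part set")
})

test_that("a wide enough model memorizes a single batch", {
  set.seed(66)
  ds <- make_dataset(4, 2, split = 0.5, seed = 17, n = 64)
  batch <- ds$train   # 4 clouds, one per class
  cfg <- classifier_config(n_classes = 4, layers = c(12L, 12L), k = 8L,
                           global_width = 24L, mask_hidden = 12L,
                           head = c(16L, 16L), dropout = 0, graph = "coords")
  model <- init_classifier(cfg, seed = 18)
  tcfg <- train_config(epochs = 200, batch_size = 4, augment = FALSE,
                       schedule = "constant", lr = 0.01, seed = 18)
  fit <- train_model(batch, model, tcfg)
  expect_lt(min(fit$log$loss), 0.01)
  expect_lte(nrow(fit$log), 200)
})

test_that("training is deterministic given the seed and validates inputs", {
  ds <- make_dataset(2, 4, split = 0.5, seed = 19, n = 32)
  cfg <- classifier_config(n_classes = 2, layers = c(6L), k = 4L,
                           global_width = 8L, mask_hidden = 6L,
                           head = c(6L, 6L), graph = "coords")
  model <- init_classifier(cfg, seed = 20)
  tcfg <- train_config(epochs = 2, batch_size = 4, seed = 21)
  f1 <- train_model(ds$train, model, tcfg)
  f2 <- train_model(ds$train, model, tcfg)
  expect_identical(pointattn:::.flatten_params(f1$model$params),
                   pointattn:::.flatten_params(f2$model$params))
  expect_equal(f1$log, f2$log)
  expect_equal(f1$log$lr, cosine_lr(0:1, 2))
  expect_error(train_model(list(), model, tcfg), "empty dataset")
})

test_that("robustness sweep returns one row per condition and model", {
  model <- tiny_classifier(n_classes = 2)
  set.seed(67)
  ds <- c(lapply(1:3, function(i) point_cloud(random_cloud(16),
                                              cloud_label = 0L)),
          lapply(1:3, function(i) point_cloud(random_cloud(16),
                                              cloud_label = 1L)))
  tab <- perturb_eval(ds, model, rotations = c(0, 10), dropout_counts = 12L,
                      translations = c(0.1, 0, 0), seed = 5)
  expect_identical(tab$protocol, c("rotate", "rotate", "dropout", "translate"))
  expect_true(all(tab$oa >= 0 & tab$oa <= 100))
})
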