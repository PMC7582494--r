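# Optimization, augmentation, robustness protocols and evaluation metrics.

#' Training configuration
#'
#' SGD with momentum and a cosine-annealed learning rate: starting at
#' \code{lr} (default 0.03) and decaying to 0 over \code{epochs} (the
#' annealing period equals the epoch budget). Augmentation follows the
#' dynamic-graph training recipe — per-cloud uniform translation, anisotropic
#' uniform scaling and point-order shuffling; deliberately no rotation, so
#' rotation robustness can be probed on a model that never saw rotated data.
#'
#' @param epochs number of training epochs.
#' @param batch_size clouds per SGD step.
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param translate_range half-width t of the per-axis uniform translation
#'   offset, drawn from [-t, t].
#' @param scale_range two-element range of the per-axis uniform scale factor.
#' @param augment apply augmentation during training?
#' @param schedule \code{"cosine"} annealing or \code{"constant"}.
#' @param early_stop_oa optional validation overall-accuracy threshold (in
#'   percent); when a validation set is supplied and its accuracy reaches
#'   this value, training stops early (the epoch budget is a cap).
#' @param seed RNG seed governing shuffling, augmentation and dropout.
#' @return A \code{train_config} list.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, lr = 0.03,
                         momentum = 0.9, weight_decay = 1e-4,
                         translate_range = 0.2,
                         scale_range = c(2 / 3, 3 / 2),
                         augment = TRUE,
                         schedule = c("cosine", "constant"),
                         early_stop_oa = NULL,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 translate_range = translate_range,
                 scale_range = scale_range,
                 augment = isTRUE(augment),
                 schedule = match.arg(schedule),
                 early_stop_oa = early_stop_oa,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' Closed form \eqn{lr(e) = \frac{lr_0}{2}\,(1 + \cos(\pi e / E))}: equals
#' \code{lr0} at epoch 0 and 0 at epoch \code{E}.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total epoch budget E (the annealing period).
#' @param lr0 initial learning rate.
#' @return learning rate at \code{epoch}.
#' @export
cosine_lr <- function(epoch, epochs, lr0 = 0.03) {
  0.5 * lr0 * (1 + cos(pi * epoch / epochs))
}

#' Augment a point cloud for training
#'
#' Applies, in order: a per-cloud uniform translation offset per axis, an
#' anisotropic per-axis uniform scale, and a random shuffle of point order
#' (labels are shuffled consistently). Uses the caller's RNG stream.
#'
#' @param cloud a \code{point_cloud}.
#' @param cfg a \code{train_config} supplying the augmentation ranges.
#' @return the augmented \code{point_cloud}.
#' @export
augment_cloud <- function(cloud, cfg = train_config()) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  t <- stats::runif(3L, -cfg$translate_range, cfg$translate_range)
  s <- stats::runif(3L, cfg$scale_range[1L], cfg$scale_range[2L])
  co <- cloud$coords * matrix(s, n, 3L, byrow = TRUE) +
    matrix(t, n, 3L, byrow = TRUE)
  perm <- sample.int(n)
  cloud$coords <- co[perm, , drop = FALSE]
  if (!is.null(cloud$extra_channels))
    cloud$extra_channels <- cloud$extra_channels[perm, , drop = FALSE]
  if (!is.null(cloud$point_labels))
    cloud$point_labels <- cloud$point_labels[perm]
  cloud
}

.rotation_matrix <- function(angle_deg, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  switch(axis,
         z = matrix(c(c2, -s2, 0, s2, c2, 0, 0, 0, 1), 3L, byrow = TRUE),
         x = matrix(c(1, 0, 0, 0, c2, -s2, 0, s2, c2), 3L, byrow = TRUE),
         y = matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3L, byrow = TRUE))
}

#' Perturb a point cloud for robustness evaluation
#'
#' Three protocols: \code{"dropout"} keeps a uniform random subset of
#' \code{n_keep} points (missing-point robustness, evaluated without
#' retraining); \code{"rotate"} applies a rigid rotation of \code{angle}
#' degrees about \code{axis} (default the gravity axis); \code{"translate"}
#' adds a constant offset to every point.
#'
#' @param cloud a \code{point_cloud}.
#' @param mode perturbation type.
#' @param n_keep points to keep in dropout mode.
#' @param angle rotation angle in degrees.
#' @param axis rotation axis, one of \code{"z"}, \code{"x"}, \code{"y"}.
#' @param offset length-3 translation vector.
#' @return the perturbed \code{point_cloud}.
#' @export
perturb_cloud <- function(cloud, mode = c("dropout", "rotate", "translate"),
                          n_keep = NULL, angle = 0, axis = "z",
                          offset = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"))
  mode <- match.arg(mode)
  n <- n_points(cloud)
  if (mode == "dropout") {
    if (is.null(n_keep) || n_keep <= 0) stop("n_keep must be positive")
    if (n_keep > n) stop("n_keep exceeds point count")
    keep <- sort(sample.int(n, n_keep))
    cloud$coords <- cloud$coords[keep, , drop = FALSE]
    if (!is.null(cloud$extra_channels))
      cloud$extra_channels <- cloud$extra_channels[keep, , drop = FALSE]
    if (!is.null(cloud$point_labels))
      cloud$point_labels <- cloud$point_labels[keep]
  } else if (mode == "rotate") {
    R <- .rotation_matrix(angle, axis)
    cloud$coords <- cloud$coords %*% t(R)
  } else {
    cloud$coords <- cloud$coords +
      matrix(as.numeric(offset), n, 3L, byrow = TRUE)
  }
  cloud
}

# ---- training loop ---------------------------------------------------------

.cloud_labels <- function(clouds) {
  vapply(clouds, function(p) {
    if (is.null(p$cloud_label)) stop("dataset clouds must carry cloud_label")
    p$cloud_label
  }, integer(1))
}

.onehot <- function(labels, m) {
  oh <- matrix(0, length(labels), m)
  oh[cbind(seq_along(labels), labels + 1L)] <- 1
  oh
}

#' Train a model with SGD and cosine annealing
#'
#' Classification models need clouds with \code{cloud_label}; segmentation
#' models need \code{point_labels} plus \code{cloud_label} as the object
#' category. Training is deterministic given \code{cfg$seed}. When a
#' validation set is supplied, the returned model is the state with the best
#' validation overall accuracy; otherwise the final state.
#'
#' @param dataset list of labeled \code{point_cloud}s.
#' @param model an initialized \code{pointattn_model}.
#' @param cfg a \code{train_config}.
#' @param val optional validation list of labeled clouds.
#' @param verbose print per-epoch progress?
#' @return list with \code{model} (trained state), \code{log} (data frame of
#'   epoch, lr, loss and accuracy trace) and \code{best_epoch}.
#' @export
train_model <- function(dataset, model, cfg = train_config(), val = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "pointattn_model"), inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("empty dataset")
  task <- model$cfg$task
  n <- length(dataset)
  set.seed(cfg$seed)
  vel <- list()
  log <- vector("list", cfg$epochs)
  log_n <- 0L
  best <- list(oa = -Inf, params = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- if (cfg$schedule == "cosine") cosine_lr(epoch, cfg$epochs, cfg$lr)
          else cfg$lr
    ord <- sample.int(n)
    losses <- c()
    correct <- 0L; total <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
      if (length(ids) < 2L && n >= 2L) next  # skip degenerate 1-cloud batch
      clouds <- dataset[ids]
      if (cfg$augment)
        clouds <- lapply(clouds, augment_cloud, cfg = cfg)
      st <- .stack_clouds(clouds)
      if (task == "classify") {
        labels <- .cloud_labels(clouds)
        lg <- .class_loss_grads(model, st$X, st$B, st$N, labels)
        pred <- max.col(lg$logits, ties.method = "first") - 1L
        correct <- correct + sum(pred == labels)
        total <- total + length(labels)
      } else {
        cats <- .cloud_labels(clouds)
        oh <- .onehot(cats, model$cfg$n_categories)
        pl <- unlist(lapply(clouds, function(p) p$point_labels))
        lg <- .seg_loss_grads(model, st$X, st$B, st$N, oh, pl)
        pred <- max.col(lg$logits, ties.method = "first") - 1L
        correct <- correct + sum(pred == pl)
        total <- total + length(pl)
      }
      model$params <- .absorb_running(model$params, lg$running)
      if (length(vel) == 0L) vel <- .zeros_like(lg$grads)
      upd <- .sgd_update(model$params, lg$grads, vel, lr, cfg$momentum,
                         cfg$weight_decay)
      model$params <- upd$params
      vel <- upd$vel
      losses <- c(losses, lg$loss)
    }
    val_oa <- NA_real_
    if (!is.null(val)) {
      val_oa <- if (task == "classify")
        suppressWarnings(evaluate_model(val, model)$oa)
      else .seg_point_accuracy(val, model)
      if (val_oa > best$oa) {
        best <- list(oa = val_oa, params = model$params, epoch = epoch)
      }
    }
    log_n <- epoch + 1L
    log[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                    loss = mean(losses),
                                    train_oa = 100 * correct / max(total, 1L),
                                    val_oa = val_oa)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  train OA %.1f%%%s",
                      epoch, lr, mean(losses), 100 * correct / max(total, 1L),
                      if (is.na(val_oa)) "" else sprintf("  val OA %.1f%%", val_oa)))
    if (!is.null(cfg$early_stop_oa) && !is.na(val_oa) &&
        val_oa >= cfg$early_stop_oa) break
  }
  if (!is.null(val) && !is.null(best$params)) {
    model$params <- best$params
  }
  list(model = model, log = do.call(rbind, log[seq_len(log_n)]),
       best_epoch = best$epoch)
}

# ---- evaluation ------------------------------------------------------------

# overall per-point label accuracy (%) of a segmentation model, inference
# mode, unrestricted argmax
.seg_point_accuracy <- function(dataset, model) {
  correct <- 0L; total <- 0L
  for (p in dataset) {
    oh <- numeric(model$cfg$n_categories)
    oh[p$cloud_label + 1L] <- 1
    logits <- segment_forward(p, oh, model)
    pred <- max.col(logits, ties.method = "first") - 1L
    correct <- correct + sum(pred == p$point_labels)
    total <- total + length(p$point_labels)
  }
  100 * correct / total
}

#' Predict class labels for a list of clouds
#'
#' @param clouds list of \code{point_cloud}s.
#' @param model a classification \code{pointattn_model}.
#' @param batch_size clouds per forward pass (clouds are grouped by point
#'   count, so mixed-size collections are handled).
#' @return integer vector of 0-based predicted class labels.
#' @export
predict_classes <- function(clouds, model, batch_size = 32L) {
  stopifnot(inherits(model, "pointattn_model"), model$cfg$task == "classify")
  ns <- vapply(clouds, n_points, integer(1))
  preds <- integer(length(clouds))
  for (sz in unique(ns)) {
    ids <- which(ns == sz)
    for (start in seq(1L, length(ids), by = batch_size)) {
      sel <- ids[start:min(start + batch_size - 1L, length(ids))]
      st <- .stack_clouds(clouds[sel])
      fw <- .class_fw(model, st$X, st$B, st$N, training = FALSE)
      preds[sel] <- max.col(fw$logits, ties.method = "first") - 1L
    }
  }
  preds
}

#' Evaluate classification accuracy
#'
#' Overall accuracy is exactly \code{100 * correct / total}; mean class
#' accuracy is the unweighted mean of per-class recalls. Classes absent from
#' the dataset are excluded from the mean with a warning. The report does not
#' depend on dataset order.
#'
#' @param dataset list of labeled \code{point_cloud}s.
#' @param model a classification \code{pointattn_model}.
#' @param batch_size forward-pass batch size.
#' @return An \code{eval_report}: list with \code{oa},
#'   \code{mean_class_accuracy}, \code{per_class} data frame and \code{n}.
#' @export
evaluate_model <- function(dataset, model, batch_size = 32L) {
  labels <- .cloud_labels(dataset)
  preds <- predict_classes(dataset, model, batch_size)
  .accuracy_report(labels, preds, model$cfg$n_classes)
}

# pure counting step shared with evaluate_model: overall accuracy and
# unweighted mean of per-class recalls from 0-based label/prediction vectors
.accuracy_report <- function(labels, preds, m) {
  per <- data.frame(class = 0:(m - 1L), n = 0L, correct = 0L,
                    recall = NA_real_)
  for (cl in 0:(m - 1L)) {
    sel <- labels == cl
    per$n[cl + 1L] <- sum(sel)
    per$correct[cl + 1L] <- sum(preds[sel] == cl)
    if (any(sel)) per$recall[cl + 1L] <- 100 * mean(preds[sel] == cl)
  }
  absent <- per$class[per$n == 0L]
  if (length(absent) > 0L)
    warning(sprintf("class(es) %s absent from dataset; excluded from mean class accuracy",
                    paste(absent, collapse = ", ")))
  structure(list(oa = 100 * sum(preds == labels) / length(labels),
                 mean_class_accuracy = mean(per$recall, na.rm = TRUE),
                 per_class = per,
                 n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  OA=%.2f%%  mean class acc=%.2f%%\n",
              x$n, x$oa, x$mean_class_accuracy))
  invisible(x)
}

#' Predict part labels restricted to a category's part set
#'
#' The argmax over part logits is taken only over the parts admissible for
#' the object's category, the convention of the standard part-segmentation
#' evaluation lineage.
#'
#' @param cloud a \code{point_cloud}.
#' @param category 0-based category index.
#' @param model a segmentation \code{pointattn_model}.
#' @param part_sets list whose element \code{i + 1} is the integer vector of
#'   part labels admissible for category \code{i}.
#' @return integer vector of per-point part labels.
#' @export
predict_parts <- function(cloud, category, model, part_sets) {
  oh <- numeric(model$cfg$n_categories)
  oh[category + 1L] <- 1
  logits <- segment_forward(cloud, oh, model)
  parts <- part_sets[[category + 1L]]
  sub <- logits[, parts + 1L, drop = FALSE]
  parts[max.col(sub, ties.method = "first")]
}

#' Part-segmentation mean intersection-over-union
#'
#' Per shape, the IoU of each part admissible for the shape's category is
#' \code{|pred & gt| / |pred | gt|}; a part absent from both prediction and
#' ground truth contributes IoU 1 (it was segmented "perfectly vacuously" —
#' the convention of the standard evaluation lineage). The shape IoU is the
#' mean over the category's parts. Instance mIoU averages over all shapes;
#' class mIoU averages shape IoUs within each category first, then over
#' categories.
#'
#' @param point_preds list of integer vectors (predicted part labels per
#'   shape), or a single vector for one shape.
#' @param point_labels ground-truth part labels, same layout.
#' @param categories integer vector of 0-based category indices per shape.
#' @param part_sets list whose element \code{i + 1} gives category i's
#'   admissible part labels.
#' @return list with \code{class_miou}, \code{instance_miou} (both in
#'   percent), \code{per_shape} and \code{per_class}.
#' @export
part_miou <- function(point_preds, point_labels, categories, part_sets) {
  if (!is.list(point_preds)) point_preds <- list(point_preds)
  if (!is.list(point_labels)) point_labels <- list(point_labels)
  stopifnot(length(point_preds) == length(point_labels),
            length(categories) == length(point_preds))
  ious <- numeric(length(point_preds))
  for (i in seq_along(point_preds)) {
    parts <- part_sets[[categories[i] + 1L]]
    gt <- point_labels[[i]]
    pr <- point_preds[[i]]
    if (length(gt) != length(pr)) stop("prediction/label length mismatch")
    if (!all(gt %in% parts) || !all(pr %in% parts))
      stop("label outside category's part set")
    part_iou <- vapply(parts, function(p) {
      inter <- sum(pr == p & gt == p)
      uni <- sum(pr == p | gt == p)
      if (uni == 0L) 1 else inter / uni
    }, numeric(1))
    ious[i] <- mean(part_iou)
  }
  per_class <- tapply(ious, categories, mean)
  list(class_miou = 100 * mean(per_class),
       instance_miou = 100 * mean(ious),
       per_shape = 100 * ious,
       per_class = 100 * per_class)
}

# ---- robustness harness ----------------------------------------------------

#' Robustness sweep over perturbations
#'
#' Evaluates one or more trained models on perturbed copies of a test set:
#' rigid rotations of increasing angle (about the gravity axis by default,
#' since training augmentation contains no rotation), random point dropout
#' down to given kept counts, and constant translations. Rotation and
#' translation are deterministic; dropout subsets are drawn from \code{seed}.
#'
#' @param dataset list of labeled test clouds.
#' @param models a single \code{pointattn_model} or a list of them (e.g.
#'   trained from different seeds); results carry a model id.
#' @param rotations numeric vector of rotation angles in degrees.
#' @param dropout_counts integer vector of kept point counts.
#' @param translations list of length-3 offset vectors (or a single vector).
#' @param axis rotation axis.
#' @param seed RNG seed for the dropout subsets.
#' @return data frame with columns \code{protocol}, \code{level},
#'   \code{model}, \code{oa}, \code{mean_class_acc}.
#' @export
perturb_eval <- function(dataset, models, rotations = NULL,
                         dropout_counts = NULL, translations = NULL,
                         axis = "z", seed = 1L) {
  if (inherits(models, "pointattn_model")) models <- list(models)
  rows <- list()
  eval_set <- function(set, model) {
    r <- suppressWarnings(evaluate_model(set, model))
    c(r$oa, r$mean_class_accuracy)
  }
  for (mi in seq_along(models)) {
    for (ang in rotations) {
      set <- lapply(dataset, perturb_cloud, mode = "rotate", angle = ang,
                    axis = axis)
      v <- eval_set(set, models[[mi]])
      rows[[length(rows) + 1L]] <- data.frame(protocol = "rotate", level = ang,
                                              model = mi, oa = v[1],
                                              mean_class_acc = v[2])
    }
    for (nk in dropout_counts) {
      set.seed(seed + nk)
      set <- lapply(dataset, perturb_cloud, mode = "dropout", n_keep = nk)
      v <- eval_set(set, models[[mi]])
      rows[[length(rows) + 1L]] <- data.frame(protocol = "dropout", level = nk,
                                              model = mi, oa = v[1],
                                              mean_class_acc = v[2])
    }
    if (!is.null(translations)) {
      if (!is.list(translations)) translations <- list(translations)
      for (tv in translations) {
        set <- lapply(dataset, perturb_cloud, mode = "translate", offset = tv)
        v <- eval_set(set, models[[mi]])
        rows[[length(rows) + 1L]] <- data.frame(protocol = "translate",
                                                level = sqrt(sum(tv^2)),
                                                model = mi, oa = v[1],
                                                mean_class_acc = v[2])
      }
    }
  }
  do.call(rbind, rows)
}
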