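# Full architectures: a trunk of one CW-EdgeConv++ layer plus further
# CW-EdgeConv layers, the global feature builder, the point-wise attention
# mask, and task heads. Forward passes run on a stacked batch of equal-size
# clouds: X is a (B*N) x C matrix with clouds in contiguous blocks. Backward
# passes are hand-written and mirror the forward caches exactly.

#' Classification architecture configuration
#'
#' Defaults follow the reference architecture: four edge-convolution layers
#' of widths (64, 64, 128, 256), group size k = 20, a 1024-wide global
#' feature, max + average pooling (pooled width 2048) and a 3-layer head
#' 512 -> 256 -> m with dropout 0.5 on the first two layers. The head's
#' reduction factor is \code{head[1] / head[2]}.
#'
#' @param n_classes number of classes m.
#' @param layers integer vector of edge-convolution output widths.
#' @param k kNN group size.
#' @param global_width width of the per-point global feature.
#' @param mask_hidden hidden width of the attention-mask branch.
#' @param head widths of the two hidden head layers.
#' @param dropout dropout rate on the hidden head layers.
#' @param pooling \code{"maxavg"} (concatenate max- and average-pooling,
#'   doubling the pooled width) or \code{"max"}.
#' @param activation \code{"leaky"} (slope 0.2) or \code{"relu"}.
#' @param graph metric space of the kNN query in layers beyond the first:
#'   \code{"features"} recomputes the graph in each layer's feature space
#'   (dynamic graph), \code{"coords"} reuses the coordinate-space graph.
#' @param use_se enable the channel gates (disabling them, together with the
#'   mask, reduces the model to a plain edge-convolution baseline).
#' @param use_mask enable the global attention mask.
#' @param global_from \code{"all"} concatenates every layer output before the
#'   global feature MLP; \code{"last"} consumes only the final layer.
#' @return A \code{classifier_config} list.
#' @export
classifier_config <- function(n_classes,
                              layers = c(64L, 64L, 128L, 256L),
                              k = 20L,
                              global_width = 1024L,
                              mask_hidden = 64L,
                              head = c(512L, 256L),
                              dropout = 0.5,
                              pooling = c("maxavg", "max"),
                              activation = c("leaky", "relu"),
                              graph = c("features", "coords"),
                              use_se = TRUE,
                              use_mask = TRUE,
                              global_from = c("all", "last")) {
  structure(list(task = "classify",
                 n_classes = as.integer(n_classes),
                 layers = as.integer(layers),
                 k = as.integer(k),
                 global_width = as.integer(global_width),
                 mask_hidden = as.integer(mask_hidden),
                 head = as.integer(head),
                 dropout = dropout,
                 pooling = match.arg(pooling),
                 activation = match.arg(activation),
                 graph = match.arg(graph),
                 use_se = isTRUE(use_se),
                 use_mask = isTRUE(use_mask),
                 global_from = match.arg(global_from)),
            class = "classifier_config")
}

#' Part-segmentation architecture configuration
#'
#' Shares the classification trunk; the per-point head consumes the tiled
#' one-hot object category, the masked global feature and its pooled summary,
#' and maps them through a 4-layer MLP (defaults 256, 256, 128, then the part
#' count).
#'
#' @param n_parts total number of part labels P (the final head width).
#' @param n_categories number of object categories (one-hot width).
#' @param seg_head widths of the three hidden head layers.
#' @inheritParams classifier_config
#' @return A \code{segmenter_config} list.
#' @export
segmenter_config <- function(n_parts, n_categories,
                             layers = c(64L, 64L, 128L, 256L),
                             k = 20L,
                             global_width = 1024L,
                             mask_hidden = 64L,
                             seg_head = c(256L, 256L, 128L),
                             dropout = 0.5,
                             activation = c("leaky", "relu"),
                             graph = c("features", "coords"),
                             use_se = TRUE,
                             use_mask = TRUE,
                             global_from = c("all", "last")) {
  structure(list(task = "segment",
                 n_parts = as.integer(n_parts),
                 n_categories = as.integer(n_categories),
                 layers = as.integer(layers),
                 k = as.integer(k),
                 global_width = as.integer(global_width),
                 mask_hidden = as.integer(mask_hidden),
                 seg_head = as.integer(seg_head),
                 dropout = dropout,
                 activation = match.arg(activation),
                 graph = match.arg(graph),
                 use_se = isTRUE(use_se),
                 use_mask = isTRUE(use_mask),
                 global_from = match.arg(global_from)),
            class = "segmenter_config")
}

.global_in_width <- function(cfg) {
  if (cfg$global_from == "all") sum(cfg$layers) else cfg$layers[length(cfg$layers)]
}

.trunk_init <- function(cfg) {
  L <- length(cfg$layers)
  c_in <- c(3L, cfg$layers[-L])
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- list(dense = .init_dense(2L * c_in[l], cfg$layers[l],
                                            bias = FALSE),
                        bn = .init_bn(cfg$layers[l]),
                        se = if (cfg$use_se) .init_se(cfg$layers[l]) else NULL)
  }
  glob <- list(dense = .init_dense(.global_in_width(cfg), cfg$global_width,
                                   bias = FALSE),
               bn = .init_bn(cfg$global_width),
               se = if (cfg$use_se) .init_se(cfg$global_width) else NULL)
  mask <- if (cfg$use_mask) {
    list(d1 = .init_dense(10L, cfg$mask_hidden, bias = FALSE),
         bn1 = .init_bn(cfg$mask_hidden),
         d2 = .init_dense(cfg$mask_hidden, 1L))
  } else NULL
  list(layers = layers, global = glob, mask = mask)
}

#' Initialize a classification model
#'
#' @param cfg a \code{classifier_config}.
#' @param seed optional seed; the same seed always yields the same weights.
#' @return A \code{pointattn_model} holding the configuration, all
#'   parameters and the seed record.
#' @export
init_classifier <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "classifier_config"))
  params <- .with_seed(seed, {
    p <- .trunk_init(cfg)
    pool_w <- if (cfg$pooling == "maxavg") 2L * cfg$global_width else cfg$global_width
    widths <- c(pool_w, cfg$head)
    hidden <- vector("list", length(cfg$head))
    for (i in seq_along(cfg$head)) {
      hidden[[i]] <- list(dense = .init_dense(widths[i], widths[i + 1L],
                                              bias = FALSE),
                          bn = .init_bn(widths[i + 1L]))
    }
    p$head <- list(hidden = hidden,
                   final = .init_dense(widths[length(widths)], cfg$n_classes))
    p
  })
  structure(list(cfg = cfg, params = params, seed = seed),
            class = "pointattn_model")
}

#' Initialize a part-segmentation model
#'
#' @param cfg a \code{segmenter_config}.
#' @param seed optional seed.
#' @return A \code{pointattn_model}.
#' @export
init_segmenter <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "segmenter_config"))
  params <- .with_seed(seed, {
    p <- .trunk_init(cfg)
    in_w <- cfg$n_categories + 2L * cfg$global_width
    widths <- c(in_w, cfg$seg_head)
    hidden <- vector("list", length(cfg$seg_head))
    for (i in seq_along(cfg$seg_head)) {
      hidden[[i]] <- list(dense = .init_dense(widths[i], widths[i + 1L],
                                              bias = FALSE),
                          bn = .init_bn(widths[i + 1L]))
    }
    p$head <- list(hidden = hidden,
                   final = .init_dense(widths[length(widths)], cfg$n_parts))
    p
  })
  structure(list(cfg = cfg, params = params, seed = seed),
            class = "pointattn_model")
}

#' @export
print.pointattn_model <- function(x, ...) {
  cat(sprintf("<pointattn_model> task=%s, %d parameters\n",
              x$cfg$task, n_parameters(x)))
  invisible(x)
}

# ---- batched building blocks -----------------------------------------------

# kNN indices for B stacked clouds of N points; global 1-based row indices
.batch_knn <- function(X, B, N, k) {
  idx <- matrix(0L, B * N, k)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    idx[rows, ] <- .knn_indices(X[rows, , drop = FALSE], k) + (b - 1L) * N
  }
  idx
}

# scatter-add rows of dR (grouped by integer row targets) into an n-row matrix
.scatter_rows <- function(dR, rows, n) {
  A <- rowsum(dR, rows)
  out <- matrix(0, n, ncol(dR))
  out[as.integer(rownames(A)), ] <- A
  out
}

# one edge-convolution layer, batched. The shared MLP over edge features
# (x_j - x_i, x_i) is applied in decomposed form: with W = [W1; W2],
# E W = (x_j W1) + x_i (W2 - W1), so the matmul runs per point (N rows)
# rather than per edge (N*k rows) and only the gather touches the edge axis.
.layer_fw <- function(P, idx, p, act, training, B, npos) {
  k <- ncol(idx)
  D <- ncol(P)
  W <- p$dense$W
  W1 <- W[seq_len(D), , drop = FALSE]
  W2 <- W[D + seq_len(D), , drop = FALSE]
  A <- P %*% W1
  C2 <- P %*% (W2 - W1)
  H0 <- .c_gather_sum(A, C2, idx)
  bn <- .bn_fw(H0, p$bn, training)
  a <- .act_fw(bn$out, act)
  h <- a$out
  se <- NULL
  if (!is.null(p$se)) {
    se <- .se_fw(h, p$se, grp = rep(seq_len(B), each = npos * k),
                 gs = npos * k, act = act)
    h <- se$out
  }
  mx <- .maxk_fw(h, k)
  list(out = mx$out,
       cache = list(idx = idx, k = k, P = P, W1 = W1, W2 = W2,
                    bn = bn$cache, a = a$cache,
                    se = if (is.null(se)) NULL else se$cache,
                    mx = mx$cache, n_in = nrow(P), c_in = D),
       running = bn$running)
}

.layer_bw <- function(dY, cache) {
  dh <- .maxk_bw(dY, cache$mx)
  g_se <- NULL
  if (!is.null(cache$se)) {
    sb <- .se_bw(dh, cache$se)
    g_se <- list(W1 = sb$dW1, b1 = sb$db1, W2 = sb$dW2, b2 = sb$db2)
    dh <- sb$dM
  }
  da <- .act_bw(dh, cache$a)
  gb <- .bn_bw(da, cache$bn)
  dA <- .c_nbr_scatter(gb$dX, cache$idx, cache$n_in)
  dCS <- .c_centersum(gb$dX, cache$k)
  dW1 <- crossprod(cache$P, dA - dCS)
  dW2 <- crossprod(cache$P, dCS)
  dP <- dA %*% t(cache$W1) + dCS %*% t(cache$W2 - cache$W1)
  list(grads = list(dense = list(W = rbind(dW1, dW2), b = NULL),
                    bn = list(gamma = gb$dgamma, beta = gb$dbeta),
                    se = g_se),
       dP = dP)
}

# trunk forward: layers, global feature, attention mask, masked feature gm
.trunk_fw <- function(params, cfg, X, B, N, training) {
  L <- length(cfg$layers)
  k <- cfg$k
  if (N < k) stop("group size exceeds point count")
  idx1 <- .batch_knn(X, B, N, k)
  desc <- if (cfg$use_mask) .geom_mat(X, idx1) else NULL
  outs <- vector("list", L)
  caches <- vector("list", L)
  running <- vector("list", L)
  P <- X
  for (l in seq_len(L)) {
    idx <- if (l == 1L || cfg$graph == "coords") idx1
           else .batch_knn(P, B, N, k)
    fw <- .layer_fw(P, idx, params$layers[[l]], cfg$activation, training, B, N)
    outs[[l]] <- fw$out
    caches[[l]] <- fw$cache
    running[[l]] <- fw$running
    P <- fw$out
  }
  H <- if (cfg$global_from == "all") do.call(cbind, outs) else outs[[L]]
  gd <- .dense_fw(H, params$global$dense)
  gbn <- .bn_fw(gd$out, params$global$bn, training)
  ga <- .act_fw(gbn$out, cfg$activation)
  g <- ga$out
  gse <- NULL
  if (!is.null(params$global$se)) {
    gse <- .se_fw(g, params$global$se, grp = rep(seq_len(B), each = N),
                  gs = N, act = cfg$activation)
    g <- gse$out
  }
  # attention mask branch
  mcache <- NULL
  mrunning <- NULL
  if (cfg$use_mask) {
    m1 <- .dense_fw(desc, params$mask$d1)
    mbn <- .bn_fw(m1$out, params$mask$bn1, training)
    ma <- .act_fw(mbn$out, cfg$activation)
    m2 <- .dense_fw(ma$out, params$mask$d2)
    ms <- .sigmoid_fw(m2$out)
    mmx <- .maxk_fw(ms$out, k)
    w <- as.numeric(mmx$out)
    mcache <- list(d1 = m1$cache, bn = mbn$cache, a = ma$cache,
                   d2 = m2$cache, sg = ms$cache, mx = mmx$cache)
    mrunning <- mbn$running
  } else {
    w <- rep(1, B * N)
  }
  gw <- g * w
  gm <- pmax(gw, 0)
  list(gm = gm, w = w,
       cache = list(w = w, layers = caches, outs = outs,
                    H_cols = vapply(outs, ncol, integer(1)),
                    gd = gd$cache, gbn = gbn$cache, ga = ga$cache,
                    gse = if (is.null(gse)) NULL else gse$cache,
                    g = g, mask = mcache, relu = (gw > 0), B = B, N = N),
       running = list(layers = running, global = gbn$running, mask = mrunning))
}

# backward through mask application, global feature and trunk layers
.trunk_bw <- function(dgm, cache, params, cfg) {
  B <- cache$B; N <- cache$N
  dgw <- dgm * cache$relu
  dg <- dgw * cache$w
  g_mask <- NULL
  if (cfg$use_mask) {
    dw <- rowSums(dgw * cache$g)
    mc <- cache$mask
    dms <- .maxk_bw(matrix(dw, ncol = 1L), mc$mx)
    dm2 <- .sigmoid_bw(dms, mc$sg)
    g2 <- .dense_bw(dm2, mc$d2)
    dma <- .act_bw(g2$dX, mc$a)
    gbn <- .bn_bw(dma, mc$bn)
    g1 <- .dense_bw(gbn$dX, mc$d1)
    g_mask <- list(d1 = list(W = g1$dW, b = g1$db),
                   bn1 = list(gamma = gbn$dgamma, beta = gbn$dbeta),
                   d2 = list(W = g2$dW, b = g2$db))
  }
  g_se <- NULL
  if (!is.null(cache$gse)) {
    sb <- .se_bw(dg, cache$gse)
    g_se <- list(W1 = sb$dW1, b1 = sb$db1, W2 = sb$dW2, b2 = sb$db2)
    dg <- sb$dM
  }
  da <- .act_bw(dg, cache$ga)
  gb <- .bn_bw(da, cache$gbn)
  gd <- .dense_bw(gb$dX, cache$gd)
  g_global <- list(dense = list(W = gd$dW, b = gd$db),
                   bn = list(gamma = gb$dgamma, beta = gb$dbeta),
                   se = g_se)
  # split concat gradient back onto layer outputs
  L <- length(cfg$layers)
  dx <- vector("list", L)
  for (l in seq_len(L)) dx[[l]] <- matrix(0, B * N, cfg$layers[l])
  if (cfg$global_from == "all") {
    off <- 0L
    for (l in seq_len(L)) {
      dx[[l]] <- gd$dX[, off + seq_len(cache$H_cols[l]), drop = FALSE]
      off <- off + cache$H_cols[l]
    }
  } else {
    dx[[L]] <- gd$dX
  }
  g_layers <- vector("list", L)
  for (l in rev(seq_len(L))) {
    lb <- .layer_bw(dx[[l]], cache$layers[[l]])
    g_layers[[l]] <- lb$grads
    if (l > 1L) dx[[l - 1L]] <- dx[[l - 1L]] + lb$dP
  }
  list(layers = g_layers, global = g_global, mask = g_mask)
}

# per-cloud pooling of the masked global feature
.pool_fw <- function(gm, B, N, pooling) {
  mx <- .maxk_fw(gm, N)
  if (pooling == "maxavg") {
    av <- .meank_fw(gm, N)
    list(out = cbind(mx$out, av$out), cache = list(mx = mx$cache, av = av$cache,
                                                   cg = ncol(gm)))
  } else {
    list(out = mx$out, cache = list(mx = mx$cache, av = NULL, cg = ncol(gm)))
  }
}

.pool_bw <- function(dpool, cache) {
  cg <- cache$cg
  d <- .maxk_bw(dpool[, seq_len(cg), drop = FALSE], cache$mx)
  if (!is.null(cache$av))
    d <- d + .meank_bw(dpool[, cg + seq_len(cg), drop = FALSE], cache$av)
  d
}

# MLP head shared by both tasks: hidden stages (dense+BN+act+dropout), then a
# final linear map
.head_fw <- function(F0, head, act, dropout, training) {
  caches <- vector("list", length(head$hidden))
  running <- vector("list", length(head$hidden))
  h <- F0
  for (i in seq_along(head$hidden)) {
    d <- .dense_fw(h, head$hidden[[i]]$dense)
    bn <- .bn_fw(d$out, head$hidden[[i]]$bn, training)
    a <- .act_fw(bn$out, act)
    dr <- .drop_fw(a$out, dropout, training)
    caches[[i]] <- list(d = d$cache, bn = bn$cache, a = a$cache, dr = dr$cache)
    running[[i]] <- bn$running
    h <- dr$out
  }
  fin <- .dense_fw(h, head$final)
  list(out = fin$out,
       cache = list(hidden = caches, final = fin$cache),
       running = running)
}

.head_bw <- function(dY, cache) {
  gf <- .dense_bw(dY, cache$final)
  g_hidden <- vector("list", length(cache$hidden))
  dh <- gf$dX
  for (i in rev(seq_along(cache$hidden))) {
    hc <- cache$hidden[[i]]
    dh <- .drop_bw(dh, hc$dr)
    dh <- .act_bw(dh, hc$a)
    gb <- .bn_bw(dh, hc$bn)
    gd <- .dense_bw(gb$dX, hc$d)
    g_hidden[[i]] <- list(dense = list(W = gd$dW, b = gd$db),
                          bn = list(gamma = gb$dgamma, beta = gb$dbeta))
    dh <- gd$dX
  }
  list(grads = list(hidden = g_hidden,
                    final = list(W = gf$dW, b = gf$db)),
       dF = dh)
}

# full classification forward on a stacked batch
.class_fw <- function(model, X, B, N, training) {
  cfg <- model$cfg
  tr <- .trunk_fw(model$params, cfg, X, B, N, training)
  pl <- .pool_fw(tr$gm, B, N, cfg$pooling)
  hd <- .head_fw(pl$out, model$params$head, cfg$activation, cfg$dropout,
                 training)
  list(logits = hd$out, w = tr$w,
       cache = list(trunk = tr$cache, pool = pl$cache, head = hd$cache),
       running = c(tr$running, list(head = hd$running)))
}

.class_bw <- function(dlogits, cache, model) {
  hb <- .head_bw(dlogits, cache$head)
  dgm <- .pool_bw(hb$dF, cache$pool)
  tg <- .trunk_bw(dgm, cache$trunk, model$params, model$cfg)
  c(tg, list(head = hb$grads))
}

# loss + gradients for one classification batch (labels 0-based)
.class_loss_grads <- function(model, X, B, N, labels, training = TRUE) {
  fw <- .class_fw(model, X, B, N, training)
  ls <- .xent(fw$logits, labels)
  grads <- .class_bw(ls$dlogits, fw$cache, model)
  list(loss = ls$loss, grads = grads, running = fw$running,
       logits = fw$logits)
}

# full segmentation forward; onehot is B x n_categories
.seg_fw <- function(model, X, B, N, onehot, training) {
  cfg <- model$cfg
  tr <- .trunk_fw(model$params, cfg, X, B, N, training)
  mx <- .maxk_fw(tr$gm, N)
  pooled <- pmax(mx$out, 0)
  rep_pt <- rep(seq_len(B), each = N)
  F0 <- cbind(onehot[rep_pt, , drop = FALSE], tr$gm,
              pooled[rep_pt, , drop = FALSE])
  hd <- .head_fw(F0, model$params$head, cfg$activation, cfg$dropout, training)
  list(logits = hd$out, w = tr$w,
       cache = list(trunk = tr$cache, mx = mx$cache,
                    prelu = (mx$out > 0), head = hd$cache,
                    ncat = ncol(onehot), cg = ncol(tr$gm), B = B, N = N),
       running = c(tr$running, list(head = hd$running)))
}

.seg_bw <- function(dlogits, cache, model) {
  hb <- .head_bw(dlogits, cache$head)
  ncat <- cache$ncat; cg <- cache$cg; B <- cache$B; N <- cache$N
  dgm <- hb$dF[, ncat + seq_len(cg), drop = FALSE]
  dpooled_pt <- hb$dF[, ncat + cg + seq_len(cg), drop = FALSE]
  dpooled <- rowsum(dpooled_pt, rep(seq_len(B), each = N), reorder = FALSE)
  dgm <- dgm + .maxk_bw(dpooled * cache$prelu, cache$mx)
  tg <- .trunk_bw(dgm, cache$trunk, model$params, model$cfg)
  c(tg, list(head = hb$grads))
}

.seg_loss_grads <- function(model, X, B, N, onehot, point_labels, training = TRUE) {
  fw <- .seg_fw(model, X, B, N, onehot, training)
  ls <- .xent(fw$logits, point_labels)
  grads <- .seg_bw(ls$dlogits, fw$cache, model)
  list(loss = ls$loss, grads = grads, running = fw$running,
       logits = fw$logits)
}

# write the running batch-norm statistics from a forward pass back into params
.absorb_running <- function(params, running) {
  for (l in seq_along(running$layers)) {
    r <- running$layers[[l]]
    if (!is.null(r)) { params$layers[[l]]$bn[c("rmean", "rvar")] <- r }
  }
  if (!is.null(running$global)) params$global$bn[c("rmean", "rvar")] <- running$global
  if (!is.null(running$mask)) params$mask$bn1[c("rmean", "rvar")] <- running$mask
  for (i in seq_along(running$head)) {
    r <- running$head[[i]]
    if (!is.null(r)) params$head$hidden[[i]]$bn[c("rmean", "rvar")] <- r
  }
  params
}

# ---- public forward interface ----------------------------------------------

.stack_clouds <- function(clouds) {
  ns <- vapply(clouds, n_points, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all clouds in a batch must have the same point count")
  X <- do.call(rbind, lapply(clouds, function(p) p$coords))
  list(X = X, B = length(clouds), N = ns[1L])
}

#' Classify a point cloud
#'
#' Runs the full classification forward pass in inference mode (running
#' batch-norm statistics, no dropout). The scores are raw logits; apply
#' softmax for probabilities. The output is invariant to the order of the
#' input points.
#'
#' @param cloud a \code{point_cloud} (or N x 3 matrix).
#' @param model a classification \code{pointattn_model}.
#' @return numeric vector of m class logits.
#' @export
classify_forward <- function(cloud, model) {
  stopifnot(inherits(model, "pointattn_model"),
            model$cfg$task == "classify")
  X <- .as_coords(cloud)
  fw <- .class_fw(model, X, 1L, nrow(X), training = FALSE)
  as.numeric(fw$logits)
}

#' Per-point part scores for a point cloud
#'
#' Runs the segmentation forward pass in inference mode. Equivariant: a
#' permutation of the input points permutes the output rows identically.
#'
#' @param cloud a \code{point_cloud} (or N x 3 matrix).
#' @param category_onehot one-hot vector of the object's category (length
#'   \code{n_categories}, sums to 1).
#' @param model a segmentation \code{pointattn_model}.
#' @return N x P matrix of part logits.
#' @export
segment_forward <- function(cloud, category_onehot, model) {
  stopifnot(inherits(model, "pointattn_model"),
            model$cfg$task == "segment")
  v <- as.numeric(category_onehot)
  if (length(v) != model$cfg$n_categories ||
      abs(sum(v) - 1) > 1e-8 || any(v < 0))
    stop("one-hot malformed")
  X <- .as_coords(cloud)
  fw <- .seg_fw(model, X, 1L, nrow(X), matrix(v, 1L), training = FALSE)
  fw$logits
}

#' Export the global attention mask of a cloud
#'
#' Returns the learned per-point soft attention weight in (0,1) used to
#' rescale the global feature — the quantity visualized to see which regions
#' the model considers characteristic. Deterministic given model and input.
#'
#' @param cloud a \code{point_cloud} (or N x 3 matrix).
#' @param model a \code{pointattn_model} with the attention mask enabled.
#' @return numeric vector of N weights in (0,1).
#' @export
export_attention <- function(cloud, model) {
  stopifnot(inherits(model, "pointattn_model"))
  if (!model$cfg$use_mask) stop("model was built without the attention mask")
  X <- .as_coords(cloud)
  tr <- .trunk_fw(model$params, model$cfg, X, 1L, nrow(X), training = FALSE)
  tr$w
}

# ---- parameter utilities ---------------------------------------------------

# named numeric leaves of a parameter tree, excluding running BN statistics;
# the traversal order is deterministic and shared with gradient trees
.param_leaves <- function(p, path = "") {
  if (is.list(p)) {
    out <- list()
    nms <- names(p)
    if (is.null(nms)) nms <- rep("", length(p))
    for (i in seq_along(p)) {
      nm <- nms[i]
      if (nm %in% c("rmean", "rvar") || is.null(p[[i]])) next
      key <- if (nm == "") as.character(i) else nm
      out <- c(out, .param_leaves(p[[i]], paste0(path, "/", key)))
    }
    out
  } else if (is.numeric(p)) {
    stats::setNames(list(p), path)
  } else {
    list()
  }
}

.flatten_params <- function(p) {
  unlist(lapply(.param_leaves(p), as.numeric), use.names = FALSE)
}

#' Number of learnable parameters of a model
#' @param model a \code{pointattn_model}.
#' @return integer parameter count (running statistics excluded).
#' @export
n_parameters <- function(model) {
  length(.flatten_params(model$params))
}

# zero-filled copy of a gradient tree (momentum buffer initialization)
.zeros_like <- function(g) {
  if (is.list(g))
    lapply(g, function(x) if (is.null(x)) NULL else .zeros_like(x))
  else 0 * g
}

# recursive SGD-with-momentum update; the gradient tree mirrors the
# learnable leaves of the parameter tree position by position (batch-norm
# running statistics sit after gamma/beta and are untouched)
.sgd_update <- function(params, grads, vel, lr, momentum, weight_decay) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.list(g)) {
      res <- .sgd_update(params[[i]], g, vel[[i]], lr, momentum, weight_decay)
      params[[i]] <- res$params
      vel[[i]] <- res$vel
    } else {
      v <- momentum * vel[[i]] + g + weight_decay * params[[i]]
      params[[i]] <- params[[i]] - lr * v
      vel[[i]] <- v
    }
  }
  list(params = params, vel = vel)
}

# ---- serialization ---------------------------------------------------------

#' Save a model checkpoint
#'
#' The checkpoint holds the full parameter set, the architecture
#' configuration and the seed record; \code{\link{load_model}} restores it
#' bit-exactly.
#'
#' @param model a \code{pointattn_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pointattn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file path written by \code{\link{save_model}}.
#' @return the restored \code{pointattn_model}.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "pointattn_model")) stop("not a pointattn checkpoint")
  m
}
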