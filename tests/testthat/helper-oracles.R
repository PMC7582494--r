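# Independent oracles, written naively (explicit loops, no shared code with
# the implementation) so they can arbitrate the vectorized/kernel paths.

# O(N^2) brute-force kNN: full sort of Euclidean distances per center with
# index tie-break, center first
brute_knn <- function(X, k) {
  N <- nrow(X)
  rows <- lapply(seq_len(N), function(i) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- -Inf
    as.integer(order(d, seq_len(N))[seq_len(k)])
  })
  matrix(unlist(rows), N, k, byrow = TRUE)
}

# plain edge convolution (no channel gate): kNN grouping, shared linear map
# on (x_j - x_i, x_i), batch normalization over all group entries, leaky
# activation, max over each group -- computed entry by entry
naive_edgeconv <- function(X, W, gamma, beta, k, slope = 0.2, eps = 1e-5) {
  N <- nrow(X)
  D <- ncol(X)
  C <- ncol(W)
  idx <- brute_knn(X, k)
  H <- array(NA_real_, c(N, k, C))
  for (i in seq_len(N)) {
    for (j in seq_len(k)) {
      e <- c(X[idx[i, j], ] - X[i, ], X[i, ])
      H[i, j, ] <- as.numeric(e %*% W)
    }
  }
  for (c in seq_len(C)) {
    v <- H[, , c]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    H[, , c] <- (v - mu) / sqrt(s2 + eps) * gamma[c] + beta[c]
  }
  H <- ifelse(H > 0, H, slope * H)
  out <- matrix(NA_real_, N, C)
  for (i in seq_len(N)) for (c in seq_len(C)) out[i, c] <- max(H[i, , c])
  out
}

# brute-force accuracy counting
naive_accuracy <- function(labels, preds, m) {
  oa <- 100 * sum(labels == preds) / length(labels)
  recalls <- c()
  for (cl in 0:(m - 1)) {
    sel <- which(labels == cl)
    if (length(sel) > 0)
      recalls <- c(recalls, 100 * sum(preds[sel] == cl) / length(sel))
  }
  list(oa = oa, mca = mean(recalls))
}

# brute-force part IoU for one shape
naive_shape_iou <- function(pred, gt, parts) {
  ious <- c()
  for (p in parts) {
    inter <- sum(pred == p & gt == p)
    uni <- sum(pred == p | gt == p)
    ious <- c(ious, if (uni == 0) 1 else inter / uni)
  }
  mean(ious)
}

random_cloud <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * 3), n, 3)
}

# small classifier configuration used across tests
tiny_classifier <- function(seed = 7, n_classes = 3, dropout = 0,
                            graph = "coords", ...) {
  cfg <- classifier_config(n_classes = n_classes, layers = c(6L, 6L), k = 4L,
                           global_width = 12L, mask_hidden = 8L,
                           head = c(8L, 8L), dropout = dropout,
                           graph = graph, ...)
  init_classifier(cfg, seed = seed)
}

tiny_segmenter <- function(seed = 7, n_parts = 5, n_categories = 2, ...) {
  cfg <- segmenter_config(n_parts = n_parts, n_categories = n_categories,
                          layers = c(6L, 6L), k = 4L, global_width = 12L,
                          mask_hidden = 8L, seg_head = c(8L, 8L, 8L),
                          dropout = 0, ...)
  init_segmenter(cfg, seed = seed)
}
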