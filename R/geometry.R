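#' k-nearest-neighbor grouping of a point set
#'
#' For every point, forms a group of size \code{k} consisting of the point
#' itself (stored first) and its \code{k - 1} nearest neighbors under the
#' Euclidean metric. Distance ties are broken by ascending point index, so the
#' grouping is deterministic.
#'
#' @param features N x D numeric matrix (or a \code{point_cloud}, whose
#'   coordinates are used). The metric space may be raw coordinates or a
#'   layer's learned feature space (dynamic graph).
#' @param k group size, \code{1 <= k <= N}.
#' @param metric_space tag recording which space the query ran in,
#'   \code{"coords"} or \code{"features"}.
#' @return A \code{nbr_index}: list with \code{indices} (N x k integer matrix
#'   of 1-based point indices, column 1 the center itself), \code{k} and
#'   \code{metric_space}.
#' @examples
#' pts <- matrix(c(0, 0, 0, 1, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
#' knn_group(pts, 2)$indices
#' @export
knn_group <- function(features, k, metric_space = c("coords", "features")) {
  metric_space <- match.arg(metric_space)
  X <- .as_coords(features)
  if (!all(is.finite(X))) stop("features must be finite")
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(X)) stop("group size exceeds point count")
  idx <- .knn_indices(X, k)
  structure(list(indices = idx, k = k, metric_space = metric_space),
            class = "nbr_index")
}

#' @export
print.nbr_index <- function(x, ...) {
  cat(sprintf("<nbr_index> %d groups of size %d (metric: %s)\n",
              nrow(x$indices), x$k, x$metric_space))
  invisible(x)
}

# Core kNN query. Exact squared Euclidean distances with partial selection;
# ordering is lexicographic on (distance, point index), so ties break by
# ascending index and the result is deterministic. O(N^2 (D + log k)).
.knn_indices <- function(X, k) {
  .c_knn_idx(X, as.integer(k))
}

.check_nbr <- function(nbr, N) {
  if (!inherits(nbr, "nbr_index")) stop("nbr must be a nbr_index")
  if (any(nbr$indices < 1L) || any(nbr$indices > N))
    stop("neighborhood index out of range")
}

# ---- grouped feature container ---------------------------------------------

.grouped_feature <- function(values) {
  structure(list(values = values, channels = dim(values)[3L]),
            class = "grouped_feature")
}

#' @export
print.grouped_feature <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grouped_feature> %d x %d x %d (points x group x channels)\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

# flat layout used by the network internals: (N*k) x C matrix, rows ordered
# point-major with the neighbor axis varying fastest
.flat_to_array <- function(M, N, k) {
  C <- ncol(M)
  A <- array(0, c(N, k, C))
  for (c in seq_len(C)) A[, , c] <- matrix(M[, c], N, k, byrow = TRUE)
  A
}

.array_to_flat <- function(A) {
  d <- dim(A)
  M <- matrix(0, d[1L] * d[2L], d[3L])
  for (c in seq_len(d[3L])) M[, c] <- as.vector(t(A[, , c]))
  M
}

# flat neighbor / center index vectors for a (possibly batched) index matrix
.flat_nbrs <- function(idx) as.vector(t(idx))
.flat_centers <- function(idx) rep(seq_len(nrow(idx)), each = ncol(idx))

# ---- fixed feature constructions -------------------------------------------

# edge pairs (x_j - x_i, x_i) in flat layout; P is (N or B*N) x D
.edge_mat <- function(P, idx) {
  .c_edge_gather(P, idx)
}

# 10-channel geometric descriptor [x_i, x_j, x_j - x_i, ||x_j - x_i||]
.geom_mat <- function(coords, idx) {
  xj <- coords[.flat_nbrs(idx), , drop = FALSE]
  xi <- coords[.flat_centers(idx), , drop = FALSE]
  d <- xj - xi
  cbind(xi, xj, d, sqrt(rowSums(d^2)))
}

#' Edge features of a grouped point set
#'
#' For each group center \eqn{x_i} and neighbor \eqn{x_j}, stacks the pair
#' \eqn{(x_j - x_i, x_i)} — the relative edge vector plus the absolute center
#' position — doubling the channel count. This is the standard edge-feature
#' choice of dynamic-graph edge convolution.
#'
#' @param point_feats N x D numeric matrix of per-point features.
#' @param nbr a \code{nbr_index} over the same N points.
#' @return A \code{grouped_feature} with values N x k x 2D.
#' @export
edge_features <- function(point_feats, nbr) {
  P <- .as_coords(point_feats)
  .check_nbr(nbr, nrow(P))
  M <- .edge_mat(P, nbr$indices)
  .grouped_feature(.flat_to_array(M, nrow(P), nbr$k))
}

#' Low-order geometric descriptor of a grouped point set
#'
#' Per group entry: the center \eqn{x_i}, the neighbor \eqn{x_j}, their
#' difference and the Euclidean distance \eqn{\|x_j - x_i\|_2} — 10 channels.
#' Feeding the distance explicitly spares the attention MLP from having to
#' approximate it, which speeds up learning of the point-wise mask.
#'
#' @param coords N x 3 coordinate matrix (or a \code{point_cloud}).
#' @param nbr a \code{nbr_index} over the same N points.
#' @return A \code{grouped_feature} with values N x k x 10.
#' @export
geometric_descriptor <- function(coords, nbr) {
  X <- .as_coords(coords)
  if (ncol(X) != 3L) stop("coords must be 3-D")
  .check_nbr(nbr, nrow(X))
  M <- .geom_mat(X, nbr$indices)
  .grouped_feature(.flat_to_array(M, nrow(X), nbr$k))
}

#' Distance-free spatial descriptor of a grouped point set
#'
#' The 9-channel variant \eqn{[x_i, x_j, x_j - x_i]} used by the
#' spatial-attention edge convolution. The Euclidean-distance channel is
#' deliberately omitted: its gradient is unbounded as two points coincide,
#' which destabilizes training of the mask branch.
#'
#' @inheritParams geometric_descriptor
#' @return A \code{grouped_feature} with values N x k x 9.
#' @export
spatial_descriptor <- function(coords, nbr) {
  X <- .as_coords(coords)
  if (ncol(X) != 3L) stop("coords must be 3-D")
  .check_nbr(nbr, nrow(X))
  M <- .geom_mat(X, nbr$indices)[, 1:9, drop = FALSE]
  .grouped_feature(.flat_to_array(M, nrow(X), nbr$k))
}
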