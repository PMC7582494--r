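# Learnable blocks. Public constructors build plain parameter lists that the
# functional layer ops consume; the same parameter layout is embedded in full
# model states, so every block can also be exercised in isolation.
#
# The functional ops here run on a single cloud with batch-normalization
# statistics computed from the given input (training-style normalization);
# full networks additionally maintain running statistics for inference.

#' Squeeze-and-excitation channel gate parameters
#'
#' The gate recalibrates each feature channel by a scalar in (0,1): channels
#' are averaged over all spatial positions (squeeze), passed through a
#' two-stage full-width excitation map with a nonlinearity between, and
#' squashed by a sigmoid. Unlike the original squeeze-and-excitation design
#' there is no bottleneck reduction — the excitation keeps the layer's full
#' channel width, because shrinking it limits what the gate can express.
#'
#' @param channels number of feature channels the gate acts on.
#' @param dims \code{"grouped"} for N x k x C grouped features,
#'   \code{"point"} for per-point N x C features. The tag is informational;
#'   the squeeze always averages over every spatial position.
#' @param activation nonlinearity between the excitation stages.
#' @param init \code{"glorot"} for random weights or \code{"zero"} (all
#'   excitation weights and biases zero, so every gate scalar is exactly
#'   sigmoid(0) = 0.5).
#' @param seed optional seed for reproducible initialization.
#' @return A \code{channel_gate} parameter list.
#' @export
channel_gate <- function(channels, dims = c("grouped", "point"),
                         activation = c("leaky", "relu"),
                         init = c("glorot", "zero"), seed = NULL) {
  dims <- match.arg(dims)
  activation <- match.arg(activation)
  init <- match.arg(init)
  p <- .with_seed(seed, .init_se(channels, zero = (init == "zero")))
  structure(c(p, list(channels = channels, dims = dims,
                      activation = activation)),
            class = "channel_gate")
}

#' Apply a squeeze-and-excitation channel gate
#'
#' @param features a \code{grouped_feature} (N x k x C) or an N x C numeric
#'   matrix of per-point features.
#' @param gate a \code{channel_gate} with matching channel count.
#' @return The gated features, same type and shape as the input, with the
#'   per-channel gate scalars attached as attribute \code{"gate_scalars"}.
#' @export
se_gate <- function(features, gate) {
  stopifnot(inherits(gate, "channel_gate"))
  grouped <- inherits(features, "grouped_feature")
  M <- if (grouped) .array_to_flat(features$values) else as.matrix(features)
  if (ncol(M) != gate$channels)
    stop(sprintf("channel mismatch: features have %d channels, gate expects %d",
                 ncol(M), gate$channels))
  fw <- .se_fw(M, gate, grp = rep(1L, nrow(M)), gs = nrow(M),
               act = gate$activation)
  if (grouped) {
    d <- dim(features$values)
    out <- .grouped_feature(.flat_to_array(fw$out, d[1L], d[2L]))
  } else {
    out <- fw$out
  }
  attr(out, "gate_scalars") <- as.numeric(fw$s)
  out
}

#' Parameters of one channel-weighted edge convolution layer
#'
#' Holds the shared MLP (a 1 x 1 convolution over edge features, so input
#' width is \code{2 * c_in}), its batch normalization, the activation tag and
#' the channel gate. Setting \code{use_se = FALSE} omits the gate, reducing
#' the layer to a plain edge convolution.
#'
#' @param c_in per-point input channel count (edge features double it).
#' @param c_out output channel count.
#' @param activation \code{"leaky"} (slope 0.2, the default used throughout)
#'   or \code{"relu"}.
#' @param use_se include the squeeze-and-excitation gate?
#' @param seed optional seed for reproducible initialization.
#' @return A \code{layer_params} list.
#' @export
layer_params <- function(c_in, c_out, activation = c("leaky", "relu"),
                         use_se = TRUE, seed = NULL) {
  activation <- match.arg(activation)
  .with_seed(seed, {
    structure(list(dense = .init_dense(2L * c_in, c_out, bias = FALSE),
                   bn = .init_bn(c_out),
                   se = if (use_se) .init_se(c_out) else NULL,
                   activation = activation,
                   c_in = c_in, c_out = c_out),
              class = "layer_params")
  })
}

# shared single-cloud layer pipeline: edge features -> shared MLP -> BN ->
# activation -> optional SE gate -> max over the neighbor axis
.cw_forward_single <- function(P, idx, p, training = TRUE) {
  k <- ncol(idx)
  E <- .edge_mat(P, idx)
  d <- .dense_fw(E, p$dense)
  bn <- .bn_fw(d$out, p$bn, training)
  a <- .act_fw(bn$out, p$activation)
  h <- a$out
  if (!is.null(p$se)) {
    se <- .se_fw(h, p$se, grp = rep(1L, nrow(h)), gs = nrow(h),
                 act = p$activation)
    h <- se$out
  }
  .maxk_fw(h, k)$out
}

#' Channel-weighted edge convolution
#'
#' One layer of the trunk: a kNN query groups the points, edge features
#' \eqn{(x_j - x_i, x_i)} are lifted by a shared MLP with batch normalization
#' and the layer activation, the channel gate rescales each channel, and a
#' max over each group aggregates neighbors into a single per-point feature.
#' The aggregation is a max, not a sum, following the point-set network
#' convention: the strongest edge response characterizes the neighborhood.
#'
#' @param point_feats N x D matrix of per-point features (coordinates for the
#'   first layer; learned features — the dynamic graph — for deeper layers).
#' @param params a \code{layer_params} with \code{c_in = D}.
#' @param k group size for the kNN query.
#' @param nbr optional precomputed \code{nbr_index}; when \code{NULL} the
#'   query runs on \code{point_feats}.
#' @return N x \code{c_out} matrix of per-point output features.
#' @export
cw_edgeconv <- function(point_feats, params, k, nbr = NULL) {
  stopifnot(inherits(params, "layer_params"))
  P <- .as_coords(point_feats)
  if (ncol(P) != params$c_in)
    stop(sprintf("expected %d input channels, got %d", params$c_in, ncol(P)))
  if (is.null(nbr)) nbr <- knn_group(P, k, metric_space = "features")
  .check_nbr(nbr, nrow(P))
  .cw_forward_single(P, nbr$indices, params)
}

#' First-layer channel-weighted edge convolution with geometric side output
#'
#' Identical to \code{\link{cw_edgeconv}} on raw coordinates, but additionally
#' returns the 10-channel geometric descriptor of the same grouping, which
#' feeds the global attention module. Both outputs share one kNN query.
#'
#' @param coords N x 3 coordinate matrix (or a \code{point_cloud}).
#' @param params a \code{layer_params} with \code{c_in = 3}.
#' @param k group size.
#' @return list with \code{features} (N x \code{c_out}), \code{descriptor}
#'   (a 10-channel \code{grouped_feature}) and \code{nbr} (the shared
#'   \code{nbr_index}).
#' @export
cw_edgeconv_pp <- function(coords, params, k) {
  X <- .as_coords(coords)
  if (ncol(X) != 3L) stop("coords must be 3-D")
  nbr <- knn_group(X, k, metric_space = "coords")
  list(features = cw_edgeconv(X, params, k, nbr = nbr),
       descriptor = geometric_descriptor(X, nbr),
       nbr = nbr)
}

#' Parameters of the global feature builder
#'
#' @param c_in total input channel count (the concatenated layer outputs).
#' @param c_out global feature width.
#' @param activation nonlinearity tag.
#' @param use_se include the per-point 1-d channel gate?
#' @param seed optional seed.
#' @return A \code{global_params} list.
#' @export
global_params <- function(c_in, c_out, activation = c("leaky", "relu"),
                          use_se = TRUE, seed = NULL) {
  activation <- match.arg(activation)
  .with_seed(seed, {
    structure(list(dense = .init_dense(c_in, c_out, bias = FALSE),
                   bn = .init_bn(c_out),
                   se = if (use_se) .init_se(c_out) else NULL,
                   activation = activation,
                   c_in = c_in, c_out = c_out),
              class = "global_params")
  })
}

#' Per-point global feature from stacked layer outputs
#'
#' Concatenates the configured edge-convolution outputs along channels,
#' lifts them with a shared MLP (batch normalization + activation) and
#' applies a per-point 1-d channel gate. By default the full trunk output is
#' consumed; passing a single matrix reproduces the narrower variant that
#' uses only the last layer.
#'
#' @param layer_outputs a list of N x C_l matrices (or a single matrix).
#' @param params a \code{global_params} whose \code{c_in} equals the summed
#'   channel count.
#' @return N x \code{c_out} global feature matrix.
#' @export
global_feature <- function(layer_outputs, params) {
  stopifnot(inherits(params, "global_params"))
  if (is.matrix(layer_outputs)) layer_outputs <- list(layer_outputs)
  ns <- vapply(layer_outputs, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("layer outputs disagree on point count")
  H <- do.call(cbind, layer_outputs)
  if (ncol(H) != params$c_in)
    stop(sprintf("expected %d input channels, got %d", params$c_in, ncol(H)))
  d <- .dense_fw(H, params$dense)
  bn <- .bn_fw(d$out, params$bn, training = TRUE)
  a <- .act_fw(bn$out, params$activation)
  h <- a$out
  if (!is.null(params$se)) {
    h <- .se_fw(h, params$se, grp = rep(1L, nrow(h)), gs = nrow(h),
                act = params$activation)$out
  }
  h
}

#' Parameters of the point-wise attention mask branch
#'
#' Two shared 1 x 1 MLP stages reduce the 10-channel geometric descriptor to
#' a single response per group entry; batch normalization sits after the
#' first stage, before the activation. The internal width is not dictated by
#' the architecture; 64 is the default here.
#'
#' @param hidden width of the intermediate stage.
#' @param in_channels descriptor channel count (10 for the distance-carrying
#'   descriptor, 9 for the distance-free spatial variant).
#' @param activation nonlinearity tag.
#' @param zero_final zero the final stage's weights and bias (every sigmoid
#'   response is then exactly 0.5).
#' @param seed optional seed.
#' @return A \code{mask_params} list.
#' @export
mask_params <- function(hidden = 64L, in_channels = 10L,
                        activation = c("leaky", "relu"),
                        zero_final = FALSE, seed = NULL) {
  activation <- match.arg(activation)
  .with_seed(seed, {
    d2 <- .init_dense(hidden, 1L)
    if (zero_final) { d2$W[] <- 0; d2$b[] <- 0 }
    structure(list(d1 = .init_dense(in_channels, hidden, bias = FALSE),
                   bn1 = .init_bn(hidden),
                   d2 = d2,
                   activation = activation,
                   in_channels = as.integer(in_channels),
                   hidden = as.integer(hidden)),
              class = "mask_params")
  })
}

# shared mask-branch pipeline up to the per-entry sigmoid response
.mask_responses <- function(M, mp, training = TRUE) {
  d1 <- .dense_fw(M, mp$d1)
  bn <- .bn_fw(d1$out, mp$bn1, training)
  a <- .act_fw(bn$out, mp$activation)
  d2 <- .dense_fw(a$out, mp$d2)
  .sigmoid_fw(d2$out)$out
}

.mask_desc_flat <- function(desc, mp) {
  if (!inherits(desc, "grouped_feature")) stop("desc must be a grouped_feature")
  if (desc$channels != mp$in_channels)
    stop(sprintf("descriptor has %d channels, mask branch expects %d",
                 desc$channels, mp$in_channels))
  .array_to_flat(desc$values)
}

#' Soft point-wise attention mask
#'
#' Computes, for every point, the maximum sigmoid response of its group's
#' geometric descriptor entries under the two-stage mask MLP. The result is a
#' weight strictly inside (0,1) per point, later multiplied into the global
#' feature to emphasize characteristic regions (corners, boundaries, straps)
#' and damp redundant ones.
#'
#' @param desc a 10-channel \code{grouped_feature} from
#'   \code{\link{geometric_descriptor}}.
#' @param params a \code{mask_params}.
#' @return An \code{attention_mask} with \code{mode = "soft"}.
#' @export
global_attention_mask <- function(desc, params) {
  stopifnot(inherits(params, "mask_params"))
  M <- .mask_desc_flat(desc, params)
  s <- .mask_responses(M, params)
  k <- dim(desc$values)[2L]
  w <- as.numeric(.maxk_fw(s, k)$out)
  structure(list(weights = w, mode = "soft"), class = "attention_mask")
}

#' Hard (boolean) point-wise attention mask
#'
#' Averages the sigmoid responses over each group and thresholds at 0.5
#' (inclusive: a mean response of exactly 0.5 keeps the point). Points below
#' threshold are suppressed entirely when the mask is applied.
#'
#' @inheritParams global_attention_mask
#' @return An \code{attention_mask} with \code{mode = "hard"} and weights in
#'   \{0, 1\}.
#' @export
hard_attention_mask <- function(desc, params) {
  stopifnot(inherits(params, "mask_params"))
  M <- .mask_desc_flat(desc, params)
  s <- .mask_responses(M, params)
  k <- dim(desc$values)[2L]
  m <- as.numeric(.meank_fw(s, k)$out)
  structure(list(weights = as.numeric(m >= 0.5), mode = "hard"),
            class = "attention_mask")
}

#' @export
print.attention_mask <- function(x, ...) {
  cat(sprintf("<attention_mask> %s, %d points, weights in [%.3g, %.3g]\n",
              x$mode, length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Parameters of a spatial-attention edge convolution
#'
#' @param c_in per-point input channel count of the edge-convolution branch.
#' @param c_out output channel count.
#' @param hidden intermediate width of the mask branch.
#' @param activation nonlinearity tag.
#' @param seed optional seed.
#' @return An \code{sa_params} list.
#' @export
sa_params <- function(c_in, c_out, hidden = 64L,
                      activation = c("leaky", "relu"), seed = NULL) {
  activation <- match.arg(activation)
  .with_seed(seed, {
    structure(list(dense = .init_dense(2L * c_in, c_out, bias = FALSE),
                   bn = .init_bn(c_out),
                   mask = mask_params(hidden = hidden, in_channels = 9L,
                                      activation = activation),
                   activation = activation,
                   c_in = c_in, c_out = c_out),
              class = "sa_params")
  })
}

#' Spatial-attention edge convolution
#'
#' Two branches over one kNN grouping (computed in the feature space of
#' \code{point_feats}): a plain edge convolution, and a mask branch that maps
#' the distance-free 9-channel spatial descriptor of the coordinates through
#' a shared MLP (with batch normalization), a sigmoid and a max over the
#' group, yielding one soft weight per point. The output is the edge
#' convolution rescaled point-wise by that weight, so each entry is a
#' contraction of the plain edge convolution.
#'
#' @param coords N x 3 coordinates used by the mask branch.
#' @param point_feats N x D features consumed by the edge-convolution branch
#'   and the kNN query.
#' @param params an \code{sa_params} with \code{c_in = D}.
#' @param k group size.
#' @return N x \code{c_out} matrix; the per-point mask is attached as
#'   attribute \code{"mask"}.
#' @export
spatial_attention_edgeconv <- function(coords, point_feats, params, k) {
  stopifnot(inherits(params, "sa_params"))
  X <- .as_coords(coords)
  if (ncol(X) != 3L) stop("coords must be 3-D")
  P <- .as_coords(point_feats)
  if (ncol(P) != params$c_in)
    stop(sprintf("expected %d input channels, got %d", params$c_in, ncol(P)))
  if (nrow(P) != nrow(X)) stop("coords and point_feats disagree on N")
  nbr <- knn_group(P, k, metric_space = "features")
  # upper branch: plain edge convolution (no channel gate)
  E <- .edge_mat(P, nbr$indices)
  d <- .dense_fw(E, params$dense)
  bn <- .bn_fw(d$out, params$bn, training = TRUE)
  a <- .act_fw(bn$out, params$activation)
  ec <- .maxk_fw(a$out, k)$out
  # lower branch: soft mask from the distance-free descriptor
  C9 <- .geom_mat(X, nbr$indices)[, 1:9, drop = FALSE]
  s <- .mask_responses(C9, params$mask)
  w <- as.numeric(.maxk_fw(s, k)$out)
  out <- ec * w
  attr(out, "mask") <- w
  out
}

#' Apply a point-wise attention mask to a global feature
#'
#' Element-wise multiplication of each point's feature row by its mask weight
#' (broadcast over channels), followed by a ReLU.
#'
#' @param g N x C global feature matrix.
#' @param mask an \code{attention_mask} or numeric weight vector of length N.
#' @return N x C masked feature matrix.
#' @export
apply_mask <- function(g, mask) {
  g <- as.matrix(g)
  w <- if (inherits(mask, "attention_mask")) mask$weights else as.numeric(mask)
  if (length(w) != nrow(g))
    stop(sprintf("mask length %d does not match %d points", length(w), nrow(g)))
  pmax(g * w, 0)
}
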