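# Low-level differentiable primitives. Every *_fw returns list(out, cache)
# and the matching *_bw consumes the upstream gradient plus that cache and
# returns parameter gradients and/or the input gradient. Feature matrices are
# rows = positions (points, or point-neighbor pairs), columns = channels.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# run expr with a temporary RNG state seeded at `seed`; restores the caller's
# stream so parameter init does not perturb data-generation reproducibility
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# broadcast a per-channel vector across n rows: returns the recycling vector
# rep(v, each = n), which aligns with column-major matrix layout, so
# `X op .rowrep(v, nrow(X))` applies v column-wise without a matrix copy
.rowrep <- function(v, n) rep(v, each = n)

# ---- parameter constructors ------------------------------------------------

# Glorot-uniform weights, zero bias; layers immediately followed by batch
# normalization take bias = FALSE (the shift is absorbed by BN's beta, so a
# bias there would be a dead parameter)
.init_dense <- function(c_in, c_out, bias = TRUE) {
  lim <- sqrt(6 / (c_in + c_out))
  list(W = matrix(stats::runif(c_in * c_out, -lim, lim), c_in, c_out),
       b = if (bias) numeric(c_out) else NULL)
}

.init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       rmean = numeric(c_out), rvar = rep(1, c_out))
}

# full-width two-stage excitation (no bottleneck reduction)
.init_se <- function(c_out, zero = FALSE) {
  if (zero) {
    list(W1 = matrix(0, c_out, c_out), b1 = numeric(c_out),
         W2 = matrix(0, c_out, c_out), b2 = numeric(c_out))
  } else {
    c(stats::setNames(.init_dense(c_out, c_out), c("W1", "b1")),
      stats::setNames(.init_dense(c_out, c_out), c("W2", "b2")))
  }
}

# ---- dense (shared 1x1 convolution) ----------------------------------------

.dense_fw <- function(X, p) {
  Y <- X %*% p$W
  if (!is.null(p$b)) Y <- Y + .rowrep(p$b, nrow(Y))
  list(out = Y, cache = list(X = X, W = p$W, has_b = !is.null(p$b)))
}

.dense_bw <- function(dY, cache) {
  list(dW = crossprod(cache$X, dY),
       db = if (cache$has_b) colSums(dY) else NULL,
       dX = dY %*% t(cache$W))
}

# ---- batch normalization ---------------------------------------------------

# training mode normalizes with the batch statistics (biased variance) and
# returns updated running statistics; eval mode uses the stored running
# stats. Backward is only defined for training-mode caches (inference passes
# are never differentiated).
.bn_fw <- function(X, p, training) {
  if (training) {
    f <- .c_bn_train_fw(X, p$gamma, p$beta, .bn_eps)
    upd <- list(rmean = (1 - .bn_momentum) * p$rmean + .bn_momentum * f$mu,
                rvar = (1 - .bn_momentum) * p$rvar + .bn_momentum * f$var)
    list(out = f$out,
         cache = list(xhat = f$xhat, inv = f$inv, gamma = p$gamma),
         running = upd)
  } else {
    list(out = .c_bn_eval_fw(X, p$gamma, p$beta, p$rmean, p$rvar, .bn_eps),
         cache = NULL, running = NULL)
  }
}

.bn_bw <- function(dY, cache) {
  b <- .c_bn_train_bw(dY, cache$xhat, cache$inv, cache$gamma)
  list(dgamma = b$dgamma, dbeta = b$dbeta, dX = b$dX)
}

# ---- activations -----------------------------------------------------------

.act_slope <- function(act) if (act == "relu") 0 else 0.2

.act_fw <- function(X, act) {
  s <- .act_slope(act)
  list(out = .c_leaky_fw(X, s), cache = list(X = X, slope = s))
}

.act_bw <- function(dY, cache) .c_leaky_bw(dY, cache$X, cache$slope)

.sigmoid_fw <- function(X) {
  s <- 1 / (1 + exp(-X))
  list(out = s, cache = s)
}

.sigmoid_bw <- function(dY, cache) dY * cache * (1 - cache)

# ---- squeeze-and-excitation channel gate -----------------------------------

# M: rows x C feature matrix; grp: integer sample id per row (contiguous
# blocks 1..B); gs: rows per sample. Squeeze averages each channel over all
# positions of a sample; excitation is two full-width dense stages with the
# layer activation between and a sigmoid after, giving one per-channel scalar
# gate s_c in (0,1) per sample.
.se_fw <- function(M, p, grp, gs, act) {
  B <- grp[length(grp)]
  z <- .c_group_colsum(M, grp, B) / gs
  d1 <- .dense_fw(z, list(W = p$W1, b = p$b1))
  a1 <- .act_fw(d1$out, act)
  d2 <- .dense_fw(a1$out, list(W = p$W2, b = p$b2))
  s <- .sigmoid_fw(d2$out)
  out <- .c_group_scale(M, s$out, grp)
  list(out = out, s = s$out,
       cache = list(M = M, grp = grp, gs = gs, B = B, d1 = d1$cache,
                    a1 = a1$cache, d2 = d2$cache, sg = s$cache, s = s$out))
}

.se_bw <- function(dY, cache) {
  grp <- cache$grp
  dM <- .c_group_scale(dY, cache$s, grp)
  ds <- .c_group_dot(dY, cache$M, grp, cache$B)
  dz2 <- .sigmoid_bw(ds, cache$sg)
  g2 <- .dense_bw(dz2, cache$d2)
  dz1 <- .act_bw(g2$dX, cache$a1)
  g1 <- .dense_bw(dz1, cache$d1)
  dz <- g1$dX / cache$gs
  dM <- dM + dz[grp, , drop = FALSE]
  list(dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db, dM = dM)
}

# ---- reductions over the neighbor axis -------------------------------------

# E: (n*k) x C in flat layout (neighbor varies fastest). Max per group and
# channel, tracking the argmax for the backward scatter.
.maxk_fw <- function(E, k) {
  f <- .c_maxk_fw(E, k)
  list(out = f$out, cache = list(amax = f$amax, k = k))
}

.maxk_bw <- function(dY, cache) {
  .c_maxk_bw(dY, cache$amax, cache$k)
}

.meank_fw <- function(E, k) {
  n <- nrow(E) / k
  grp <- rep(seq_len(n), each = k)
  list(out = rowsum(E, grp, reorder = FALSE) / k,
       cache = list(k = k, n = n))
}

.meank_bw <- function(dY, cache) {
  (dY / cache$k)[rep(seq_len(cache$n), each = cache$k), , drop = FALSE]
}

# ---- dropout ---------------------------------------------------------------

# inverted dropout; identity when rate == 0 or not training
.drop_fw <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X))
  scale <- 1 / (1 - rate)
  list(out = X * keep * scale, cache = keep * scale)
}

.drop_bw <- function(dY, cache) {
  if (is.null(cache)) return(dY)
  dY * cache
}

# ---- loss ------------------------------------------------------------------

# mean cross-entropy of raw logits against 0-based integer labels;
# returns loss value and gradient wrt logits
.xent <- function(logits, labels) {
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  sm <- ex / rowSums(ex)
  li <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(sm[li], 1e-300)))
  dlog <- sm
  dlog[li] <- dlog[li] - 1
  list(loss = loss, dlogits = dlog / n)
}
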