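# Finite-difference gradient checker: compares an analytic gradient tree
# against central differences of `lossfun`, tensor by tensor (optionally
# subsampling elements of large tensors), and returns the worst per-tensor
# relative error.

fd_check <- function(model, lossfun, grads, h = 1e-6, max_per_tensor = Inf,
                     seed = 99) {
  pl <- pointattn:::.param_leaves(model$params)
  gl <- pointattn:::.param_leaves(grads)
  expect_identical(names(pl), names(gl))
  set.seed(seed)
  set_leaf <- function(params, path, value) {
    keys <- strsplit(sub("^/", "", path), "/")[[1]]
    rec <- function(p, keys) {
      k <- keys[1]
      ki <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      if (length(keys) == 1) { p[[ki]] <- value; return(p) }
      p[[ki]] <- rec(p[[ki]], keys[-1])
      p
    }
    rec(params, keys)
  }
  worst <- 0
  for (nm in names(pl)) {
    v <- pl[[nm]]
    ga <- as.numeric(gl[[nm]])
    els <- seq_along(v)
    if (length(els) > max_per_tensor) els <- sample(els, max_per_tensor)
    gn <- ga
    for (i in els) {
      vp <- v; vp[i] <- v[i] + h
      m1 <- model; m1$params <- set_leaf(m1$params, nm, vp)
      vp[i] <- v[i] - h
      m2 <- model; m2$params <- set_leaf(m2$params, nm, vp)
      gn[i] <- (lossfun(m1) - lossfun(m2)) / (2 * h)
    }
    rel <- sqrt(sum((ga[els] - gn[els])^2)) /
      (sqrt(sum(ga[els]^2)) + sqrt(sum(gn[els]^2)) + 1e-10)
    worst <- max(worst, rel)
  }
  worst
}

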