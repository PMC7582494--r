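# Synthetic labeled point clouds with the statistical structure the network
# assumes: single-object surface samples (the CAD-model style) and fixed-size
# density-volume samples (the cryo-tomography style). Shapes are generated
# directly at their analytically unit-normalized size (farthest surface point
# at radius 1, centered), so the normalization invariants hold exactly before
# jitter.

.shape_families <- c("sphere", "cube", "torus", "cylinder", "cone")

#' Specification of a synthetic object-surface cloud
#'
#' @param family one of \code{"sphere"}, \code{"cube"}, \code{"torus"},
#'   \code{"cylinder"}, \code{"cone"}.
#' @param n points per cloud.
#' @param sigma standard deviation of additive Gaussian jitter, in normalized
#'   units (default 0.01).
#' @param seed optional seed; clouds are pure functions of it.
#' @return A \code{shape_spec} list.
#' @export
shape_spec <- function(family, n = 1024L, sigma = 0.01, seed = NULL) {
  if (!family %in% .shape_families)
    stop(sprintf("unknown family '%s'", family))
  structure(list(family = family, n = as.integer(n), sigma = sigma,
                 seed = seed),
            class = "shape_spec")
}

# uniform surface samples of each family; returns list(coords, parts)
# sphere: radius 1.  cube: half-side 1/sqrt(3) (corner radius 1).
# torus: R=0.75, r=0.25.  cylinder: radius 0.5, half-height sqrt(3)/2,
# parts side/top/bottom.  cone: base radius 0.6, apex height 0.8, parts
# side/base.
.sample_surface <- function(family, n) {
  if (family == "sphere") {
    v <- matrix(stats::rnorm(3L * n), n, 3L)
    co <- v / sqrt(rowSums(v^2))
    return(list(coords = co, parts = NULL))
  }
  if (family == "cube") {
    s <- 1 / sqrt(3)
    face <- sample.int(6L, n, replace = TRUE)
    u <- stats::runif(n, -s, s); v <- stats::runif(n, -s, s)
    co <- matrix(0, n, 3L)
    ax <- (face - 1L) %/% 2L + 1L       # fixed axis 1..3
    sgn <- ifelse(face %% 2L == 1L, s, -s)
    for (i in seq_len(n)) {
      rest <- setdiff(1:3, ax[i])
      co[i, ax[i]] <- sgn[i]
      co[i, rest] <- c(u[i], v[i])
    }
    return(list(coords = co, parts = NULL))
  }
  if (family == "torus") {
    R <- 0.75; r <- 0.25
    u <- stats::runif(n, 0, 2 * pi)
    # rejection sampling for uniform area: density of the tube angle v is
    # proportional to R + r*cos(v)
    v <- numeric(n); got <- 0L
    while (got < n) {
      cand <- stats::runif(n, 0, 2 * pi)
      acc <- stats::runif(n) < (R + r * cos(cand)) / (R + r)
      take <- cand[acc]
      m <- min(length(take), n - got)
      if (m > 0L) { v[(got + 1L):(got + m)] <- take[seq_len(m)]; got <- got + m }
    }
    co <- cbind((R + r * cos(v)) * cos(u),
                (R + r * cos(v)) * sin(u),
                r * sin(v))
    return(list(coords = co, parts = NULL))
  }
  if (family == "cylinder") {
    a <- 0.5; h <- sqrt(3) / 2
    area_side <- 2 * pi * a * 2 * h
    area_cap <- pi * a^2
    p <- c(area_side, area_cap, area_cap)
    comp <- sample.int(3L, n, replace = TRUE, prob = p / sum(p))
    th <- stats::runif(n, 0, 2 * pi)
    co <- matrix(0, n, 3L)
    side <- comp == 1L
    co[side, ] <- cbind(a * cos(th[side]), a * sin(th[side]),
                        stats::runif(sum(side), -h, h))
    for (cap in 2:3) {
      sel <- comp == cap
      rr <- a * sqrt(stats::runif(sum(sel)))
      co[sel, ] <- cbind(rr * cos(th[sel]), rr * sin(th[sel]),
                         if (cap == 2L) rep(h, sum(sel)) else rep(-h, sum(sel)))
    }
    parts <- c(0L, 1L, 2L)[comp]   # side, top cap, bottom cap
    return(list(coords = co, parts = parts))
  }
  # cone: apex at (0,0,h), base disc radius a at z = -h
  a <- 0.6; h <- 0.8
  slant <- sqrt(a^2 + (2 * h)^2)
  area_side <- pi * a * slant
  area_base <- pi * a^2
  comp <- sample.int(2L, n, replace = TRUE,
                     prob = c(area_side, area_base) / (area_side + area_base))
  th <- stats::runif(n, 0, 2 * pi)
  co <- matrix(0, n, 3L)
  side <- comp == 1L
  t <- sqrt(stats::runif(sum(side)))  # fractional distance from apex
  co[side, ] <- cbind(a * t * cos(th[side]), a * t * sin(th[side]),
                      h - 2 * h * t)
  sel <- comp == 2L
  rr <- a * sqrt(stats::runif(sum(sel)))
  co[sel, ] <- cbind(rr * cos(th[sel]), rr * sin(th[sel]), rep(-h, sum(sel)))
  parts <- c(0L, 1L)[comp]   # side, base
  list(coords = co, parts = parts)
}

#' Generate a synthetic object-surface point cloud
#'
#' Uniform area-weighted surface sampling of the family at its analytically
#' normalized size, followed by additive Gaussian jitter. The cloud label is
#' the family's index (0-based) in the canonical family order sphere, cube,
#' torus, cylinder, cone. Deterministic per seed.
#'
#' @param spec a \code{shape_spec}.
#' @return a labeled \code{point_cloud}.
#' @export
make_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  if (spec$n < 1L) stop("n must be at least 1")
  .with_seed(spec$seed, {
    s <- .sample_surface(spec$family, spec$n)
    co <- s$coords
    if (spec$sigma > 0)
      co <- co + matrix(stats::rnorm(length(co), 0, spec$sigma),
                        nrow(co), ncol(co))
    point_cloud(co,
                cloud_label = match(spec$family, .shape_families) - 1L)
  })
}

#' Generate a part-labeled synthetic shape
#'
#' Only families with analytically defined parts are supported: cylinder
#' (side, top cap, bottom cap — labels 0, 1, 2) and cone (side, base —
#' labels 0, 1). At zero jitter the labels separate exactly at the analytic
#' boundaries.
#'
#' @param spec a \code{shape_spec} whose family supports parts.
#' @return a \code{point_cloud} with \code{point_labels} and
#'   \code{cloud_label} set to the part-category index (cylinder 0, cone 1).
#' @export
make_part_labeled_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  if (!spec$family %in% c("cylinder", "cone"))
    stop(sprintf("family '%s' has no part decomposition", spec$family))
  .with_seed(spec$seed, {
    s <- .sample_surface(spec$family, spec$n)
    co <- s$coords
    if (spec$sigma > 0)
      co <- co + matrix(stats::rnorm(length(co), 0, spec$sigma),
                        nrow(co), ncol(co))
    point_cloud(co, point_labels = s$parts,
                cloud_label = match(spec$family, c("cylinder", "cone")) - 1L)
  })
}

#' Part sets of the part-labeled shape categories
#'
#' @return list: element 1 the parts of category 0 (cylinder), element 2
#'   those of category 1 (cone).
#' @export
shape_part_sets <- function() list(0:2, 0:1)

#' Specification of a density-volume cloud
#'
#' A mixture of isotropic Gaussian blobs rasterized on a cubic voxel grid
#' spanning [-1, 1]^3. Sampling draws a constant number of points per cloud
#' with probability proportional to voxel density — emulating fixed-size
#' point sets extracted from 3-D tomography densities.
#'
#' @param centers matrix of blob centers (rows) in [-1, 1]^3.
#' @param widths per-blob Gaussian standard deviations.
#' @param weights per-blob mixture weights.
#' @param dims voxels per axis (scalar).
#' @param n points per cloud.
#' @param seed optional seed.
#' @param label optional 0-based class label attached to generated clouds.
#' @return A \code{volume_spec} list (with the rasterized density cached).
#' @export
volume_spec <- function(centers, widths, weights = NULL, dims = 32L,
                        n = 1024L, seed = NULL, label = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be 3-D")
  nb <- nrow(centers)
  widths <- rep_len(widths, nb)
  if (is.null(weights)) weights <- rep(1, nb)
  weights <- rep_len(weights, nb)
  if (any(weights < 0)) stop("weights must be non-negative")
  dims <- as.integer(dims)[1L]
  ax <- seq(-1, 1, length.out = dims)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dens <- numeric(nrow(grid))
  for (i in seq_len(nb)) {
    d2 <- rowSums((grid - matrix(centers[i, ], nrow(grid), 3L, byrow = TRUE))^2)
    dens <- dens + weights[i] * exp(-d2 / (2 * widths[i]^2))
  }
  if (sum(dens) <= 0) stop("density has zero total mass")
  structure(list(centers = centers, widths = widths, weights = weights,
                 dims = dims, n = as.integer(n), seed = seed, label = label,
                 grid = grid, density = dens, voxel = ax[2L] - ax[1L]),
            class = "volume_spec")
}

#' Sample a fixed-size point cloud from a density volume
#'
#' Draws exactly \code{n} voxels (with replacement, probability proportional
#' to density) and jitters each point uniformly within its voxel. The voxel
#' grid spans [-1, 1]^3, so coordinates are already unit-normalized by the
#' volume extent.
#'
#' @param spec a \code{volume_spec}.
#' @return a \code{point_cloud} (with \code{cloud_label} if the spec carries
#'   one).
#' @export
sample_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  .with_seed(spec$seed, {
    ids <- sample.int(nrow(spec$grid), spec$n, replace = TRUE,
                      prob = spec$density)
    jit <- matrix(stats::runif(3L * spec$n, -spec$voxel / 2, spec$voxel / 2),
                  spec$n, 3L)
    point_cloud(spec$grid[ids, , drop = FALSE] + jit,
                cloud_label = spec$label)
  })
}

# random blob layout for one volume class (uses the caller's RNG stream)
.random_layout <- function(label, dims, n) {
  nb <- sample(3:5, 1L)
  volume_spec(centers = matrix(stats::runif(3L * nb, -0.55, 0.55), nb, 3L),
              widths = stats::runif(nb, 0.08, 0.2),
              weights = stats::runif(nb, 0.5, 1.5),
              dims = dims, n = n, label = label)
}

#' Generate a stratified synthetic train/test dataset
#'
#' Shape mode draws the classes from the canonical shape families; volume
#' mode builds one random blob layout per class (a stand-in for distinct
#' macromolecular structures) and samples fixed-size clouds from each. The
#' split is stratified per class and train/test are disjoint by construction.
#' Fully reproducible from \code{seed}.
#'
#' @param n_classes number of classes (at most 5 in shape mode).
#' @param per_class clouds per class (at least 2).
#' @param split training fraction in (0, 1).
#' @param seed RNG seed.
#' @param mode \code{"shapes"} or \code{"volumes"}.
#' @param n points per cloud.
#' @param sigma jitter standard deviation (shape mode).
#' @param dims voxel grid size (volume mode).
#' @return list with \code{train} and \code{test} lists of labeled clouds.
#' @export
make_dataset <- function(n_classes, per_class, split = 0.8, seed = 1L,
                         mode = c("shapes", "volumes"), n = 1024L,
                         sigma = 0.01, dims = 32L) {
  mode <- match.arg(mode)
  if (per_class < 2L) stop("per_class must be at least 2")
  if (split <= 0 || split >= 1) stop("split must lie strictly in (0, 1)")
  if (mode == "shapes" && n_classes > length(.shape_families))
    stop(sprintf("at most %d shape classes available", length(.shape_families)))
  n_train <- round(split * per_class)
  if (n_train < 1L || n_train >= per_class)
    stop("split leaves an empty train or test partition")
  train <- list(); test <- list()
  .with_seed(seed, {
    layouts <- if (mode == "volumes")
      lapply(seq_len(n_classes) - 1L, .random_layout, dims = dims, n = n)
    for (cl in seq_len(n_classes) - 1L) {
      for (i in seq_len(per_class)) {
        cloud <- if (mode == "shapes") {
          sp <- shape_spec(.shape_families[cl + 1L], n = n, sigma = sigma)
          out <- make_shape(sp)
          out$cloud_label <- cl
          out
        } else {
          sample_volume(layouts[[cl + 1L]])
        }
        if (i <= n_train) train[[length(train) + 1L]] <- cloud
        else test[[length(test) + 1L]] <- cloud
      }
    }
  })
  list(train = train, test = test)
}
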