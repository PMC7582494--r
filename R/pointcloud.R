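#' Construct a point cloud
#'
#' A point cloud is an unordered set of N points in 3-D space, optionally
#' carrying extra per-point channels (e.g. normals), per-point part labels
#' (for segmentation) and a whole-cloud class label (for classification).
#'
#' Labels follow the common point-set dataset dialect: integer codes starting
#' at 0. Point indices inside the package are ordinary 1-based R indices.
#'
#' @param coords N x 3 numeric matrix of point coordinates.
#' @param extra_channels optional N x q numeric matrix of additional per-point
#'   features.
#' @param point_labels optional integer vector of length N with per-point part
#'   labels (0-based codes).
#' @param cloud_label optional single integer class label (0-based code).
#' @return An object of class \code{point_cloud}.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3), cloud_label = 0L)
#' n_points(pc)
#' @export
point_cloud <- function(coords, extra_channels = NULL, point_labels = NULL,
                        cloud_label = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have exactly 3 columns")
  if (nrow(coords) < 1L) stop("a point cloud needs at least one point")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.null(extra_channels)) {
    extra_channels <- as.matrix(extra_channels)
    storage.mode(extra_channels) <- "double"
    if (nrow(extra_channels) != nrow(coords))
      stop("extra_channels must have one row per point")
    if (!all(is.finite(extra_channels))) stop("extra_channels must be finite")
  }
  if (!is.null(point_labels)) {
    point_labels <- as.integer(point_labels)
    if (length(point_labels) != nrow(coords))
      stop("point_labels must have one entry per point")
  }
  if (!is.null(cloud_label)) {
    cloud_label <- as.integer(cloud_label)[1L]
  }
  structure(list(coords = coords, extra_channels = extra_channels,
                 point_labels = point_labels, cloud_label = cloud_label),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param x a \code{point_cloud}.
#' @return integer point count.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "point_cloud"))
  nrow(x$coords)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", nrow(x$coords)))
  if (!is.null(x$extra_channels))
    cat(sprintf(", %d extra channel(s)", ncol(x$extra_channels)))
  if (!is.null(x$cloud_label)) cat(sprintf(", class %d", x$cloud_label))
  if (!is.null(x$point_labels))
    cat(sprintf(", %d part label(s)", length(unique(x$point_labels))))
  cat("\n")
  invisible(x)
}

#' Center and scale a cloud to the unit sphere
#'
#' Translates the centroid to the origin and rescales so the farthest point
#' lies at radius 1 — the normalization convention of the CAD point-set
#' dataset lineage.
#'
#' @param x a \code{point_cloud} or an N x 3 matrix.
#' @return the same type of object, normalized.
#' @export
normalize_cloud <- function(x) {
  if (inherits(x, "point_cloud")) {
    x$coords <- normalize_cloud(x$coords)
    return(x)
  }
  x <- as.matrix(x)
  ctr <- colMeans(x)
  x <- x - matrix(ctr, nrow(x), 3L, byrow = TRUE)
  r <- sqrt(max(rowSums(x^2)))
  if (r > 0) x <- x / r
  x
}

# coordinates as a plain matrix, accepting either a cloud or a matrix
.as_coords <- function(x) {
  if (inherits(x, "point_cloud")) return(x$coords)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}
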