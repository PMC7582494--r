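# Readers and writers for the point-set file formats this tool meets in the
# wild: OFF meshes (CAD-model releases), PLY (ascii and binary little-endian),
# whitespace XYZ tables, and a plain-text multi-cloud table for stacked
# datasets. Coordinates are written at full double precision (%.17g), so
# write-then-read is an exact identity.

.fmt_num <- function(x) sprintf("%.17g", x)

.infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = "off", ply = "ply", xyz = "xyz", txt = "xyz",
         csv = "table",
         stop(sprintf("cannot infer point-cloud format from '%s'", path)))
}

# area-weighted uniform resampling of a triangulated surface
.sample_mesh <- function(vertices, faces, n) {
  # fan-triangulate polygons with more than 3 vertices
  tris <- list()
  for (f in faces) {
    if (length(f) < 3L) next
    for (j in 2:(length(f) - 1L))
      tris[[length(tris) + 1L]] <- f[c(1L, j, j + 1L)]
  }
  if (length(tris) == 0L) stop("mesh has no faces to sample from")
  T <- do.call(rbind, tris)
  a <- vertices[T[, 1L], , drop = FALSE]
  b <- vertices[T[, 2L], , drop = FALSE]
  cc <- vertices[T[, 3L], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- 0.5 * sqrt(rowSums(cr(b - a, cc - a)^2))
  if (sum(area) <= 0) stop("mesh has zero surface area")
  pick <- sample.int(nrow(T), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  a[pick, , drop = FALSE] * w1 + b[pick, , drop = FALSE] * w2 +
    cc[pick, , drop = FALSE] * w3
}

# ---- OFF -------------------------------------------------------------------

#' Read an OFF mesh as a point cloud
#'
#' Returns the mesh vertices; when \code{n_points} is given and faces are
#' present, resamples the surface uniformly by face area instead.
#'
#' @param path OFF file path.
#' @param n_points optional number of surface samples.
#' @param normalize center and rescale to the unit sphere?
#' @return a \code{point_cloud}.
#' @export
read_off <- function(path, n_points = NULL, normalize = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty OFF file")
  hdr <- lines[1L]
  rest <- lines[-1L]
  if (hdr != "OFF") {
    # some writers glue the counts onto the header line: "OFF 8 6 0"
    if (startsWith(hdr, "OFF")) {
      rest <- c(trimws(sub("^OFF", "", hdr)), rest)
      rest <- rest[nchar(rest) > 0]
    } else {
      stop(sprintf("malformed OFF header at line 1: '%s'", hdr))
    }
  }
  cnt <- suppressWarnings(as.numeric(strsplit(rest[1L], "\\s+")[[1L]]))
  if (length(cnt) < 2L || anyNA(cnt))
    stop(sprintf("malformed OFF count line: '%s'", rest[1L]))
  nv <- cnt[1L]; nf <- cnt[2L]
  if (nv < 1L) stop("empty geometry: OFF file declares no vertices")
  if (length(rest) < 1L + nv + nf) stop("truncated OFF file")
  verts <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    v <- suppressWarnings(as.numeric(strsplit(rest[1L + i], "\\s+")[[1L]]))
    if (length(v) < 3L || anyNA(v[1:3]))
      stop(sprintf("malformed OFF vertex at line %d: '%s'", i + 2L, rest[1L + i]))
    verts[i, ] <- v[1:3]
  }
  faces <- vector("list", nf)
  for (i in seq_len(nf)) {
    v <- suppressWarnings(as.numeric(strsplit(rest[1L + nv + i], "\\s+")[[1L]]))
    if (length(v) < 1L || anyNA(v[1L]) || length(v) < 1L + v[1L])
      stop(sprintf("malformed OFF face at line %d", nv + i + 2L))
    faces[[i]] <- as.integer(v[2:(1L + v[1L])]) + 1L  # OFF indices are 0-based
  }
  co <- if (!is.null(n_points) && nf > 0L) .sample_mesh(verts, faces, n_points)
        else verts
  if (normalize) co <- normalize_cloud(co)
  point_cloud(co)
}

#' Write a point cloud (and optional faces) as OFF
#'
#' @param cloud a \code{point_cloud} or N x 3 matrix.
#' @param path output path.
#' @param faces optional list of integer vertex index vectors (1-based).
#' @export
write_off <- function(cloud, path, faces = NULL) {
  co <- .as_coords(cloud)
  nf <- length(faces)
  out <- c("OFF",
           sprintf("%d %d 0", nrow(co), nf),
           apply(co, 1L, function(r) paste(.fmt_num(r), collapse = " ")))
  if (nf > 0L)
    out <- c(out, vapply(faces, function(f)
      paste(c(length(f), f - 1L), collapse = " "), character(1)))
  writeLines(out, path)
  invisible(path)
}

# ---- PLY -------------------------------------------------------------------

.ply_rtypes <- c(char = "integer", uchar = "integer", short = "integer",
                 ushort = "integer", int = "integer", uint = "integer",
                 int8 = "integer", uint8 = "integer", int16 = "integer",
                 uint16 = "integer", int32 = "integer", uint32 = "integer",
                 float = "double", float32 = "double",
                 double = "double", float64 = "double")
.ply_sizes <- c(char = 1L, uchar = 1L, short = 2L, ushort = 2L, int = 4L,
                uint = 4L, int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
                int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
                double = 8L, float64 = 8L)

#' Read a PLY file as a point cloud
#'
#' Supports ascii and binary little-endian PLY. The vertex element's
#' \code{x}, \code{y}, \code{z} become the coordinates; any further numeric
#' vertex properties (e.g. an attention \code{weight}) are returned as named
#' \code{extra_channels}. When \code{n_points} is given and a face element is
#' present, the surface is resampled by area.
#'
#' @inheritParams read_off
#' @return a \code{point_cloud}.
#' @export
read_ply <- function(path, n_points = NULL, normalize = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed PLY header: no end_header line")
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(hdr[1L]) != "ply")
    stop(sprintf("malformed PLY header at line 1: '%s'", hdr[1L]))
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (length(fmt_line) != 1L) stop("malformed PLY header: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s'", fmt))
  # parse element/property declarations
  elements <- list()
  cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], type = tok[4L], list = TRUE, count_type = tok[3L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], type = tok[2L], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || elements$vertex$count < 1L)
    stop("empty geometry: PLY file has no vertices")

  read_element_ascii <- function(el, lines) {
    vals <- lapply(el$props, function(p) vector("list", el$count))
    faces <- vector("list", el$count)
    for (i in seq_len(el$count)) {
      tok <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
      pos <- 1L
      for (j in seq_along(el$props)) {
        p <- el$props[[j]]
        if (p$list) {
          cnt <- tok[pos]; pos <- pos + 1L
          vals[[j]][[i]] <- tok[pos:(pos + cnt - 1L)]; pos <- pos + cnt
        } else {
          vals[[j]][[i]] <- tok[pos]; pos <- pos + 1L
        }
      }
    }
    vals
  }
  read_element_bin <- function(el, con) {
    vals <- lapply(el$props, function(p) vector("list", el$count))
    simple <- !any(vapply(el$props, `[[`, logical(1), "list"))
    if (simple && length(unique(vapply(el$props, `[[`, character(1), "type"))) == 1L) {
      tp <- el$props[[1L]]$type
      m <- matrix(readBin(con, .ply_rtypes[[tp]],
                          n = el$count * length(el$props),
                          size = .ply_sizes[[tp]], endian = "little"),
                  el$count, length(el$props), byrow = TRUE)
      for (j in seq_along(el$props)) vals[[j]] <- as.list(m[, j])
      return(vals)
    }
    for (i in seq_len(el$count)) {
      for (j in seq_along(el$props)) {
        p <- el$props[[j]]
        if (p$list) {
          cnt <- readBin(con, .ply_rtypes[[p$count_type]], n = 1L,
                         size = .ply_sizes[[p$count_type]], endian = "little")
          vals[[j]][[i]] <- readBin(con, .ply_rtypes[[p$type]], n = cnt,
                                    size = .ply_sizes[[p$type]],
                                    endian = "little")
        } else {
          vals[[j]][[i]] <- readBin(con, .ply_rtypes[[p$type]], n = 1L,
                                    size = .ply_sizes[[p$type]],
                                    endian = "little")
        }
      }
    }
    vals
  }

  data <- list()
  if (fmt == "ascii") {
    body <- readLines(con)
    pos <- 1L
    for (el in elements) {
      data[[el$name]] <- read_element_ascii(el, body[pos:(pos + el$count - 1L)])
      pos <- pos + el$count
    }
  } else {
    for (el in elements) data[[el$name]] <- read_element_bin(el, con)
  }

  vx <- elements$vertex
  pn <- vapply(vx$props, `[[`, character(1), "name")
  if (!all(c("x", "y", "z") %in% pn))
    stop("PLY vertex element lacks x/y/z properties")
  getcol <- function(nm) unlist(data$vertex[[which(pn == nm)]])
  co <- cbind(getcol("x"), getcol("y"), getcol("z"))
  extras <- setdiff(pn, c("x", "y", "z"))
  ex <- NULL
  if (length(extras) > 0L) {
    ex <- do.call(cbind, lapply(extras, getcol))
    colnames(ex) <- extras
  }
  faces <- NULL
  if (!is.null(elements$face)) {
    fp <- vapply(elements$face$props, `[[`, logical(1), "list")
    if (any(fp))
      faces <- lapply(data$face[[which(fp)[1L]]], function(f) as.integer(f) + 1L)
  }
  if (!is.null(n_points) && !is.null(faces) && length(faces) > 0L) {
    co <- .sample_mesh(co, faces, n_points)
    ex <- NULL
  }
  if (normalize) co <- normalize_cloud(co)
  point_cloud(co, extra_channels = ex)
}

#' Write a point cloud as PLY
#'
#' Coordinates (and any extra per-point scalar properties) are written as
#' PLY \code{double} properties, so values survive a round trip exactly.
#'
#' @param cloud a \code{point_cloud} or N x 3 matrix.
#' @param path output path.
#' @param format \code{"ascii"} or \code{"binary_little_endian"}.
#' @param properties optional named list of per-point numeric vectors to
#'   store as additional vertex properties (e.g. \code{weight}).
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary_little_endian"),
                      properties = NULL) {
  format <- match.arg(format)
  co <- .as_coords(cloud)
  cols <- list(x = co[, 1L], y = co[, 2L], z = co[, 3L])
  if (inherits(cloud, "point_cloud") && !is.null(cloud$extra_channels)) {
    ec <- cloud$extra_channels
    nms <- colnames(ec)
    if (is.null(nms)) nms <- paste0("c", seq_len(ncol(ec)))
    for (j in seq_len(ncol(ec))) cols[[nms[j]]] <- ec[, j]
  }
  for (nm in names(properties)) cols[[nm]] <- as.numeric(properties[[nm]])
  n <- nrow(co)
  hdr <- c("ply",
           sprintf("format %s 1.0", format),
           sprintf("element vertex %d", n),
           sprintf("property double %s", names(cols)),
           "end_header")
  if (format == "ascii") {
    M <- do.call(cbind, cols)
    body <- apply(M, 1L, function(r) paste(.fmt_num(r), collapse = " "))
    writeLines(c(hdr, body), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    M <- t(do.call(cbind, cols))
    writeBin(as.vector(M), con, size = 8L, endian = "little")
  }
  invisible(path)
}

# ---- whitespace XYZ --------------------------------------------------------

#' Read a whitespace-delimited XYZ point table
#' @param path file path; rows are "x y z".
#' @param normalize center and rescale to the unit sphere?
#' @return a \code{point_cloud}.
#' @export
read_xyz <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) < 3L) stop("XYZ file must have at least 3 columns")
  co <- m[, 1:3, drop = FALSE]
  if (normalize) co <- normalize_cloud(co)
  point_cloud(co)
}

#' Write a point cloud as a whitespace XYZ table
#' @param cloud a \code{point_cloud} or N x 3 matrix.
#' @param path output path.
#' @export
write_xyz <- function(cloud, path) {
  co <- .as_coords(cloud)
  writeLines(apply(co, 1L, function(r) paste(.fmt_num(r), collapse = " ")),
             path)
  invisible(path)
}

# ---- stacked multi-cloud table ---------------------------------------------

#' Write a collection of clouds as one plain-text table
#'
#' One CSV with columns \code{cloud} (0-based cloud id), \code{x,y,z}, and —
#' when present on every cloud — \code{label} (cloud class) and \code{pid}
#' (per-point part label). Numbers are written at full double precision, so
#' the table round-trips exactly.
#'
#' @param clouds list of \code{point_cloud}s.
#' @param path output path.
#' @export
write_cloud_table <- function(clouds, path) {
  stopifnot(length(clouds) > 0L)
  has_lab <- all(vapply(clouds, function(p) !is.null(p$cloud_label), logical(1)))
  has_pid <- all(vapply(clouds, function(p) !is.null(p$point_labels), logical(1)))
  rows <- lapply(seq_along(clouds), function(i) {
    p <- clouds[[i]]
    n <- n_points(p)
    r <- paste(i - 1L,
               .fmt_num(p$coords[, 1L]), .fmt_num(p$coords[, 2L]),
               .fmt_num(p$coords[, 3L]), sep = ",")
    if (has_lab) r <- paste(r, rep(p$cloud_label, n), sep = ",")
    if (has_pid) r <- paste(r, p$point_labels, sep = ",")
    r
  })
  hdr <- paste(c("cloud", "x", "y", "z",
                 if (has_lab) "label", if (has_pid) "pid"), collapse = ",")
  writeLines(c(hdr, unlist(rows)), path)
  invisible(path)
}

#' Read a multi-cloud table written by \code{\link{write_cloud_table}}
#' @param path table path.
#' @return list of \code{point_cloud}s.
#' @export
read_cloud_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("cloud", "x", "y", "z") %in% names(df)))
    stop("cloud table lacks cloud/x/y/z columns")
  lapply(sort(unique(df$cloud)), function(id) {
    d <- df[df$cloud == id, , drop = FALSE]
    point_cloud(cbind(d$x, d$y, d$z),
                point_labels = if ("pid" %in% names(df)) d$pid else NULL,
                cloud_label = if ("label" %in% names(df)) d$label[1L] else NULL)
  })
}

# ---- dispatching front ends ------------------------------------------------

#' Read point clouds from any supported format
#'
#' Dispatches on \code{format} (or the file extension): OFF, PLY, whitespace
#' XYZ, or the multi-cloud CSV table. Single-cloud formats return one
#' \code{point_cloud}; the table returns a list.
#'
#' @param path input path.
#' @param format one of \code{"off"}, \code{"ply"}, \code{"xyz"},
#'   \code{"table"}; inferred from the extension when \code{NULL}.
#' @param n_points optional surface resampling count (mesh formats).
#' @param normalize center and rescale to the unit sphere?
#' @return a \code{point_cloud} or a list of them.
#' @export
read_pointcloud <- function(path, format = NULL, n_points = NULL,
                            normalize = FALSE) {
  if (is.null(format)) format <- .infer_format(path)
  switch(format,
         off = read_off(path, n_points, normalize),
         ply = read_ply(path, n_points, normalize),
         xyz = read_xyz(path, normalize),
         table = read_cloud_table(path),
         stop(sprintf("unsupported format '%s'", format)))
}

#' Write a point cloud to any supported format
#' @param cloud a \code{point_cloud} (or list of clouds for \code{"table"}).
#' @param path output path.
#' @param format as in \code{\link{read_pointcloud}}.
#' @param ... passed to the format writer.
#' @export
write_pointcloud <- function(cloud, path, format = NULL, ...) {
  if (is.null(format)) format <- .infer_format(path)
  switch(format,
         off = write_off(cloud, path, ...),
         ply = write_ply(cloud, path, ...),
         xyz = write_xyz(cloud, path),
         table = write_cloud_table(if (inherits(cloud, "point_cloud"))
           list(cloud) else cloud, path),
         stop(sprintf("unsupported format '%s'", format)))
}

# ---- attention export ------------------------------------------------------

#' Export an attention mask as CSV
#'
#' Columns \code{index,x,y,z,weight}: point index (0-based), coordinates and
#' the soft attention weight.
#'
#' @param cloud the \code{point_cloud} the mask belongs to.
#' @param weights numeric vector of per-point weights.
#' @param path output path.
#' @export
export_attention_csv <- function(cloud, weights, path) {
  co <- .as_coords(cloud)
  if (length(weights) != nrow(co)) stop("weights length must match point count")
  writeLines(c("index,x,y,z,weight",
               paste(seq_len(nrow(co)) - 1L,
                     .fmt_num(co[, 1L]), .fmt_num(co[, 2L]), .fmt_num(co[, 3L]),
                     .fmt_num(weights), sep = ",")),
             path)
  invisible(path)
}

#' Export an attention mask as PLY with a per-vertex weight property
#' @inheritParams export_attention_csv
#' @param format PLY flavor.
#' @export
export_attention_ply <- function(cloud, weights, path,
                                 format = c("ascii", "binary_little_endian")) {
  co <- .as_coords(cloud)
  if (length(weights) != nrow(co)) stop("weights length must match point count")
  write_ply(point_cloud(co), path, format = match.arg(format),
            properties = list(weight = weights))
}

# ---- run configuration -----------------------------------------------------

#' Write a run configuration as YAML
#' @param config a named list.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  yaml::read_yaml(path)
}
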