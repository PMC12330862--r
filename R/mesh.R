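#' Triangle mesh
#'
#' A discretized surface: vertex coordinates in millimetres and 0-based
#' triangle connectivity. Triangles must be non-degenerate (strictly
#' positive area) and every index must fall in `[0, N)`.
#'
#' @param vertices numeric N x 3 matrix of coordinates (mm).
#' @param faces integer F x 3 matrix of 0-based vertex indices.
#' @return an object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop_es("vertices must be N x 3", class = "validation_error")
  if (ncol(faces) != 3L) stop_es("faces must be F x 3", class = "validation_error")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = c("triangle_mesh", "es_mesh"))
  validate_mesh(m)
  m
}

#' Tetrahedral mesh
#'
#' A discretized volume: vertex coordinates in millimetres and 0-based
#' tetrahedron connectivity. Tetrahedra are canonicalized to positive
#' orientation (positive signed volume).
#'
#' @param vertices numeric N x 3 matrix of coordinates (mm).
#' @param tets integer T x 4 matrix of 0-based vertex indices.
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(vertices, tets) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(vertices) <- dimnames(tets) <- NULL
  if (ncol(vertices) != 3L) stop_es("vertices must be N x 3", class = "validation_error")
  if (ncol(tets) != 4L) stop_es("tets must be T x 4", class = "validation_error")
  ## canonicalize orientation: swap two vertices of negatively oriented tets
  sv <- tet_signed_volumes(vertices, tets)
  neg <- which(sv < 0)
  if (length(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  m <- structure(list(vertices = vertices, tets = tets),
                 class = c("tet_mesh", "es_mesh"))
  validate_mesh(m)
  m
}

n_vertices <- function(mesh) nrow(mesh$vertices)

is_tet_mesh <- function(mesh) inherits(mesh, "tet_mesh")

validate_mesh <- function(mesh) {
  n <- n_vertices(mesh)
  if (n < 4L) stop_es("mesh needs at least 4 vertices, got ", n,
                      class = "validation_error")
  conn <- if (is_tet_mesh(mesh)) mesh$tets else mesh$faces
  if (any(conn < 0L) || any(conn >= n)) {
    bad <- which(apply(conn, 1L, function(r) any(r < 0L | r >= n)))
    stop_es("element indices out of range [0, ", n, ") in elements: ",
            paste(head(bad, 10L), collapse = ", "), class = "validation_error")
  }
  dup <- which(apply(conn, 1L, anyDuplicated) > 0L)
  if (length(dup)) {
    stop_es("duplicated vertex index within elements: ",
            paste(head(dup, 10L), collapse = ", "), class = "validation_error")
  }
  if (is_tet_mesh(mesh)) {
    vol <- tet_signed_volumes(mesh$vertices, mesh$tets)
    bad <- which(vol <= 0)
    if (length(bad)) stop_es("non-positive tetrahedron volume in elements: ",
                             paste(head(bad, 10L), collapse = ", "),
                             class = "validation_error")
  } else {
    a <- triangle_areas(mesh)
    bad <- which(a <= 0)
    if (length(bad)) stop_es("zero-area triangles at elements: ",
                             paste(head(bad, 10L), collapse = ", "),
                             class = "validation_error")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(triangle_areas(x))))
  invisible(x)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d vertices, %d tets, volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$tets),
              sum(tet_signed_volumes(x$vertices, x$tets))))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Triangle areas of a surface mesh
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3(e1, e2)^2))
}

tet_signed_volumes <- function(vertices, tets) {
  t1 <- tets + 1L
  a <- vertices[t1[, 2], , drop = FALSE] - vertices[t1[, 1], , drop = FALSE]
  b <- vertices[t1[, 3], , drop = FALSE] - vertices[t1[, 1], , drop = FALSE]
  d <- vertices[t1[, 4], , drop = FALSE] - vertices[t1[, 1], , drop = FALSE]
  rowSums(cross3(a, b) * d) / 6
}

#' Undirected edge list of a mesh
#' @param mesh a `triangle_mesh` or `tet_mesh`.
#' @return integer matrix with two 0-based columns, one row per unique edge.
#' @export
mesh_edges <- function(mesh) {
  conn <- if (is_tet_mesh(mesh)) mesh$tets else mesh$faces
  pairs <- if (is_tet_mesh(mesh)) {
    rbind(conn[, c(1, 2)], conn[, c(1, 3)], conn[, c(1, 4)],
          conn[, c(2, 3)], conn[, c(2, 4)], conn[, c(3, 4)])
  } else {
    rbind(conn[, c(1, 2)], conn[, c(2, 3)], conn[, c(3, 1)])
  }
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  unique(cbind(lo, hi))
}

#' Per-vertex scalar map on a mesh
#'
#' Values are one scalar per vertex; missing data (medial wall, NaN) are
#' represented by the logical mask, the package's only internal missing
#' data representation. Masked entries are treated as absent by every
#' statistic.
#'
#' @param values numeric vector, one value per vertex. `NA`/`NaN` entries
#'   are converted to masked-out vertices.
#' @param mask optional logical vector, `TRUE` = valid datum.
#' @return an object of class `surface_map` with `values` and `mask`.
#' @export
surface_map <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  if (length(mask) != length(values)) {
    stop_es("mask length ", length(mask), " != values length ", length(values),
            class = "dimension_error")
  }
  mask <- as.logical(mask) & is.finite(values)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map: %d vertices (%d masked out)\n",
              length(x$values), sum(!x$mask)))
  invisible(x)
}

as_surface_map <- function(x) {
  if (inherits(x, "surface_map")) x else surface_map(x)
}

check_map_mesh <- function(map, mesh) {
  if (length(map$values) != n_vertices(mesh)) {
    stop_es("map has ", length(map$values), " values but mesh has ",
            n_vertices(mesh), " vertices", class = "dimension_error")
  }
  invisible(TRUE)
}
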