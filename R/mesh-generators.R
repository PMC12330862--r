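#' Icosphere surface mesh
#'
#' Recursively subdivided icosahedron projected onto the sphere. Vertex
#' count is `10 * 4^s + 2` and face count `20 * 4^s` at subdivision level
#' `s`. Used throughout as a synthetic stand-in for cortical meshes.
#'
#' @param subdivisions non-negative integer number of subdivision passes
#'   (at most 8).
#' @param radius sphere radius in mm.
#' @return a [triangle_mesh()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  stopifnot(subdivisions >= 0, subdivisions <= 8, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  for (s in seq_len(subdivisions)) {
    f1 <- f + 1L
    edges <- rbind(f1[, c(1, 2)], f1[, c(2, 3)], f1[, c(3, 1)])
    lo <- pmin(edges[, 1], edges[, 2]); hi <- pmax(edges[, 1], edges[, 2])
    key <- paste(lo, hi)
    ukey <- !duplicated(key)
    mid_id <- match(key, key[ukey])           # 1-based id among unique edges
    mids <- (v[lo[ukey], , drop = FALSE] + v[hi[ukey], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    base <- nrow(v)
    v <- rbind(v, mids)
    nf <- nrow(f)
    mab <- base + mid_id[seq_len(nf)]                 # midpoint of (a,b)
    mbc <- base + mid_id[nf + seq_len(nf)]            # midpoint of (b,c)
    mca <- base + mid_id[2L * nf + seq_len(nf)]       # midpoint of (c,a)
    a <- f1[, 1]; b <- f1[, 2]; cc <- f1[, 3]
    f <- rbind(cbind(a, mab, mca), cbind(b, mbc, mab),
               cbind(cc, mca, mbc), cbind(mab, mbc, mca)) - 1L
  }
  triangle_mesh(v * radius, f)
}

#' Bumpy sphere: icosphere with band-limited random radial displacement
#'
#' Breaks the exact rotational symmetry of the sphere so that eigenvalues
#' within a former spherical-harmonic group are no longer degenerate,
#' while keeping the mesh valid. The displacement field is a fixed-seed
#' band-limited sum of low-frequency plane waves evaluated on the unit
#' directions, scaled to `bump_amplitude * radius` peak amplitude.
#'
#' @inheritParams make_icosphere
#' @param bump_amplitude peak radial displacement as a fraction of the
#'   radius; must be below 0.5.
#' @param seed integer seed; the mesh is a pure function of
#'   `(subdivisions, radius, bump_amplitude, seed)`.
#' @return a [triangle_mesh()].
#' @export
make_bumpy_sphere <- function(subdivisions = 3L, radius = 1,
                              bump_amplitude = 0.1, seed = 1L) {
  stopifnot(bump_amplitude >= 0, bump_amplitude < 0.5)
  base <- make_icosphere(subdivisions, radius)
  if (bump_amplitude == 0) return(base)
  u <- base$vertices / radius
  field <- withr::with_seed(as.integer(seed), {
    k <- matrix(rnorm(3 * 12), ncol = 3) * 2.5       # band-limited wavevectors
    ph <- runif(12, 0, 2 * pi)
    amp <- rnorm(12)
    rowSums(vapply(seq_len(12), function(j) {
      amp[j] * cos(u %*% k[j, ] + ph[j])
    }, numeric(nrow(u))))
  })
  field <- field / max(abs(field))
  r <- radius * (1 + bump_amplitude * field)
  triangle_mesh(u * r, base$faces)
}

#' Tetrahedral ball mesh
#'
#' Fills the ball of the given radius with tetrahedra obtained by slicing
#' a regular grid of cubes (6 tets per cube) and keeping tetrahedra whose
#' centroid lies inside the sphere. The centroid rule is first-order
#' unbiased, so the total volume converges to the analytic ball volume as
#' the target edge is refined.
#'
#' @param radius ball radius (mm).
#' @param target_edge approximate edge length (mm); must be below the
#'   radius.
#' @return a [tet_mesh()].
#' @export
make_tet_ball <- function(radius = 1, target_edge = radius / 6) {
  stopifnot(target_edge > 0, target_edge < radius)
  h <- target_edge
  g <- seq(-radius - h, radius + h, by = h)
  n <- length(g)
  coord <- as.matrix(expand.grid(x = g, y = g, z = g))
  idx3 <- function(i, j, k) (k - 1L) * n * n + (j - 1L) * n + i  # 1-based
  ii <- seq_len(n - 1L)
  cell <- as.matrix(expand.grid(i = ii, j = ii, k = ii))
  c000 <- idx3(cell[, 1], cell[, 2], cell[, 3])
  c100 <- idx3(cell[, 1] + 1L, cell[, 2], cell[, 3])
  c010 <- idx3(cell[, 1], cell[, 2] + 1L, cell[, 3])
  c110 <- idx3(cell[, 1] + 1L, cell[, 2] + 1L, cell[, 3])
  c001 <- idx3(cell[, 1], cell[, 2], cell[, 3] + 1L)
  c101 <- idx3(cell[, 1] + 1L, cell[, 2], cell[, 3] + 1L)
  c011 <- idx3(cell[, 1], cell[, 2] + 1L, cell[, 3] + 1L)
  c111 <- idx3(cell[, 1] + 1L, cell[, 2] + 1L, cell[, 3] + 1L)
  ## six-tet Kuhn decomposition of each cube (shares the c000-c111 diagonal)
  tets <- rbind(
    cbind(c000, c100, c110, c111), cbind(c000, c110, c010, c111),
    cbind(c000, c010, c011, c111), cbind(c000, c011, c001, c111),
    cbind(c000, c001, c101, c111), cbind(c000, c101, c100, c111))
  cen <- (coord[tets[, 1], ] + coord[tets[, 2], ] +
            coord[tets[, 3], ] + coord[tets[, 4], ]) / 4
  keep <- rowSums(cen^2) <= radius^2
  tets <- tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(n^3)
  remap[used] <- seq_along(used)
  tet_mesh(coord[used, , drop = FALSE],
           matrix(remap[tets], ncol = 4L) - 1L)
}

#' Extract the submesh induced by a vertex mask
#'
#' Keeps elements all of whose vertices are kept, renumbering vertices
#' compactly while preserving their order. The typical use is cutting the
#' medial wall (or a polar cap of a synthetic sphere) so that eigenmodes
#' can be computed on the open surface with natural boundary conditions.
#'
#' @param mesh a [triangle_mesh()] or [tet_mesh()].
#' @param keep logical vector over vertices, `TRUE` = keep.
#' @param largest_component if the kept region is edge-disconnected, keep
#'   only the largest component (default `FALSE`: warn and keep all).
#' @return a list with `mesh` (the cut mesh), `index_map` (0-based old
#'   index for every new vertex) and `new_index` (0-based new index per
#'   old vertex, `NA` where dropped).
#' @export
extract_submesh <- function(mesh, keep, largest_component = FALSE) {
  n <- n_vertices(mesh)
  stopifnot(length(keep) == n, is.logical(keep))
  if (!any(keep)) stop_es("empty submesh", class = "validation_error")
  conn <- if (is_tet_mesh(mesh)) mesh$tets else mesh$faces
  elem_keep <- matrix(keep[conn + 1L], nrow = nrow(conn))
  kept_elems <- conn[rowSums(elem_keep) == ncol(conn), , drop = FALSE]
  ## connectivity check on the kept region
  ed <- mesh_edges(if (is_tet_mesh(mesh)) tet_mesh(mesh$vertices, kept_elems)
                   else triangle_mesh(mesh$vertices, kept_elems))
  g <- igraph::graph_from_edgelist(cbind(ed[, 1], ed[, 2]) + 1L, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  used_vids <- sort(unique(as.vector(kept_elems))) + 1L
  comps_used <- unique(comp$membership[used_vids])
  if (length(comps_used) > 1L) {
    sizes <- sort(comp$csize[comps_used], decreasing = TRUE)
    if (largest_component) {
      main <- comps_used[which.max(comp$csize[comps_used])]
      in_main <- comp$membership == main
      elem_main <- matrix(in_main[kept_elems + 1L], nrow = nrow(kept_elems))
      kept_elems <- kept_elems[rowSums(elem_main) == ncol(kept_elems), , drop = FALSE]
    } else {
      warning("kept region is disconnected; component sizes: ",
              paste(sizes, collapse = ", "))
    }
  }
  used <- sort(unique(as.vector(kept_elems)))        # 0-based old ids
  new_index <- rep(NA_integer_, n)
  new_index[used + 1L] <- seq_along(used) - 1L
  new_conn <- matrix(new_index[kept_elems + 1L], ncol = ncol(kept_elems))
  sub <- if (is_tet_mesh(mesh)) {
    tet_mesh(mesh$vertices[used + 1L, , drop = FALSE], new_conn)
  } else {
    triangle_mesh(mesh$vertices[used + 1L, , drop = FALSE], new_conn)
  }
  list(mesh = sub, index_map = used, new_index = new_index)
}

#' Boundary edges of a triangle mesh
#'
#' Edges belonging to exactly one face; empty for a closed surface.
#' @param mesh a [triangle_mesh()].
#' @return integer matrix of 0-based edge endpoints.
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  pairs <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(pairs[, 1], pairs[, 2]); hi <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(lo, hi)
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  m <- do.call(rbind, strsplit(single, " "))
  if (is.null(m)) return(matrix(integer(0), ncol = 2))
  matrix(as.integer(m), ncol = 2)
}
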