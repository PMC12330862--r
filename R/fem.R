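#' Assemble linear finite-element Laplace-Beltrami operators
#'
#' Builds the P1 (linear) finite-element pair for a triangle or
#' tetrahedral mesh: the cotangent-weighted stiffness matrix `A`
#' (symmetric positive semi-definite, constants in its null space) and
#' the consistent mass matrix `B` (symmetric positive definite; its
#' entries sum to the total surface area or volume). Meshes with a
#' boundary receive natural (Neumann, zero normal derivative) boundary
#' conditions, which in the weak form require no extra constraint rows.
#'
#' @param mesh a [triangle_mesh()] or [tet_mesh()].
#' @param lumped_mass if `TRUE`, replace the consistent mass matrix by
#'   its row-lumped diagonal. Off by default.
#' @return an object of class `fem_pair`: list with sparse `stiffness`
#'   and `mass` matrices.
#' @export
assemble_fem <- function(mesh, lumped_mass = FALSE) {
  if (is_tet_mesh(mesh)) fem_tet(mesh, lumped_mass) else fem_tri(mesh, lumped_mass)
}

check_degenerate <- function(measure, what) {
  bad <- which(measure < 1e-12 * mean(measure))
  if (length(bad)) {
    stop_es("near-degenerate ", what, " (relative size < 1e-12) at elements: ",
            paste(head(bad, 10L), collapse = ", "), class = "validation_error")
  }
}

fem_tri <- function(mesh, lumped_mass) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  n <- nrow(v)
  area <- triangle_areas(mesh)
  check_degenerate(area, "triangles")
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e1 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]  # edge opposite vertex 1
  e2 <- v[i1, , drop = FALSE] - v[i3, , drop = FALSE]
  e3 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  ## cotangent of the angle at each vertex (between the two adjacent edges)
  cot1 <- rowSums((-e2) * e3) / (2 * area)   # angle at v1 between (v2-v1),(v3-v1)
  cot2 <- rowSums((-e3) * e1) / (2 * area)
  cot3 <- rowSums((-e1) * e2) / (2 * area)
  ## off-diagonal contribution for edge (j,k) is -cot(angle at i)/2
  ii <- c(i2, i3, i1, i3, i1, i2)
  jj <- c(i3, i2, i3, i1, i2, i1)
  xx <- -0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  di <- c(i2, i3, i1, i3, i1, i2)
  dx <- 0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  A <- Matrix::sparseMatrix(i = c(ii, di), j = c(jj, di), x = c(xx, dx),
                            dims = c(n, n))
  ## consistent P1 mass: area/6 on diagonal, area/12 off-diagonal
  mi <- c(i1, i2, i3, i1, i1, i2, i2, i3, i3)
  mj <- c(i1, i2, i3, i2, i3, i1, i3, i1, i2)
  mx <- c(rep(area / 6, 3), rep(area / 12, 6))
  B <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))
  fem_pair(A, B, lumped_mass)
}

fem_tet <- function(mesh, lumped_mass) {
  v <- mesh$vertices
  tt <- mesh$tets + 1L
  n <- nrow(v)
  vol <- tet_signed_volumes(mesh$vertices, mesh$tets)
  check_degenerate(vol, "tetrahedra")
  p1 <- v[tt[, 1], , drop = FALSE]; p2 <- v[tt[, 2], , drop = FALSE]
  p3 <- v[tt[, 3], , drop = FALSE]; p4 <- v[tt[, 4], , drop = FALSE]
  ## gradients of barycentric coordinates: grad_i = n_i / (6V) where n_i is
  ## the inward-scaled normal of the face opposite vertex i
  g1 <- cross3(p4 - p2, p3 - p2) / (6 * vol)
  g2 <- cross3(p3 - p1, p4 - p1) / (6 * vol)
  g3 <- cross3(p4 - p1, p2 - p1) / (6 * vol)
  g4 <- cross3(p2 - p1, p3 - p1) / (6 * vol)
  G <- list(g1, g2, g3, g4)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in 1:4) for (b in 1:4) {
    ii <- c(ii, tt[, a]); jj <- c(jj, tt[, b])
    xx <- c(xx, vol * rowSums(G[[a]] * G[[b]]))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  mi <- mj <- integer(0); mx <- numeric(0)
  for (a in 1:4) for (b in 1:4) {
    mi <- c(mi, tt[, a]); mj <- c(mj, tt[, b])
    mx <- c(mx, vol * (if (a == b) 1 / 10 else 1 / 20))
  }
  B <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))
  fem_pair(A, B, lumped_mass)
}

fem_pair <- function(A, B, lumped_mass = FALSE) {
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  B <- Matrix::forceSymmetric((B + Matrix::t(B)) / 2)
  if (lumped_mass) B <- Matrix::Diagonal(nrow(B), Matrix::rowSums(B))
  structure(list(stiffness = A, mass = B), class = "fem_pair")
}

#' @export
print.fem_pair <- function(x, ...) {
  cat(sprintf("fem_pair: %d dof, mass total %.6g\n",
              nrow(x$stiffness), sum(x$mass)))
  invisible(x)
}
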