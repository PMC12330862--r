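#' Solve the Laplace-Beltrami eigenproblem
#'
#' Computes the `n_modes` smallest-eigenvalue solutions of the
#' generalized symmetric eigenproblem `A psi = lambda B psi` for a FEM
#' pair, i.e. the geometric eigenmodes of the mesh. Eigenvalues are
#' returned ascending (units 1/mm^2); modes are B-orthonormal
#' (`t(Psi) %*% B %*% Psi = I`). The first mode is the constant with
#' eigenvalue 0 (closed meshes and Neumann-open meshes alike). A
#' deterministic sign convention is applied: the entry of largest
#' magnitude in each mode is positive. If the requested cut would split a
#' numerically degenerate eigenvalue cluster (relative gap below
#' `cluster_tol`), the returned set is extended to the end of the
#' cluster, so whole eigengroups are never truncated mid-cluster.
#'
#' @param fem a `fem_pair` from [assemble_fem()], or a mesh (assembled
#'   on the fly).
#' @param n_modes number of modes requested (at most N - 1).
#' @param solver `"auto"` (dense for small problems, ARPACK shift-invert
#'   otherwise), `"dense"`, or `"arpack"`.
#' @param tol ARPACK convergence tolerance.
#' @param cluster_tol relative eigenvalue gap under which adjacent modes
#'   are treated as one degenerate cluster.
#' @return an object of class `eigen_basis`: list with `modes` (N x M
#'   matrix), `eigenvalues` (ascending), `boundary` (`"closed"` or
#'   `"neumann-open"`), `mesh_hash`, `fem` and `solver` metadata.
#' @export
compute_eigenbasis <- function(fem, n_modes, solver = c("auto", "dense", "arpack"),
                               tol = 1e-10, cluster_tol = 1e-8) {
  solver <- match.arg(solver)
  boundary <- "closed"
  mesh_hash <- NULL
  if (inherits(fem, "es_mesh")) {
    mesh <- fem
    boundary <- if (!is_tet_mesh(mesh) && nrow(boundary_edges(mesh)) > 0) {
      "neumann-open"
    } else "closed"
    mesh_hash <- content_hash(mesh)
    fem <- assemble_fem(mesh)
  }
  A <- fem$stiffness
  B <- fem$mass
  n <- nrow(A)
  if (n_modes > n - 1L) {
    stop_es("n_modes (", n_modes, ") must be at most N - 1 = ", n - 1L,
            class = "validation_error")
  }
  if (solver == "auto") solver <- if (n <= 1500L || n_modes > n / 3) "dense" else "arpack"
  res <- if (solver == "dense") {
    eig_dense(A, B, min(n, n_modes + 8L))
  } else {
    eig_arpack(A, B, n_modes, tol)
  }
  vals <- res$values
  vecs <- res$vectors
  ## complete a split degenerate cluster
  m <- n_modes
  while (m < length(vals) &&
         (vals[m + 1] - vals[m]) <= cluster_tol * max(vals[m], 1e-300)) {
    m <- m + 1L
  }
  vals <- vals[seq_len(m)]
  vecs <- vecs[, seq_len(m), drop = FALSE]
  ## deterministic sign: largest-magnitude entry positive
  piv <- max.col(t(abs(vecs)), ties.method = "first")
  sgn <- sign(vecs[cbind(piv, seq_len(m))])
  sgn[sgn == 0] <- 1
  vecs <- sweep(vecs, 2L, sgn, "*")
  vals[1] <- max(vals[1], 0)
  vals[vals < 0 & vals > -1e-9 * max(vals)] <- 0
  ## residual check
  R <- A %*% vecs - B %*% vecs %*% Matrix::Diagonal(m, vals)
  rn <- sqrt(Matrix::colSums(R^2))
  an <- sqrt(Matrix::colSums((A %*% vecs)^2))
  bad <- rn > 1e-6 * pmax(an, 1e-12)
  if (any(bad[-1])) {
    stop_es("eigensolver did not converge; worst relative residual ",
            format(max(rn / pmax(an, 1e-12)), digits = 3),
            class = "solver_error")
  }
  structure(list(modes = as.matrix(vecs), eigenvalues = vals,
                 boundary = boundary, mesh_hash = mesh_hash,
                 fem = fem, solver = solver),
            class = "eigen_basis")
}

eig_dense <- function(A, B, k) {
  Ad <- as.matrix(A)
  Bd <- as.matrix(B)
  U <- chol(Bd)                                  # B = U'U
  Y <- backsolve(U, Ad, transpose = TRUE)        # U^-T A
  At <- backsolve(U, t(Y), transpose = TRUE)     # U^-T A' U^-1 (A symmetric)
  At <- (At + t(At)) / 2
  e <- eigen(At, symmetric = TRUE)
  ord <- seq(ncol(At), ncol(At) - k + 1L)        # eigen() returns descending
  vals <- e$values[ord]
  vecs <- backsolve(U, e$vectors[, ord, drop = FALSE])
  list(values = vals, vectors = vecs)
}

eig_arpack <- function(A, B, k, tol) {
  n <- nrow(A)
  scale <- mean(Matrix::diag(A)) / mean(Matrix::diag(B))
  sigma <- -1e-3 * scale
  ch_b <- Matrix::expand(Matrix::Cholesky(B, perm = TRUE, LDL = FALSE, super = FALSE))
  L <- ch_b$L
  P <- ch_b$P                                    # B = P' L L' P
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A - sigma * B),
                          perm = TRUE, LDL = FALSE)
  ## symmetric operator K (A - sigma B)^-1 K' with K = L'P; theta = 1/(lambda - sigma)
  opfun <- function(x, extra = NULL) {
    w <- as.numeric(Matrix::crossprod(P, L %*% x))
    y <- as.numeric(Matrix::solve(fac, w))
    as.numeric(Matrix::t(L) %*% (P %*% y))
  }
  nev <- min(k + 8L, n - 1L)
  ncv <- min(n, max(2L * nev + 1L, 20L))
  ar <- igraph::arpack(opfun, sym = TRUE,
                       options = list(n = n, nev = nev, ncv = ncv,
                                      which = "LA", maxiter = 3000, tol = tol))
  theta <- ar$values
  lambda <- sigma + 1 / theta
  ord <- order(lambda)
  lambda <- lambda[ord]
  U <- ar$vectors[, ord, drop = FALSE]
  ## map back: psi = P' L^-T u
  Psi <- as.matrix(Matrix::crossprod(P, Matrix::solve(Matrix::t(L), U)))
  list(values = lambda, vectors = Psi)
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen_basis: %d modes on %d vertices (%s), lambda in [%.3g, %.3g] mm^-2\n",
              ncol(x$modes), nrow(x$modes), x$boundary,
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Mass-weighted inner product of maps with basis modes
#'
#' Computes the spectral coefficients `beta = t(Psi) %*% B %*% y`, the
#' discrete mass inner product of a fully valid (unmasked) map with the
#' eigenmodes. For a complete basis this is the exact adjoint of
#' reconstruction, so `Psi %*% beta` reproduces `y`. Masked maps must be
#' decomposed with [decompose_map()] instead, which fits retained modes
#' to the valid vertices only.
#'
#' @param basis an `eigen_basis` (or a plain matrix of column vectors, in
#'   which case `mass` must be given).
#' @param map a [surface_map()] or numeric vector with no masked entries.
#' @param mass sparse mass matrix when `basis` is a plain matrix.
#' @return numeric vector of coefficients, one per mode.
#' @export
mass_inner_product <- function(basis, map, mass = NULL) {
  map <- as_surface_map(map)
  if (!all(map$mask)) {
    stop_es("mass_inner_product requires a fully valid map; use decompose_map() ",
            "for masked maps", class = "validation_error")
  }
  if (inherits(basis, "eigen_basis")) {
    Psi <- basis$modes
    B <- basis$fem$mass
  } else {
    Psi <- as.matrix(basis)
    B <- mass
    if (is.null(B)) stop_es("mass matrix required", class = "validation_error")
  }
  as.numeric(crossprod(Psi, as.numeric(B %*% map$values)))
}

#' Fraction of the complete surface-mode set retained
#'
#' A surface mesh with `N` vertices carries `N - 1` non-constant
#' eigenmodes (the complete spectral basis once the uniform mode is
#' excluded); this helper expresses a truncation depth as a percentage of
#' that complete set.
#'
#' @param n_modes number of modes retained.
#' @param n_vertices vertex count of the mesh.
#' @return percentage (0-100).
#' @export
mode_fraction <- function(n_modes, n_vertices) {
  stopifnot(n_vertices > 1)
  100 * n_modes / (n_vertices - 1)
}

#' Serialize an eigenbasis to a directory
#'
#' Writes `modes.tsv` (vertices x modes, tab-separated), `eigenvalues.txt`
#' and a JSON provenance record (mesh hash, boundary tag, solver).
#'
#' @param basis an `eigen_basis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_eigenbasis <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(basis$modes, file.path(dir, "modes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("%.17g", basis$eigenvalues), file.path(dir, "eigenvalues.txt"))
  jsonlite::write_json(list(boundary = basis$boundary,
                            mesh_hash = basis$mesh_hash,
                            solver = basis$solver,
                            n_modes = ncol(basis$modes),
                            n_vertices = nrow(basis$modes)),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load an eigenbasis written by [save_eigenbasis()]
#'
#' The FEM pair is not serialized; supply the mesh (or `fem_pair`) so
#' mass inner products remain available.
#'
#' @param dir directory written by [save_eigenbasis()].
#' @param mesh the mesh (or `fem_pair`) the basis belongs to.
#' @return an `eigen_basis`.
#' @export
load_eigenbasis <- function(dir, mesh) {
  modes <- as.matrix(utils::read.table(file.path(dir, "modes.tsv"), sep = "\t"))
  dimnames(modes) <- NULL
  vals <- as.numeric(readLines(file.path(dir, "eigenvalues.txt")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  fem <- if (inherits(mesh, "fem_pair")) mesh else assemble_fem(mesh)
  structure(list(modes = modes, eigenvalues = vals,
                 boundary = prov$boundary, mesh_hash = prov$mesh_hash,
                 fem = fem, solver = prov$solver),
            class = "eigen_basis")
}
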