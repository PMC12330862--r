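#' Pairwise vertex distances on a mesh
#'
#' Returns a condensed set of vertex pairs with their separation in mm,
#' either all unordered pairs or a seeded uniform subsample (the default
#' above 5,000 vertices, where all-pairs storage becomes the bottleneck).
#' Euclidean distances are straight-line; geodesic distances are computed
#' on the triangulated surface with the heat method (Crane-style: short
#' time heat diffusion, normalized gradient, Poisson recovery) and floored
#' at the Euclidean chord length, the analytic lower bound for a surface
#' path. Tetrahedral meshes support the Euclidean metric only.
#'
#' @param mesh a [triangle_mesh()] or [tet_mesh()].
#' @param metric `"euclidean"` or `"geodesic"`.
#' @param subsample optional number of random vertex pairs; `NULL` means
#'   all pairs for meshes up to 5,000 vertices and 200,000 pairs above.
#' @param seed seed for the pair subsample.
#' @return a data.frame of class `pair_distances` with 0-based columns
#'   `i`, `j` (`i < j`) and `d` (mm); attributes `metric` and `n_vertices`.
#' @export
pairwise_distances <- function(mesh, metric = c("euclidean", "geodesic"),
                               subsample = NULL, seed = 1L) {
  metric <- match.arg(metric)
  if (metric == "geodesic" && is_tet_mesh(mesh)) {
    stop_es("geodesic distances are defined for surface meshes only",
            class = "validation_error")
  }
  n <- n_vertices(mesh)
  n2 <- n * (n - 1) / 2
  if (is.null(subsample) && n > 5000L) subsample <- 200000L
  if (!is.null(subsample)) {
    subsample <- min(subsample, n2)
    codes <- withr::with_seed(as.integer(seed), {
      if (n2 <= 2^31 - 1) sort(sample(n2, subsample))
      else sort(unique(ceiling(runif(subsample * 1.05) * n2)))[seq_len(subsample)]
    })
    ## decode condensed index (row-wise upper triangle, i < j, 1-based)
    i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * codes))
    base <- (i - 1) * n - (i - 1) * i / 2     # pairs in rows before i
    j <- codes - base + i
    i <- as.integer(i); j <- as.integer(j)
  } else {
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L, from = 2L) + rep.int(0L:(n - 2L), (n - 1L):1L)
  }
  v <- mesh$vertices
  d_euc <- sqrt(rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2))
  d <- if (metric == "euclidean") d_euc else {
    geo <- geodesic_from_sources(mesh, i, j)
    pmax(geo, d_euc)
  }
  out <- data.frame(i = i - 1L, j = j - 1L, d = d)
  class(out) <- c("pair_distances", "data.frame")
  attr(out, "metric") <- metric
  attr(out, "n_vertices") <- n
  out
}

## heat-method geodesics from each unique source in `i` (1-based)
geodesic_from_sources <- function(mesh, i, j) {
  hm <- heat_method_setup(mesh)
  d <- numeric(length(i))
  for (s in unique(i)) {
    sel <- i == s
    phi <- heat_geodesic(hm, s)
    d[sel] <- phi[j[sel]]
  }
  d
}

heat_method_setup <- function(mesh) {
  fem <- assemble_fem(mesh)
  A <- fem$stiffness
  m_lumped <- Matrix::rowSums(fem$mass)
  ed <- mesh_edges(mesh) + 1L
  h <- mean(sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                            mesh$vertices[ed[, 2], , drop = FALSE])^2)))
  t_heat <- h^2
  n <- n_vertices(mesh)
  heat_op <- Matrix::Diagonal(n, m_lumped) + t_heat * A
  fac_heat <- Matrix::Cholesky(Matrix::forceSymmetric(heat_op), perm = TRUE, LDL = FALSE)
  pois_op <- A + 1e-8 * mean(Matrix::diag(A)) * Matrix::Diagonal(n)
  fac_pois <- Matrix::Cholesky(Matrix::forceSymmetric(pois_op), perm = TRUE, LDL = FALSE)
  f <- mesh$faces + 1L
  v <- mesh$vertices
  e1 <- v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE]  # opposite vertex 1
  e2 <- v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE]
  e3 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cross3(e3, -e2)
  dbl_area <- sqrt(rowSums(nrm^2))
  unit_n <- nrm / dbl_area
  list(mesh = mesh, fac_heat = fac_heat, fac_pois = fac_pois, n = n,
       f = f, e1 = e1, e2 = e2, e3 = e3, unit_n = unit_n, dbl_area = dbl_area)
}

heat_geodesic <- function(hm, source) {
  n <- hm$n
  delta <- numeric(n)
  delta[source] <- 1
  u <- as.numeric(Matrix::solve(hm$fac_heat, delta))
  f <- hm$f
  ## per-face gradient: grad u = (1/2A) sum_i u_i (N x e_i)
  g <- (u[f[, 1]] * cross3(hm$unit_n, hm$e1) +
          u[f[, 2]] * cross3(hm$unit_n, hm$e2) +
          u[f[, 3]] * cross3(hm$unit_n, hm$e3)) / hm$dbl_area
  gn <- sqrt(rowSums(g^2))
  gn[gn == 0] <- 1
  X <- -g / gn
  ## integrated divergence per vertex:
  ## div_i = 1/2 * sum_faces (cot t1 * (e1 . X) + cot t2 * (e2 . X))
  cot_at <- function(a, b) rowSums(a * b) / sqrt(pmax(rowSums(cross3(a, b)^2), 1e-300))
  ## angles at each corner: at vertex 1 between edges (v2-v1) and (v3-v1)
  c1 <- cot_at(hm$e3, -hm$e2)   # angle at vertex 1
  c2 <- cot_at(hm$e1, -hm$e3)   # at vertex 2
  c3 <- cot_at(hm$e2, -hm$e1)   # at vertex 3
  ## edge vectors from each vertex
  d12 <- rowSums(hm$e3 * X); d13 <- rowSums(-hm$e2 * X)
  d21 <- rowSums(-hm$e3 * X); d23 <- rowSums(hm$e1 * X)
  d31 <- rowSums(hm$e2 * X); d32 <- rowSums(-hm$e1 * X)
  div <- numeric(n)
  acc <- function(idx, val) {
    s <- rowsum(val, idx)
    div[as.integer(rownames(s))] <<- div[as.integer(rownames(s))] + s[, 1]
  }
  acc(f[, 1], 0.5 * (c3 * d12 + c2 * d13))
  acc(f[, 2], 0.5 * (c3 * d21 + c1 * d23))
  acc(f[, 3], 0.5 * (c2 * d31 + c1 * d32))
  phi <- as.numeric(Matrix::solve(hm$fac_pois, div))
  phi <- phi - phi[source]
  abs(phi)
}
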