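# Mesh generation, validation, submesh extraction, and file round trips.

test_that("icosphere has the expected combinatorics and geometry", {
  m0 <- ico(0)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m4 <- make_icosphere(4, 2.5)
  expect_equal(nrow(m4$vertices), 10 * 4^4 + 2)
  expect_equal(nrow(m4$faces), 20 * 4^4)
  expect_lt(max(abs(sqrt(rowSums(m4$vertices^2)) - 2.5)), 1e-9 * 2.5)
  ## summed triangle area approaches the analytic sphere area
  m3 <- ico(3)
  expect_lt(abs(sum(triangle_areas(m3)) - 4 * pi) / (4 * pi), 0.015)
})

test_that("Euler characteristic is 2 for closed spheres, 1 after cutting a cap", {
  for (s in 0:3) {
    m <- ico(s)
    ## brute-force edge enumeration
    E <- nrow(mesh_edges(m))
    expect_equal(nrow(m$vertices) - E + nrow(m$faces), 2L)
  }
  cap <- cut_cap_sphere(2)
  E <- nrow(mesh_edges(cap$mesh))
  expect_equal(nrow(cap$mesh$vertices) - E + nrow(cap$mesh$faces), 1L)
  expect_gt(nrow(boundary_edges(cap$mesh)), 0L)
})

test_that("mesh validation rejects bad connectivity", {
  m <- ico(0)
  bad <- m$faces
  bad[3, 2] <- nrow(m$vertices)          # index = N is out of range
  expect_error(triangle_mesh(m$vertices, bad), "out of range",
               class = "validation_error")
  dup <- m$faces
  dup[1, ] <- c(0L, 0L, 1L)
  expect_error(triangle_mesh(m$vertices, dup), "duplicated",
               class = "validation_error")
  degen <- rbind(m$vertices, m$vertices[1, ] * (1 + 1e-17))
  f <- rbind(m$faces, c(0L, 1L, nrow(m$vertices)))
  expect_error(triangle_mesh(degen, f), class = "validation_error")
})

test_that("surface mesh formats round-trip exactly (or to stated precision)", {
  m <- ico(1)
  tmp <- withr::local_tempdir()
  ## text-exact formats
  for (fmt in c("off", "ply")) {
    p <- file.path(tmp, paste0("m.", fmt))
    write_mesh(m, p, fmt)
    m2 <- read_mesh(p, fmt)
    expect_equal(m2$vertices, m$vertices)
    expect_identical(m2$faces, m$faces)
  }
  ## FreeSurfer binary stores float32 coordinates
  p <- file.path(tmp, "lh.sphere")
  write_mesh(m, p, "freesurfer-surface")
  m2 <- read_mesh(p, "freesurfer-surface")
  expect_identical(m2$faces, m$faces)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  ## GIFTI surface (float32)
  p <- file.path(tmp, "m.surf.gii")
  write_mesh(m, p)
  m2 <- read_mesh(p)
  expect_identical(m2$faces, m$faces)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
})

test_that("tet mesh formats round-trip", {
  ball <- cached("ball_small", make_tet_ball(1, 0.35))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "ball.node")
  write_mesh(ball, p, "node-ele")
  b2 <- read_mesh(p, "node-ele")
  expect_equal(b2$vertices, ball$vertices)
  expect_identical(b2$tets, ball$tets)
  p <- file.path(tmp, "ball.vtk")
  write_mesh(ball, p, "vtk")
  b3 <- read_mesh(p, "vtk")
  expect_equal(b3$vertices, ball$vertices)
  expect_identical(b3$tets, ball$tets)
})

test_that("OFF parser reports malformed input", {
  tmp <- withr::local_tempfile(fileext = ".off")
  writeLines(c("not-off", "1 2 3"), tmp)
  expect_error(read_mesh(tmp, "off"), "line", class = "format_error")
  ## face index out of range caught by mesh validation
  tmp2 <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1", "3 0 1 4"),
             tmp2)
  expect_error(read_mesh(tmp2, "off"), class = "validation_error")
})

test_that("map formats round-trip with NaN as the missing-data sentinel", {
  tmp <- withr::local_tempdir()
  vals <- c(1.5, -2.25, NaN, 0.125, 7e-3, exp(1), NA, 42)
  map <- surface_map(vals)
  expect_identical(map$mask, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  ## text: exact for finite values
  p <- file.path(tmp, "m.txt")
  write_map(map, p)
  m2 <- read_map(p)
  expect_identical(m2$mask, map$mask)
  expect_identical(m2$values[m2$mask], map$values[map$mask])
  ## curv / gifti: float32 precision
  for (ext in c("m.curv", "m.func.gii")) {
    p <- file.path(tmp, ext)
    write_map(map, p)
    m3 <- read_map(p)
    expect_identical(m3$mask, map$mask)
    expect_lt(max(abs(m3$values[m3$mask] - map$values[map$mask])), 1e-5)
  }
  ## length check
  expect_error(read_map(file.path(tmp, "m.txt"), n_vertices = 99),
               "99", class = "dimension_error")
})

test_that("NIfTI maps route through an explicit voxel-to-vertex table", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "vol.nii.gz")
  idx <- c(3L, 17L, 42L, 100L)
  map <- surface_map(c(0.5, -1, 2, NaN))
  write_map(map, p, "nifti", dim = c(5, 5, 5), voxel_index = idx)
  m2 <- read_map(p, "nifti", voxel_index = idx)
  expect_identical(m2$mask, map$mask)
  expect_equal(m2$values[m2$mask], map$values[map$mask], tolerance = 1e-7)
})

test_that("a GRF map survives a GIFTI round trip to float32 precision", {
  m <- ico(2, 10)
  vol <- simulate_grf_volume(grf_spec(1.5, 32, 1, 4))
  map <- sample_to_mesh(vol, m)
  tmp <- withr::local_tempfile(fileext = ".func.gii")
  write_map(map, tmp)
  m2 <- read_map(tmp)
  expect_lt(max(abs(m2$values - map$values)), 1e-6)
})

test_that("bumpy sphere is deterministic in its seed and reduces to the icosphere", {
  expect_equal(make_bumpy_sphere(2, 1, 0, seed = 5), ico(2))
  b1 <- make_bumpy_sphere(2, 1, 0.2, seed = 9)
  b2 <- make_bumpy_sphere(2, 1, 0.2, seed = 9)
  expect_identical(b1, b2)
  b3 <- make_bumpy_sphere(2, 1, 0.2, seed = 10)
  expect_false(identical(b1$vertices, b3$vertices))
  expect_true(all(triangle_areas(b1) > 0))
})

test_that("tet ball volume converges to the analytic ball volume", {
  vol_true <- 4 / 3 * pi
  ball <- cached("ball_r6", make_tet_ball(1, 1 / 6))
  v1 <- sum(eigenstrapr:::tet_signed_volumes(ball$vertices, ball$tets))
  expect_lt(abs(v1 - vol_true) / vol_true, 0.05)
  ball2 <- make_tet_ball(1, 1 / 12)
  v2 <- sum(eigenstrapr:::tet_signed_volumes(ball2$vertices, ball2$tets))
  expect_lt(abs(v2 - vol_true), abs(v1 - vol_true))
})

test_that("tet ball interior faces are shared by exactly two tets", {
  ball <- cached("ball_small", make_tet_ball(1, 0.35))
  tt <- ball$tets + 1L
  tri <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)], tt[, c(1, 3, 4)],
               tt[, c(2, 3, 4)])
  key <- apply(tri, 1L, function(r) paste(sort(r), collapse = "-"))
  counts <- table(key)
  expect_true(all(counts <= 2))       # manifold-with-boundary
  expect_true(any(counts == 2))       # has interior faces
})

test_that("extract_submesh keeps exactly the masked vertices and is invertible", {
  m <- ico(2)
  keep <- rep(TRUE, nrow(m$vertices))
  all_kept <- extract_submesh(m, keep)
  expect_equal(all_kept$mesh$vertices, m$vertices)
  expect_identical(all_kept$mesh$faces, m$faces)
  cap <- cut_cap_sphere(2)
  used_in_faces <- sort(unique(as.vector(cap$mesh$faces)))
  expect_identical(used_in_faces, 0:(nrow(cap$mesh$vertices) - 1L))
  ## index table is a bijection
  expect_identical(anyDuplicated(cap$index_map), 0L)
  expect_equal(cap$mesh$vertices,
               m$vertices[cap$index_map + 1L, , drop = FALSE])
})

test_that("disconnected submeshes warn with component sizes, largest kept on request", {
  m <- ico(2)
  two_caps <- abs(m$vertices[, 3]) > 0.62   # two antipodal polar caps
  expect_warning(res <- extract_submesh(m, two_caps), "component sizes")
  expect_silent(res_main <- extract_submesh(m, two_caps, largest_component = TRUE))
  expect_lt(nrow(res_main$mesh$vertices), nrow(res$mesh$vertices))
  ## the kept component is edge-connected: Euler characteristic of a disk
  E <- nrow(mesh_edges(res_main$mesh))
  expect_equal(nrow(res_main$mesh$vertices) - E + nrow(res_main$mesh$faces), 1L)
})

test_that("pairwise distances match a brute-force oracle and are seed-stable", {
  m <- ico(0)
  d <- pairwise_distances(m)
  D <- as.matrix(dist(m$vertices))
  expect_equal(d$d, D[cbind(d$i + 1L, d$j + 1L)], tolerance = 1e-12)
  expect_equal(nrow(d), choose(12, 2))
  ## subsample: reproducible, valid decode
  m3 <- ico(3)
  s1 <- pairwise_distances(m3, subsample = 2000, seed = 7)
  s2 <- pairwise_distances(m3, subsample = 2000, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$i < s1$j))
  chk <- sqrt(rowSums((m3$vertices[s1$i + 1L, ] - m3$vertices[s1$j + 1L, ])^2))
  expect_equal(s1$d, chk)
})

test_that("geodesic distances dominate euclidean and recover sphere arcs", {
  m <- ico(3)
  v <- m$vertices
  anti <- which.min(rowSums(sweep(v, 2, -v[1, ])^2))
  g <- pairwise_distances(m, metric = "geodesic",
                          subsample = NULL)
  e <- pairwise_distances(m, metric = "euclidean")
  expect_true(all(g$d >= e$d - 1e-6 * pmax(e$d, 1)))
  sel <- g$i == 0L & g$j == anti - 1L
  expect_lt(abs(g$d[sel] - pi) / pi, 0.02)  # antipodal arc on the unit sphere
  expect_equal(e$d[sel], 2, tolerance = 1e-9)
})
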