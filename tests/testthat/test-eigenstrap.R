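# The surrogate engine: eigengroup partition, decomposition, rotation,
# reconstruction, amplitude adjustment, mode-count heuristic.

test_that("eigengroup partition has sizes 1,3,5,... and drops incomplete tails", {
  b16 <- ico_basis(3, 1, 16)
  p <- partition_eigengroups(b16)
  expect_identical(p$sizes, c(1L, 3L, 5L, 7L))
  expect_identical(p$group_number, 0:3)
  expect_identical(p$n_dropped, 0L)
  expect_false(p$rotatable[1])
  expect_true(all(p$rotatable[-1]))
  ## kappa * zeta = 1 elementwise for rotatable modes
  rot_idx <- unlist(p$groups[-1])
  expect_equal(p$kappa[rot_idx] * p$zeta[rot_idx], rep(1, length(rot_idx)))
  ## ranges tile [1, 16] without overlap
  expect_identical(sort(unlist(p$groups)), 1:16)
  ## 18 modes: same groups, 2 dropped
  b18 <- compute_eigenbasis(ico(3), 18)
  expect_warning(p18 <- partition_eigengroups(b18), "dropped")
  expect_identical(p18$sizes, c(1L, 3L, 5L, 7L))
  expect_gte(p18$n_dropped, 1L)
  expect_error(partition_eigengroups(list(eigenvalues = c(0, 1, 2))),
               class = "validation_error")
})

test_that("index-based groups coincide with eigenvalue clusters on the sphere", {
  b <- ico_basis(3, 1, 36)
  p <- partition_eigengroups(b)
  ## independent cluster detection by eigenvalue gaps
  ev <- b$eigenvalues[1:36]
  gaps <- which(diff(ev) > 0.5)       # sphere clusters are separated by >> 0.5
  cluster_id <- cumsum(c(1, diff(ev) > 0.5))
  index_id <- rep(seq_along(p$groups), p$sizes)
  expect_identical(as.integer(cluster_id), index_id)
})

test_that("decomposition is complete without a mask and exact for single modes", {
  m <- ico(1)
  b <- compute_eigenbasis(m, 41)
  y <- withr::with_seed(8, rnorm(42))
  d <- decompose_map(y, b, 36)
  expect_identical(d$method, "inner-product")
  y_hat <- as.numeric(b$modes[, 1:36] %*% d$coefficients) + d$residuals
  expect_equal(y_hat, y, tolerance = 1e-10)
  ## y = 3 psi_5 recovers beta exactly
  d5 <- decompose_map(3 * b$modes[, 5], b, 16)
  expect_equal(d5$coefficients[5], 3, tolerance = 1e-8)
  expect_lt(max(abs(d5$coefficients[-5])), 1e-8)
  expect_lt(max(abs(d5$residuals)), 1e-8)
})

test_that("complete decomposition drives the residual to zero", {
  m <- ico(2)
  b <- compute_eigenbasis(m, 161)   # N - 1 = complete
  y <- withr::with_seed(9, rnorm(162))
  d <- decompose_map(y, b, 144)     # largest whole-group count
  ## residual only carries the dropped tail; reconstruct with all modes
  beta_all <- mass_inner_product(b, y)
  expect_lt(sqrt(sum((as.numeric(b$modes %*% beta_all) - y)^2)) / sqrt(sum(y^2)),
            1e-6)
})

test_that("masked decomposition equals the normal-equations oracle", {
  m <- ico(1)
  b <- compute_eigenbasis(m, 16)
  y <- withr::with_seed(10, rnorm(42))
  mask <- rep(TRUE, 42); mask[c(3, 11, 25, 40)] <- FALSE
  yv <- y; yv[!mask] <- NaN
  d <- decompose_map(surface_map(yv), b, 16)
  expect_identical(d$method, "least-squares")
  X <- b$modes[mask, 1:16]
  beta_oracle <- solve(crossprod(X), crossprod(X, y[mask]))
  expect_equal(d$coefficients, as.numeric(beta_oracle), tolerance = 1e-8)
  expect_true(all(is.na(d$residuals[!mask])))
  expect_error(decompose_map(surface_map(c(y[1:10], rep(NA, 32))), b, 16),
               "rank", class = "validation_error")
})

test_that("n_modes not spanning whole groups is truncated with a warning", {
  b <- ico_basis(3, 1, 16)
  y <- withr::with_seed(11, rnorm(642))
  expect_warning(d <- decompose_map(y, b, 15), "whole eigengroups")
  expect_identical(d$n_modes, 9L)
})

test_that("random rotations are orthogonal and Haar-distributed", {
  withr::local_seed(42)
  ## orthogonality at tight tolerance, many draws and sizes
  for (n in c(1, 2, 3, 7, 15)) {
    R <- random_rotation(n)
    expect_lt(max(abs(crossprod(R) - diag(n))), 1e-10)
  }
  ## Monte-Carlo Haar checks at n = 3
  draws <- replicate(10000, random_rotation(3))
  means <- apply(draws, c(1, 2), mean)
  se <- 1 / sqrt(3 * 10000)              # entry variance is 1/3 under Haar
  expect_lt(max(abs(means)), 3.3 * se)
  ## first column is uniform on the sphere: z-coordinate ~ U(-1, 1)
  z <- draws[3, 1, ]
  ks <- suppressWarnings(stats::ks.test(z, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("group rotation preserves orthonormality and group projectors on the sphere", {
  b <- ico_basis(3, 1, 16)
  p <- partition_eigengroups(b)
  ## identity rotations leave the basis untouched
  ident <- lapply(seq_along(p$groups), function(g) {
    if (!p$rotatable[g]) NULL else diag(p$sizes[g])
  })
  r0 <- rotate_groups(b, p, ident)
  expect_equal(r0$modes, b$modes[, 1:16])
  ## random rotation: B-orthonormality preserved under exact degeneracy
  ## (the l = 3 group's FEM eigenvalues are split by the icosahedral mesh,
  ## so its tolerance follows the eigenvalue spread rather than 1e-8)
  withr::local_seed(5)
  r1 <- rotate_groups(b, p)
  Bm <- b$fem$mass
  G <- crossprod(r1$modes, as.matrix(Bm %*% r1$modes))
  expect_lt(max(abs(G[1:9, 1:9] - diag(9))), 1e-8)
  spread3 <- diff(range(b$eigenvalues[10:16])) / mean(b$eigenvalues[10:16])
  expect_lt(max(abs(G - diag(16))), 10 * spread3)
  ## group projector Psi_L diag(kappa^2) Psi_L' B is rotation invariant
  for (g in 2:4) {
    idx <- p$groups[[g]]
    proj <- function(M) {
      M[, idx] %*% (t(M[, idx]) * p$kappa[idx]^2) %*% as.matrix(Bm)
    }
    expect_lt(max(abs(proj(r1$modes) - proj(b$modes[, 1:16]))), 1e-7)
  }
})

test_that("rotating a zero-eigenvalue group is rejected", {
  b <- ico_basis(3, 1, 16)
  p <- partition_eigengroups(b)
  p$kappa[p$groups[[2]]] <- NA_real_   # simulate lambda = 0 in a rotatable group
  expect_error(rotate_groups(b, p), "kappa", class = "validation_error")
})

test_that("identity rotations + identity permutation reproduce the input exactly", {
  m <- ico(2)
  b <- compute_eigenbasis(m, 161)
  p <- suppressWarnings(partition_eigengroups(b))
  y <- withr::with_seed(12, rnorm(162))
  d <- decompose_map(y, b, p$n_used)
  ident <- lapply(seq_along(p$groups), function(g) {
    if (!p$rotatable[g]) NULL else diag(p$sizes[g])
  })
  gamma <- eigenstrapr:::apply_group_rotations(d$coefficients, p, ident,
                                               length(p$groups))
  expect_equal(gamma, d$coefficients, tolerance = 1e-12)
  y_surr <- as.numeric(b$modes[, 1:p$n_used] %*% gamma) + d$residuals
  expect_equal(y_surr, y, tolerance = 1e-8)
})

test_that("surrogates regenerate bit-identically from their seed", {
  m <- ico(2)
  b <- compute_eigenbasis(m, 144)
  y <- withr::with_seed(13, rnorm(162))
  p <- suppressWarnings(partition_eigengroups(b))
  opts <- surrogate_options(n_modes = 100, n_surrogates = 4, seed = 99)
  e1 <- generate_surrogates(y, b, opts, partition = p)
  e2 <- generate_surrogates(y, b, opts, partition = p)
  expect_identical(e1$maps, e2$maps)
  expect_identical(e1$provenance$surrogate_seeds, e2$provenance$surrogate_seeds)
  ## truncated to whole groups
  expect_identical(e1$provenance$n_modes, 100L)
  ## different seed, different maps
  opts2 <- surrogate_options(n_modes = 100, n_surrogates = 4, seed = 100)
  expect_false(identical(generate_surrogates(y, b, opts2, partition = p)$maps,
                         e1$maps))
})

test_that("per-group power is conserved exactly in degenerate groups", {
  b <- ico_basis(3, 1, 36)
  p <- partition_eigengroups(b)
  y <- withr::with_seed(14, rnorm(642))
  opts <- surrogate_options(n_modes = 36, amplitude_adjust = FALSE,
                            residual_policy = "zero", n_surrogates = 8, seed = 3)
  ens <- generate_surrogates(y, b, opts, partition = p)
  beta0 <- decompose_map(y, b, 36)$coefficients
  spread <- vapply(p$groups, function(i) {
    ev <- b$eigenvalues[i]
    diff(range(ev)) / mean(ev)
  }, numeric(1))
  for (s in seq_len(8)) {
    beta1 <- decompose_map(ens$maps[, s], b, 36)$coefficients
    for (g in 2:length(p$groups)) {
      i <- p$groups[[g]]
      rel <- abs(sum(beta1[i]^2) - sum(beta0[i]^2)) / sum(beta0[i]^2)
      if (spread[g] < 1e-10) {
        expect_lt(rel, 1e-8)                 # exact degeneracy: exact conservation
      } else {
        expect_lt(rel, 50 * spread[g] + 1e-8)  # tolerance grows with the split
      }
    }
    ## constant-mode contribution (the mean) is carried over verbatim
    expect_equal(beta1[1], beta0[1], tolerance = 1e-10)
  }
})

test_that("amplitude adjustment is a multiset-exact, idempotent monotone remap", {
  withr::local_seed(15)
  orig <- rexp(300)              # deliberately non-Gaussian
  surr <- rnorm(300)
  adj <- amplitude_adjust(surr, orig)
  expect_identical(sort(adj), sort(orig))
  expect_equal(cor(adj, surr, method = "spearman"), 1)
  expect_identical(amplitude_adjust(adj, orig), adj)
  ## respects masks
  mask <- c(rep(TRUE, 250), rep(FALSE, 50))
  adj_m <- amplitude_adjust(surr, orig, mask)
  expect_identical(sort(adj_m[mask]), sort(orig[mask]))
  expect_true(all(is.na(adj_m[!mask])))
})

test_that("unadjusted surrogates of a skewed map Gaussianize as modes accumulate", {
  m <- ico(3)
  b <- cached("basis_3_1_144", compute_eigenbasis(m, 144))
  vol <- simulate_grf_volume(grf_spec(2, 32, 1/10, 21))
  base <- sample_to_mesh(vol, m, voxel_size = 1/10)
  skewed <- exp(base$values)     # lognormal amplitude distribution
  skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
  opts <- surrogate_options(n_modes = 144, amplitude_adjust = FALSE,
                            residual_policy = "zero", n_surrogates = 30, seed = 2)
  ens <- generate_surrogates(skewed, b, opts)
  sk_orig <- skewness(skewed)
  sk_surr <- mean(apply(ens$maps, 2, skewness))
  expect_lt(abs(sk_surr), abs(sk_orig) / 2)
  ## amplitude adjustment restores the original multiset exactly
  opts_adj <- surrogate_options(n_modes = 144, amplitude_adjust = TRUE,
                                residual_policy = "zero", n_surrogates = 3, seed = 2)
  ens_adj <- generate_surrogates(skewed, b, opts_adj)
  expect_identical(sort(ens_adj$maps[, 1]), sort(skewed))
})

test_that("surrogates of masked maps never place values in the masked region", {
  m <- ico(2)
  b <- compute_eigenbasis(m, 100)
  mask <- m$vertices[, 3] < 0.8
  y <- withr::with_seed(16, rnorm(162))
  y[!mask] <- NaN
  opts <- surrogate_options(n_modes = 64, n_surrogates = 5, seed = 4)
  ens <- generate_surrogates(surface_map(y), b, opts)
  expect_true(all(is.na(ens$maps[!mask, ])))
  expect_true(all(is.finite(ens$maps[mask, ])))
  expect_identical(ens$mask, mask)
})

test_that("surrogate-surrogate correlations are zero centered", {
  m <- ico(3)
  b <- cached("basis_3_1_144", compute_eigenbasis(m, 144))
  vol <- simulate_grf_volume(grf_spec(1.5, 32, 1/10, 31))
  y <- sample_to_mesh(vol, m, voxel_size = 1/10)
  opts <- surrogate_options(n_modes = 144, n_surrogates = 120, seed = 8)
  ens <- generate_surrogates(y, b, opts)
  C <- cor(ens$maps)
  rr <- C[upper.tri(C)]
  ## mean within 3 standard errors of zero
  expect_lt(abs(mean(rr)), 3 * sd(rr) / sqrt(length(rr) / 60))
  ## (the correlations share surrogates, so use a conservative effective n)
})

test_that("the FWHM heuristic keeps more groups for rougher maps", {
  m <- ico(3)
  b <- cached("basis_3_1_144", compute_eigenbasis(m, 144))
  p <- partition_eigengroups(b)
  dst <- ico_distances(3, 1, subsample = 30000)
  ## white vertex noise: every whole group of the basis
  white <- withr::with_seed(17, rnorm(642))
  expect_identical(choose_n_modes(white, b, p, dst), p$n_used)
  ## a single coarse mode (l = 2) plus tiny noise: only a few coarse groups
  coarse <- b$modes[, 6] + withr::with_seed(18, rnorm(642)) * 1e-3
  n_coarse <- choose_n_modes(coarse, b, p, dst)
  expect_lte(n_coarse, 25L)         # at most a handful of groups
  expect_gte(n_coarse, 4L)          # always at least one rotatable group
  expect_lt(n_coarse, p$n_used)
})

test_that("the chosen mode count is non-increasing in map smoothness", {
  m <- cached("ico_3_28", make_icosphere(3, 28))
  b <- cached("basis28_225", compute_eigenbasis(m, 225))
  p <- partition_eigengroups(b)
  dst <- cached("dist28", pairwise_distances(m, subsample = 30000, seed = 11))
  counts <- vapply(c(0, 1.5, 3), function(a) {
    mean(vapply(1:4, function(k) {
      pr <- simulate_grf_pair(a, m, seed = 1000 + k)
      choose_n_modes(pr$y, b, p, dst)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})
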