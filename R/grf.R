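#' Gaussian random field specification
#'
#' Describes a 3-D Gaussian random field with power-law power spectral
#' density `P(k) ~ |k|^(-alpha)`: `alpha = 0` is white Gaussian noise,
#' larger `alpha` gives smoother fields (more spatial autocorrelation).
#'
#' @param alpha spectral slope, `>= 0`.
#' @param grid_n voxels per axis (`>= 16`).
#' @param voxel_size voxel edge in mm.
#' @param seed integer seed; the field is a pure function of the spec.
#' @return a `grf_spec` list.
#' @export
grf_spec <- function(alpha = 1, grid_n = 64L, voxel_size = 1, seed = 1L) {
  stopifnot(alpha >= 0, grid_n >= 16L, voxel_size > 0)
  structure(list(alpha = alpha, grid_n = as.integer(grid_n),
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "grf_spec")
}

#' Simulate a 3-D Gaussian random field with power-law spectrum
#'
#' Spectral synthesis: a white Gaussian field is Fourier transformed, its
#' spectrum scaled by `|k|^(-alpha/2)` (zero-frequency term set to 0),
#' inverse transformed, and the result standardized to mean 0, variance 1.
#' `alpha = 0` reduces to iid noise up to the standardization.
#'
#' @param spec a [grf_spec()].
#' @return 3-D array of standardized field values; attribute `voxel_size`.
#' @export
simulate_grf_volume <- function(spec) {
  n <- spec$grid_n
  w <- withr::with_seed(spec$seed, array(rnorm(n^3), dim = c(n, n, n)))
  if (spec$alpha > 0) {
    freq <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
    k2 <- outer(outer(freq^2, freq^2, "+"), freq^2, "+")
    amp <- array(0, dim = dim(k2))
    amp[k2 > 0] <- k2[k2 > 0]^(-spec$alpha / 4)   # |k|^(-alpha/2)
    f <- fft(w) * amp
    w <- Re(fft(f, inverse = TRUE)) / n^3
  }
  w <- (w - mean(w)) / sd(w)
  attr(w, "voxel_size") <- spec$voxel_size
  w
}

#' Sample a volume onto mesh vertices by trilinear interpolation
#'
#' The voxel grid is centered on the origin: voxel `(i, j, k)` has
#' coordinate `((i - (n+1)/2) * voxel_size, ...)` mm. Every mesh vertex
#' must lie inside the grid with a margin of at least 2 voxels. An
#' optional mask is applied afterwards (masked vertices become NaN, the
#' medial-wall convention).
#'
#' @param volume 3-D array (with `voxel_size` attribute, or pass
#'   `voxel_size`).
#' @param mesh a [triangle_mesh()] or [tet_mesh()].
#' @param voxel_size voxel edge in mm.
#' @param mask optional logical per-vertex mask applied to the result.
#' @return a [surface_map()].
#' @export
sample_to_mesh <- function(volume, mesh, voxel_size = NULL, mask = NULL) {
  voxel_size <- voxel_size %||% attr(volume, "voxel_size") %||% 1
  n <- dim(volume)[1]
  ## continuous voxel coordinates (1-based grid index space)
  gc <- mesh$vertices / voxel_size + (n + 1) / 2
  if (any(gc < 3 - 1e-9) || any(gc > n - 2 + 1e-9)) {
    stop_es("mesh does not fit inside the volume with a 2-voxel margin",
            class = "validation_error")
  }
  i0 <- pmin(floor(gc[, 1]), n - 1L); fx <- gc[, 1] - i0
  j0 <- pmin(floor(gc[, 2]), n - 1L); fy <- gc[, 2] - j0
  k0 <- pmin(floor(gc[, 3]), n - 1L); fz <- gc[, 3] - k0
  at <- function(di, dj, dk) volume[cbind(i0 + di, j0 + dj, k0 + dk)]
  vals <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  if (!is.null(mask)) vals[!mask] <- NaN
  surface_map(vals)
}

#' Simulate a pair of GRF maps on a mesh
#'
#' With `rho = NULL` the two maps are sampled from independent fields
#' (their sample correlation scatters around zero, increasingly widely
#' for larger `alpha`). With `rho` set, the second volume is mixed as
#' `z = rho * y + sqrt(1 - rho^2) * w` at the volume stage, before mesh
#' sampling, so both maps are exchangeable GRFs of the same `alpha`.
#'
#' @param alpha spectral slope.
#' @param mesh target mesh.
#' @param rho target correlation in `(-1, 1)`, `NULL` for independent
#'   pairs, or exactly 1 (test hook: returns `z = y`).
#' @param seed integer seed.
#' @param grid_n,voxel_size grid settings, see [grf_spec()].
#' @param mask optional per-vertex mask applied to both maps.
#' @return list with [surface_map()]s `y` and `z`.
#' @export
simulate_grf_pair <- function(alpha, mesh, rho = NULL, seed = 1L,
                              grid_n = 64L, voxel_size = 1, mask = NULL) {
  if (!is.null(rho)) stopifnot(abs(rho) <= 1)
  seeds <- derive_seeds(seed, 2L, stream = "grf-pair")
  vy <- simulate_grf_volume(grf_spec(alpha, grid_n, voxel_size, seeds[1]))
  vz <- if (!is.null(rho) && rho == 1) vy else {
    w <- simulate_grf_volume(grf_spec(alpha, grid_n, voxel_size, seeds[2]))
    if (is.null(rho)) w else rho * vy + sqrt(1 - rho^2) * w
  }
  list(y = sample_to_mesh(vy, mesh, voxel_size, mask),
       z = sample_to_mesh(vz, mesh, voxel_size, mask))
}

#' Composite map pair with heterogeneous smoothness
#'
#' Builds a pair of maps whose smoothness differs between the two halves
#' of the mesh: the front half (first coordinate above the splitting
#' plane) takes vertices from a high-`alpha` (smooth) field and the rear
#' half from a low-`alpha` (rough) field. Each composite map is built the
#' same way from its own independent field pair, and the two composites
#' are mutually independent.
#'
#' @param alpha_low,alpha_high spectral slopes of the rear and front
#'   halves (`alpha_high > alpha_low` except in degenerate test cases).
#' @param mesh target mesh.
#' @param seed integer seed.
#' @param axis coordinate axis (1-3) defining the splitting plane.
#' @param grid_n,voxel_size,mask as in [simulate_grf_pair()].
#' @return list with maps `y`, `z`, logical `front`, and `delta_alpha`.
#' @export
make_heterogeneous_pair <- function(alpha_low, alpha_high, mesh, seed = 1L,
                                    axis = 1L, grid_n = 64L, voxel_size = 1,
                                    mask = NULL) {
  stopifnot(alpha_high >= alpha_low)
  front <- mesh$vertices[, axis] >= stats::median(mesh$vertices[, axis])
  seeds <- derive_seeds(seed, 4L, stream = "heterogeneous")
  build <- function(s_low, s_high) {
    lo <- sample_to_mesh(simulate_grf_volume(
      grf_spec(alpha_low, grid_n, voxel_size, s_low)), mesh, voxel_size)
    hi <- sample_to_mesh(simulate_grf_volume(
      grf_spec(alpha_high, grid_n, voxel_size, s_high)), mesh, voxel_size)
    vals <- ifelse(front, hi$values, lo$values)
    if (!is.null(mask)) vals[!mask] <- NaN
    surface_map(vals)
  }
  list(y = build(seeds[1], seeds[2]), z = build(seeds[3], seeds[4]),
       front = front, delta_alpha = alpha_high - alpha_low)
}
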