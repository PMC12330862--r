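#' Pearson correlation between two maps over their joint mask
#'
#' The test statistic for map-to-map association: the sample correlation
#' over vertices where both maps are valid. Masked vertices carry no
#' information and are excluded.
#'
#' @param y,z [surface_map()] objects or numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(y, z) {
  y <- as_surface_map(y); z <- as_surface_map(z)
  if (length(y$values) != length(z$values)) {
    stop_es("maps differ in length: ", length(y$values), " vs ", length(z$values),
            class = "dimension_error")
  }
  joint <- y$mask & z$mask
  if (sum(joint) < 3L) stop_es("joint mask has fewer than 3 vertices",
                               class = "validation_error")
  yv <- y$values[joint]; zv <- z$values[joint]
  if (sd(yv) == 0) stop_es("first map has zero variance on the joint mask",
                           class = "validation_error")
  if (sd(zv) == 0) stop_es("second map has zero variance on the joint mask",
                           class = "validation_error")
  cor(yv, zv)
}

#' Empirical variogram (Matheron estimator)
#'
#' `gamma(h) = (1 / (2 |N(h)|)) * sum over pairs in N(h) of (y_i - y_j)^2`
#' binned by separation distance. Pairs touching a masked vertex are
#' excluded; empty bins are reported as `NA`, never 0.
#'
#' @param map a [surface_map()] or numeric vector.
#' @param distances a `pair_distances` object on the same mesh.
#' @param bins number of equal-width bins over `(0, max_lag]`.
#' @param max_lag largest separation considered (mm); defaults to 1/4 of
#'   the maximum pairwise distance.
#' @return an object of class `es_variogram`: data.frame with `lower`,
#'   `upper`, `center` (mm), `gamma` (map units squared) and `n_pairs`.
#' @export
variogram <- function(map, distances, bins = 25L, max_lag = NULL) {
  map <- as_surface_map(map)
  n <- attr(distances, "n_vertices")
  if (!is.null(n) && n != length(map$values)) {
    stop_es("distances were computed on a ", n, "-vertex mesh, map has ",
            length(map$values), class = "dimension_error")
  }
  max_lag <- max_lag %||% (max(distances$d) / 4)
  i <- distances$i + 1L; j <- distances$j + 1L
  ok <- map$mask[i] & map$mask[j] & distances$d > 0 & distances$d <= max_lag
  d <- distances$d[ok]
  sq <- (map$values[i[ok]] - map$values[j[ok]])^2
  edges <- seq(0, max_lag, length.out = bins + 1L)
  bin <- pmin(pmax(ceiling(d / (max_lag / bins)), 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  sums <- numeric(bins)
  agg <- rowsum(sq, bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  gamma <- ifelse(counts > 0, sums / (2 * counts), NA_real_)
  out <- data.frame(lower = edges[-(bins + 1L)], upper = edges[-1L],
                    center = (edges[-1L] + edges[-(bins + 1L)]) / 2,
                    gamma = gamma, n_pairs = counts)
  class(out) <- c("es_variogram", "data.frame")
  attr(out, "max_lag") <- max_lag
  out
}

#' Spatial weight matrices for Moran's I
#'
#' `"adjacency"`: 1 for mesh edges, 0 elsewhere. `"inverse-distance"`:
#' `1/d_ij` over the pairs present in a `pair_distances` object (all
#' pairs, or the seeded subsample for large meshes).
#'
#' @param x a mesh (for `adjacency`) or a `pair_distances` object (for
#'   `inverse-distance`).
#' @param scheme weighting scheme.
#' @return a symmetric sparse weight matrix with zero diagonal.
#' @export
build_weights <- function(x, scheme = c("inverse-distance", "adjacency")) {
  scheme <- match.arg(scheme)
  if (scheme == "adjacency") {
    stopifnot(inherits(x, "es_mesh"))
    ed <- mesh_edges(x) + 1L
    n <- n_vertices(x)
    Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                         x = 1, dims = c(n, n))
  } else {
    stopifnot(inherits(x, "pair_distances"))
    n <- attr(x, "n_vertices")
    pos <- x$d > 0
    Matrix::sparseMatrix(i = c(x$i[pos], x$j[pos]) + 1L,
                         j = c(x$j[pos], x$i[pos]) + 1L,
                         x = rep(1 / x$d[pos], 2L), dims = c(n, n))
  }
}

#' Moran's I global spatial autocorrelation
#'
#' `I = (n / sum(w)) * sum_ij w_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i - ybar)^2`
#' over valid vertices. Positive for smooth maps, negative for
#' checkerboard-like alternation.
#'
#' @param map a [surface_map()] or numeric vector.
#' @param weights square weight matrix (zero diagonal, nonnegative).
#' @return Moran's I.
#' @export
morans_i <- function(map, weights) {
  map <- as_surface_map(map)
  n_all <- length(map$values)
  if (nrow(weights) != n_all) {
    stop_es("weights are ", nrow(weights), " x ", ncol(weights),
            " but map has ", n_all, " vertices", class = "dimension_error")
  }
  valid <- map$mask
  W <- weights[valid, valid, drop = FALSE]
  if (any(Matrix::diag(W) != 0)) stop_es("weights must have zero diagonal",
                                         class = "validation_error")
  yv <- map$values[valid]
  n <- length(yv)
  dev <- yv - mean(yv)
  ss <- sum(dev^2)
  if (ss == 0) stop_es("map has zero variance", class = "validation_error")
  sw <- sum(W)
  if (sw <= 0) stop_es("weights have no positive entries among valid vertices",
                       class = "validation_error")
  (n / sw) * sum(dev * as.numeric(W %*% dev)) / ss
}

#' Estimate a map's characteristic FWHM from its variogram
#'
#' Uses the spatial autocorrelation proxy `rho(h) = 1 - gamma(h)/sill`
#' with the sill set to the map variance, and returns `2 * h_half` where
#' `rho(h_half) = 0.5` by linear interpolation between bin centers
#' (anchored at `rho(0) = 1`). For white noise the crossing falls inside
#' the first bin, so the estimate is at or below the first bin center.
#'
#' @param map a [surface_map()] or numeric vector.
#' @param distances a `pair_distances` object.
#' @param bins,max_lag forwarded to [variogram()].
#' @return FWHM in mm.
#' @export
estimate_fwhm <- function(map, distances, bins = 25L, max_lag = NULL) {
  map <- as_surface_map(map)
  yv <- map$values[map$mask]
  sill <- var(yv)
  if (!is.finite(sill) || sill <= 0) {
    stop_es("map has no positive variance; FWHM undefined",
            class = "validation_error")
  }
  vg <- variogram(map, distances, bins = bins, max_lag = max_lag)
  ok <- !is.na(vg$gamma)
  h <- c(0, vg$center[ok])
  rho <- c(1, 1 - vg$gamma[ok] / sill)
  cross <- which(rho <= 0.5)[1]
  if (is.na(cross)) {
    stop(rlang::error_cnd(
      class = c("eigenstrapr_no_crossing", "eigenstrapr_error"),
      message = paste0("spatial correlation never decays below 0.5 within max_lag = ",
                       format(attr(vg, "max_lag"), digits = 4),
                       " mm; increase max_lag")))
  }
  h_half <- if (cross == 1L) h[1] else {
    h[cross - 1] + (0.5 - rho[cross - 1]) * (h[cross] - h[cross - 1]) /
      (rho[cross] - rho[cross - 1])
  }
  2 * h_half
}

#' Modal power spectrum by eigengroup
#'
#' Per-group power `P_L = sum of beta^2 over the group's modes`; the
#' constant group (the squared mean loading) is reported separately via
#' the group number 0.
#'
#' @param decomposition a [decompose_map()] result.
#' @param partition the matching [partition_eigengroups()].
#' @return data.frame with `group` (degree), `size` and `power`.
#' @export
modal_power_spectrum <- function(decomposition, partition) {
  beta <- decomposition$coefficients
  ng <- decomposition$n_groups
  if (partition$n_used < decomposition$n_modes) {
    stop_es("partition and decomposition do not share a basis",
            class = "validation_error")
  }
  data.frame(group = partition$group_number[seq_len(ng)],
             size = partition$sizes[seq_len(ng)],
             power = vapply(partition$groups[seq_len(ng)],
                            function(idx) sum(beta[idx]^2), numeric(1)))
}

#' Two-tailed nonparametric p-value from a surrogate null
#'
#' `p = (1 + #{|r_null| >= |r_obs|}) / (1 + S)`; the add-one convention
#' guarantees `p in (0, 1]` and exactness of the permutation bound.
#'
#' @param r_obs observed statistic.
#' @param r_null numeric vector of S null statistics.
#' @return list of class `null_test`: `r_obs`, `r_null`, `p`,
#'   `n_extreme`, `S`.
#' @export
nonparametric_p <- function(r_obs, r_null) {
  S <- length(r_null)
  stopifnot(S >= 1L)
  n_extreme <- sum(abs(r_null) >= abs(r_obs))
  structure(list(r_obs = r_obs, r_null = r_null,
                 p = (1 + n_extreme) / (1 + S),
                 n_extreme = n_extreme, S = S),
            class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("null_test: r_obs = %.4f, p = %.4g (S = %d surrogates)\n",
              x$r_obs, x$p, x$S))
  invisible(x)
}

#' Family-wise error corrected p-values (max-statistic)
#'
#' Westfall-Young style single-step correction over a family of target
#' maps tested against one shared surrogate ensemble: for surrogate `s`
#' the max statistic is `m_s = max_t |r_null[t, s]|`, and the adjusted
#' p-value of target `t` is `(1 + #{m_s >= |r_obs_t|}) / (1 + S)`.
#' Adjusted p-values are never smaller than the unadjusted ones.
#'
#' @param r_obs numeric vector of observed correlations, one per target.
#' @param r_null matrix of null correlations, targets x surrogates (all
#'   targets share the same S).
#' @return data.frame with `r_obs`, `p` (unadjusted) and `p_fwe`.
#' @export
fwe_correct <- function(r_obs, r_null) {
  r_null <- as.matrix(r_null)
  if (length(r_obs) != nrow(r_null)) {
    stop_es("r_obs has ", length(r_obs), " targets but r_null has ",
            nrow(r_null), " rows", class = "dimension_error")
  }
  S <- ncol(r_null)
  m <- apply(abs(r_null), 2L, max)
  p_raw <- vapply(seq_along(r_obs), function(t) {
    (1 + sum(abs(r_null[t, ]) >= abs(r_obs[t]))) / (1 + S)
  }, numeric(1))
  p_fwe <- vapply(abs(r_obs), function(a) (1 + sum(m >= a)) / (1 + S), numeric(1))
  data.frame(r_obs = r_obs, p = p_raw, p_fwe = pmax(p_fwe, p_raw))
}

#' Correlation test of two maps against an eigenstrapped null
#'
#' Convenience wrapper: correlates every surrogate of `y` with `z` and
#' returns the two-tailed surrogate p-value for the observed correlation.
#'
#' @param y,z [surface_map()] objects (surrogates are generated from `y`).
#' @param ensemble a `surrogate_ensemble` of `y` (from
#'   [generate_surrogates()]).
#' @return a `null_test`.
#' @export
compare_maps <- function(y, z, ensemble) {
  y <- as_surface_map(y); z <- as_surface_map(z)
  r_obs <- pearson_r(y, z)
  r_null <- surrogate_correlations(ensemble, z)
  nonparametric_p(r_obs, r_null)
}

## fast correlation of every ensemble column with a target map
surrogate_correlations <- function(ensemble, z) {
  z <- as_surface_map(z)
  joint <- ensemble$mask & z$mask
  Y <- ensemble$maps[joint, , drop = FALSE]
  zv <- z$values[joint]
  Yc <- sweep(Y, 2L, colMeans(Y))
  zc <- zv - mean(zv)
  num <- as.numeric(crossprod(Yc, zc))
  den <- sqrt(colSums(Yc^2) * sum(zc^2))
  num / den
}
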