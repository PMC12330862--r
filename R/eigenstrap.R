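#' Partition eigenmodes into eigengroups
#'
#' Assigns modes, in ascending-eigenvalue index order, to groups of sizes
#' 1, 3, 5, 7, ... mirroring the spherical-harmonic multiplicity
#' `2L + 1` of degree `L`. On a sphere the index groups coincide with the
#' degenerate eigenvalue clusters; on folded geometry the grouping is by
#' index position, which is deterministic and keeps group sizes fixed.
#' Trailing modes that do not complete a group are dropped with a
#' warning. The size-1 constant group (eigenvalue 0) is flagged
#' non-rotatable.
#'
#' @param basis an `eigen_basis` (ascending eigenvalues).
#' @return an object of class `eigengroup_partition`: list with `groups`
#'   (list of integer index vectors, 1-based into the basis), `group_number`
#'   (the degree `L` per group), `kappa`/`zeta` (per-mode `lambda^(-1/2)` /
#'   `lambda^(1/2)`), `xi` (per-group mean eigenvalue), `rotatable`,
#'   `n_used`, `n_dropped`.
#' @export
partition_eigengroups <- function(basis) {
  vals <- basis$eigenvalues
  M <- length(vals)
  if (M < 4L) stop_es("need at least 4 modes to form a rotatable eigengroup, got ",
                      M, class = "validation_error")
  if (is.unsorted(vals, strictly = FALSE)) {
    stop_es("basis eigenvalues must be ascending", class = "validation_error")
  }
  n_groups <- as.integer(floor(sqrt(M)))  # 1 + 3 + ... + (2L+1) = (L+1)^2
  n_used <- n_groups * n_groups
  n_dropped <- as.integer(M) - n_used
  if (n_dropped > 0) {
    warning(n_dropped, " trailing mode(s) dropped: they do not complete an eigengroup")
  }
  sizes <- 2L * seq_len(n_groups) - 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  groups <- Map(seq.int, starts, ends)
  kappa <- rep(NA_real_, n_used)
  zeta <- rep(NA_real_, n_used)
  nz <- vals[seq_len(n_used)] > 0
  kappa[nz] <- vals[seq_len(n_used)][nz]^(-0.5)
  zeta[nz] <- vals[seq_len(n_used)][nz]^(0.5)
  structure(list(groups = groups,
                 group_number = seq_len(n_groups) - 1L,
                 sizes = sizes,
                 kappa = kappa, zeta = zeta,
                 xi = vapply(groups, function(g) mean(vals[g]), numeric(1)),
                 rotatable = sizes > 1L,
                 n_used = n_used, n_dropped = n_dropped),
            class = "eigengroup_partition")
}

#' @export
print.eigengroup_partition <- function(x, ...) {
  cat(sprintf("eigengroup_partition: %d groups (%d modes used, %d dropped)\n",
              length(x$groups), x$n_used, x$n_dropped))
  invisible(x)
}

#' Decompose a map onto eigenmodes
#'
#' For fully valid maps the coefficients are the mass inner products
#' `beta = t(Psi) %*% B %*% y`. For masked maps (medial wall) the
#' retained modes are fit to the valid vertices by ordinary least squares
#' (optionally mass-weighted), the linear-model route that accommodates a
#' boundary. The residual is defined on valid vertices only. `n_modes` is
#' truncated down to a whole number of eigengroups.
#'
#' @param map a [surface_map()] or numeric vector.
#' @param basis an `eigen_basis`.
#' @param n_modes number of leading modes to retain (default: all modes
#'   that complete eigengroups).
#' @param weighted use mass-weighted least squares for masked maps.
#' @return an object of class `map_decomposition`: `coefficients`,
#'   `residuals` (NA at masked vertices), `mask`, `n_modes`, `n_groups`,
#'   `method` (`"inner-product"` or `"least-squares"`).
#' @export
decompose_map <- function(map, basis, n_modes = NULL, weighted = FALSE) {
  map <- as_surface_map(map)
  if (length(map$values) != nrow(basis$modes)) {
    stop_es("map has ", length(map$values), " values but basis has ",
            nrow(basis$modes), " vertices", class = "dimension_error")
  }
  M <- ncol(basis$modes)
  n_modes <- n_modes %||% as.integer(floor(sqrt(M))^2)
  whole <- as.integer(floor(sqrt(n_modes))^2)
  if (whole < n_modes) {
    warning("n_modes = ", n_modes, " does not span whole eigengroups; truncated to ",
            whole)
    n_modes <- whole
  }
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L || n_modes > M) {
    stop_es("n_modes must be in [1, ", M, "]", class = "validation_error")
  }
  Psi <- basis$modes[, seq_len(n_modes), drop = FALSE]
  valid <- map$mask
  if (all(valid)) {
    beta <- as.numeric(crossprod(Psi, as.numeric(basis$fem$mass %*% map$values)))
    method <- "inner-product"
  } else {
    if (sum(valid) < n_modes) {
      stop_es("rank error: ", sum(valid), " valid vertices < ", n_modes, " modes",
              class = "validation_error")
    }
    X <- Psi[valid, , drop = FALSE]
    yv <- map$values[valid]
    if (weighted) {
      w <- Matrix::rowSums(basis$fem$mass)[valid]
      beta <- qr.coef(qr(X * sqrt(w)), yv * sqrt(w))
    } else {
      beta <- qr.coef(qr(X), yv)
    }
    beta <- as.numeric(beta)
    method <- "least-squares"
  }
  fit <- as.numeric(Psi %*% beta)
  res <- map$values - fit
  res[!valid] <- NA_real_
  structure(list(coefficients = beta, residuals = res, mask = valid,
                 n_modes = n_modes, n_groups = as.integer(sqrt(n_modes)),
                 method = method),
            class = "map_decomposition")
}

#' Haar-distributed random orthogonal matrix
#'
#' Draws from the Haar (uniform) measure on the orthogonal group `O(n)`
#' via QR decomposition of a standard-normal matrix with the
#' sign-of-diagonal correction; reflections are included, since eigenmode
#' sign is arbitrary. `n = 1` returns +1 or -1 with equal probability.
#' Uses R's global RNG stream; seed outside for reproducibility.
#'
#' @param n dimension.
#' @return an `n x n` orthogonal matrix.
#' @export
random_rotation <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(matrix(sample(c(-1, 1), 1L), 1L, 1L))
  qrz <- qr(matrix(rnorm(n * n), n, n))
  Q <- qr.Q(qrz)
  d <- sign(diag(qr.R(qrz)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, "*")
}

## per-group coefficient-space rotation operator:
## gamma_L = diag(kappa_L) R_L diag(zeta_L) beta_L, so that
## Psi_L' beta_L = Psi_L gamma_L. Returns the list of R_L (NULL for the
## constant group) drawn from the current RNG stream.
draw_group_rotations <- function(partition, n_groups) {
  lapply(seq_len(n_groups), function(g) {
    if (!partition$rotatable[g]) return(NULL)
    random_rotation(partition$sizes[g])
  })
}

apply_group_rotations <- function(beta, partition, rotations, n_groups) {
  gamma <- beta
  for (g in seq_len(n_groups)) {
    idx <- partition$groups[[g]]
    if (is.null(rotations[[g]])) next
    k <- partition$kappa[idx]
    z <- partition$zeta[idx]
    gamma[idx] <- k * as.numeric(rotations[[g]] %*% (z * beta[idx]))
  }
  gamma
}

#' Rotate eigengroups of a basis
#'
#' Applies an independent random rotation to each rotatable eigengroup in
#' its degeneracy-normalized (spherical) representation:
#' `Psi_L' = (Psi_L . diag(kappa_L)) R_L . diag(zeta_L)` with
#' `kappa = lambda^(-1/2)` and `zeta = lambda^(1/2)`. The constant group
#' is returned unrotated. Rotations are drawn from the current RNG
#' stream unless an explicit list is supplied.
#'
#' @param basis an `eigen_basis`.
#' @param partition the [partition_eigengroups()] of that basis.
#' @param rotations optional list of orthogonal matrices, one per group
#'   (`NULL` entries for non-rotatable groups); defaults to fresh Haar
#'   draws.
#' @return list with `modes` (the rotated mode matrix over the partition's
#'   used modes) and `rotations`.
#' @export
rotate_groups <- function(basis, partition, rotations = NULL) {
  if (partition$n_used > ncol(basis$modes)) {
    stop_es("partition does not belong to this basis", class = "validation_error")
  }
  if (any(!is.finite(partition$kappa[unlist(partition$groups[partition$rotatable])]))) {
    stop_es("zero eigenvalue inside a rotatable group: kappa undefined",
            class = "validation_error")
  }
  ng <- length(partition$groups)
  rotations <- rotations %||% draw_group_rotations(partition, ng)
  out <- basis$modes[, seq_len(partition$n_used), drop = FALSE]
  for (g in seq_len(ng)) {
    if (is.null(rotations[[g]])) next
    idx <- partition$groups[[g]]
    k <- partition$kappa[idx]
    z <- partition$zeta[idx]
    out[, idx] <- (out[, idx, drop = FALSE] %*%
                     (rotations[[g]] * k)) * rep(z, each = nrow(out))
  }
  list(modes = out, rotations = rotations)
}

#' Surrogate generation options
#'
#' @param n_modes integer mode count (rounded down to whole eigengroups)
#'   or `"auto"` for the FWHM heuristic of [choose_n_modes()].
#' @param amplitude_adjust rank-remap surrogate values onto the original
#'   value distribution (on by default; recovers the empirical amplitude
#'   distribution that the rotated modal sum Gaussianizes).
#' @param residual_policy `"permute"` (uniform random permutation of the
#'   decomposition residual over valid vertices, fresh per surrogate) or
#'   `"zero"`.
#' @param n_surrogates ensemble size S.
#' @param seed integer root seed; each surrogate's rotations and residual
#'   permutation are a pure function of `(seed, surrogate index)`.
#' @return a `surrogate_options` list.
#' @export
surrogate_options <- function(n_modes = "auto", amplitude_adjust = TRUE,
                              residual_policy = c("permute", "zero"),
                              n_surrogates = 1L, seed = 1L) {
  residual_policy <- match.arg(residual_policy)
  stopifnot(n_surrogates >= 1L)
  structure(list(n_modes = n_modes, amplitude_adjust = amplitude_adjust,
                 residual_policy = residual_policy,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "surrogate_options")
}

#' Generate an ensemble of eigenstrapped surrogate maps
#'
#' The core resampling step: the map is decomposed onto whole eigengroups,
#' each rotatable group's coefficients are transported through an
#' independent Haar-random rotation of the degeneracy-normalized group,
#' and a surrogate is recomposed as the rotated modal sum plus a
#' residual term (permuted over valid vertices, or zero). The constant
#' mode's contribution (the map mean) is carried over unrotated. Optional
#' amplitude adjustment rank-remaps each surrogate onto the original
#' value multiset. Masked vertices stay masked in every surrogate.
#'
#' @param map a [surface_map()] or numeric vector.
#' @param basis an `eigen_basis` for the map's mesh.
#' @param options a [surrogate_options()] list.
#' @param distances a `pair_distances` object, required when
#'   `options$n_modes == "auto"` (the FWHM heuristic needs distances).
#' @param partition optionally precomputed [partition_eigengroups()].
#' @return an object of class `surrogate_ensemble`: `maps` (N x S matrix,
#'   NA at masked vertices), `mask`, `provenance` (options echo, root
#'   seed, per-surrogate seeds, basis hash, n_modes used), plus the
#'   `decomposition`.
#' @export
generate_surrogates <- function(map, basis, options = surrogate_options(),
                                distances = NULL, partition = NULL) {
  map <- as_surface_map(map)
  if (length(map$values) != nrow(basis$modes)) {
    stop_es("map length ", length(map$values), " does not match basis mesh (",
            nrow(basis$modes), ")", class = "dimension_error")
  }
  partition <- partition %||% partition_eigengroups(basis)
  if (identical(options$n_modes, "auto")) {
    if (is.null(distances)) {
      stop_es("auto mode count needs a pair_distances object",
              class = "validation_error")
    }
    n_modes <- choose_n_modes(map, basis, partition, distances)
  } else {
    n_modes <- min(as.integer(options$n_modes), partition$n_used)
  }
  dec <- decompose_map(map, basis, n_modes)
  n_groups <- dec$n_groups
  valid <- map$mask
  nv <- sum(valid)
  S <- options$n_surrogates
  sub_seeds <- derive_seeds(options$seed, S, stream = "surrogates")
  Psi <- basis$modes[, seq_len(n_modes), drop = FALSE]
  Gamma <- matrix(0, n_modes, S)
  Eps <- matrix(0, nv, S)
  resid_valid <- dec$residuals[valid]
  ## Rotating a group's coefficients by a Haar-random orthogonal matrix is
  ## equivalent in distribution to drawing a uniform random direction with
  ## the same norm (the orbit of a fixed vector under Haar measure is the
  ## uniform sphere), so each surrogate draws the rotated coefficients
  ## directly: gamma_L = kappa . u * |zeta . beta_L| with u uniform on the
  ## unit sphere of the group's dimension.
  beta <- dec$coefficients
  for (s in seq_len(S)) {
    withr::with_seed(sub_seeds[s], {
      gamma <- beta
      for (g in seq_len(n_groups)) {
        if (!partition$rotatable[g]) next
        idx <- partition$groups[[g]]
        v <- partition$zeta[idx] * beta[idx]
        u <- rnorm(length(idx))
        gamma[idx] <- partition$kappa[idx] * u * (sqrt(sum(v^2)) / sqrt(sum(u^2)))
      }
      Gamma[, s] <- gamma
      if (options$residual_policy == "permute") {
        Eps[, s] <- resid_valid[sample.int(nv)]
      }
    })
  }
  Y <- Psi[valid, , drop = FALSE] %*% Gamma + Eps
  if (options$amplitude_adjust) {
    orig_sorted <- sort(map$values[valid])
    for (s in seq_len(S)) {
      Y[order(Y[, s], method = "radix"), s] <- orig_sorted
    }
  }
  maps <- matrix(NA_real_, length(map$values), S)
  maps[valid, ] <- as.matrix(Y)
  structure(list(maps = maps, mask = valid,
                 decomposition = dec,
                 provenance = list(options = unclass(options),
                                   seed = options$seed,
                                   surrogate_seeds = sub_seeds,
                                   basis_hash = content_hash(
                                     list(basis$eigenvalues, dim(basis$modes))),
                                   n_modes = n_modes)),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("surrogate_ensemble: %d surrogates on %d vertices (%d modes, seed %d)\n",
              ncol(x$maps), nrow(x$maps), x$provenance$n_modes, x$provenance$seed))
  invisible(x)
}

#' Rank-order amplitude adjustment
#'
#' Replaces the k-th smallest surrogate value with the k-th smallest
#' original value over the valid vertices, so the output's value multiset
#' equals the original's exactly while the surrogate's spatial rank
#' pattern is retained (a monotone remap; Spearman correlation with the
#' input surrogate is 1). Ties are broken by stable vertex order, and the
#' operation is idempotent.
#'
#' @param surrogate numeric vector of surrogate values.
#' @param original numeric vector of original values.
#' @param mask optional logical mask; adjustment acts on valid vertices.
#' @return adjusted numeric vector (NA outside the mask).
#' @export
amplitude_adjust <- function(surrogate, original, mask = NULL) {
  mask <- mask %||% (is.finite(surrogate) & is.finite(original))
  if (sum(is.finite(surrogate[mask])) != sum(is.finite(original[mask]))) {
    stop_es("surrogate and original must have equal valid-vertex counts",
            class = "validation_error")
  }
  out <- rep(NA_real_, length(surrogate))
  sv <- surrogate[mask]
  out[mask] <- sv
  out[mask][order(sv, method = "radix")] <- sort(original[mask])
  out
}

#' FWHM-based automatic mode count
#'
#' Chooses the truncation depth for a map: every whole eigengroup whose
#' characteristic FWHM is at least the map's estimated FWHM is retained.
#' A group of mean eigenvalue `lambda` has nominal wavelength
#' `2*pi/sqrt(lambda)`; its characteristic FWHM is taken as half that
#' wavelength (one lobe of the mode). Rougher maps therefore keep more
#' (finer) groups. At least one rotatable group is always included. A map
#' whose spatial correlation never decays below one half across the mesh
#' is treated as coarser than every group, yielding the minimal count.
#'
#' @param map a [surface_map()].
#' @param basis an `eigen_basis`.
#' @param partition the basis's [partition_eigengroups()].
#' @param distances a `pair_distances` object on the same mesh.
#' @return integer mode count spanning whole groups.
#' @export
choose_n_modes <- function(map, basis, partition, distances) {
  fwhm_to_n_modes(map_fwhm_for_heuristic(map, distances), partition)
}

map_fwhm_for_heuristic <- function(map, distances) {
  map <- as_surface_map(map)
  tryCatch(
    estimate_fwhm(map, distances, max_lag = max(distances$d)),
    eigenstrapr_no_crossing = function(e) Inf)
}

fwhm_to_n_modes <- function(fwhm_map, partition) {
  if (is.nan(fwhm_map)) {
    stop_es("map FWHM not estimable", class = "validation_error")
  }
  xi <- partition$xi
  fwhm_group <- ifelse(xi > 0, pi / sqrt(xi), Inf)
  keep <- fwhm_group >= fwhm_map
  last <- if (any(keep)) max(which(keep)) else 1L
  last <- max(last, 2L)                       # constant group + one rotatable
  as.integer(last^2)
}
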