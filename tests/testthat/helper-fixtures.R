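## shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ico <- function(s, r = 1) {
  cached(sprintf("ico_%d_%g", s, r), make_icosphere(s, r))
}

ico_basis <- function(s, r = 1, k, solver = "auto") {
  cached(sprintf("basis_%d_%g_%d_%s", s, r, k, solver),
         compute_eigenbasis(ico(s, r), k, solver = solver))
}

ico_partition <- function(s, r = 1, k) {
  cached(sprintf("part_%d_%g_%d", s, r, k),
         suppressWarnings(partition_eigengroups(ico_basis(s, r, k))))
}

ico_distances <- function(s, r = 1, subsample = NULL) {
  cached(sprintf("dist_%d_%g_%s", s, r, subsample %||% "all"),
         pairwise_distances(ico(s, r), subsample = subsample, seed = 11L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small sphere with a polar cap removed (open mesh, Neumann boundary)
cut_cap_sphere <- function(s = 2, r = 1, z_cut = 0.8) {
  cached(sprintf("cap_%d_%g_%g", s, r, z_cut), {
    m <- make_icosphere(s, r)
    extract_submesh(m, m$vertices[, 3] < z_cut * r)
  })
}
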