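# eigenstrapr

Surrogate maps with preserved spatial autocorrelation, for valid
inference on brain-map associations — an R implementation of
**eigenstrapping**.

## The problem

Maps on cortical surfaces and subcortical volumes (fMRI contrasts,
receptor densities, gene-expression gradients, cortical thickness, ...)
are spatially smooth. When two maps are correlated across `N` vertices,
that smoothness (spatial autocorrelation, SA) shrinks the effective
sample size far below `N`: under the null the correlation of two
white-noise maps has variance `1/N`, but for smooth maps the null widens
dramatically, and naive permutation tests reject wildly too often.
Honest inference needs a null distribution built from surrogates that
keep each map's SA but break any alignment between maps.

## The method

Eigenstrapping constructs such surrogates from the geometry itself:

1. Solve the Laplace–Beltrami eigenproblem on the mesh with linear
   finite elements, `A psi = lambda B psi` (cotangent stiffness,
   consistent mass), under natural (Neumann) boundary conditions so cut
   surfaces — a hemisphere without its medial wall — work unchanged.
2. Decompose the map on the modes, `y = Psi beta + eps` (mass inner
   products; least squares on the valid vertices when the map is
   masked).
3. Partition modes into eigengroups of sizes 1, 3, 5, ... — the
   spherical-harmonic multiplicities `2L + 1`. Normalize each group by
   `lambda^(-1/2)`, rotate it with an independent Haar-random orthogonal
   matrix, scale back by `lambda^(1/2)`.
4. Recompose: rotated modal sum, plus a random permutation of the
   residual (or zero), plus an optional rank remap onto the original
   value distribution (amplitude adjustment).

Each surrogate keeps the map's spatial power spectrum — hence its
variogram and Moran's I — while randomizing phase across scales. The
two-tailed surrogate p-value for maps `y`, `z` is
`p = (1 + #{|r_null| >= |r_obs|}) / (1 + S)`; max-statistic
family-wise-error correction is available for families of targets.

## Worked example

Two *independent* smooth random fields (spectral slope `alpha = 3`)
sampled on a sphere happen to correlate — does the association survive a
null that respects their smoothness?

```r
library(eigenstrapr)

mesh  <- make_icosphere(3, radius = 28)         # 642-vertex sphere
basis <- compute_eigenbasis(mesh, n_modes = 625)
dist  <- pairwise_distances(mesh, subsample = 50000, seed = 7)

pair <- simulate_grf_pair(alpha = 3, mesh, seed = 11)  # independent maps
ens  <- generate_surrogates(pair$y, basis,
          surrogate_options(n_modes = "auto", n_surrogates = 999, seed = 7),
          distances = dist)
compare_maps(pair$y, pair$z, ens)
#> null_test: r_obs = -0.1260, p = 0.222 (S = 999 surrogates)
```

The chance correlation is r = −0.126 — far outside what white noise
produces on 642 vertices. The eigenstrapped null is honestly wide
(null sd 0.099 versus the white-noise 1/sqrt(642) = 0.039), so the test
correctly retains the null (p = 0.222). An SA-naive vertex permutation
of the same data yields p = 0.003: a false positive.

A shell entry point wraps the same pipeline
(`inst/exec/eigenstrap`): `eigenmodes`, `surrogate`, `compare`,
`variogram`, `moran`, `simulate-grf`, `benchmark-fpr`, `benchmark-tpr`,
with YAML/JSON configs and JSON provenance sidecars next to every
output.

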