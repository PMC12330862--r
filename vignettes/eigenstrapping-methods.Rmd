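---
title: "Spatial-autocorrelation-preserving surrogate maps by eigenmode rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-autocorrelation-preserving surrogate maps by eigenmode rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenstrapr)
```

## The inference problem

Scalar maps measured on a cortical surface or a subcortical volume — fMRI
contrasts, receptor densities, gene-expression components, morphometry —
are spatially smooth: nearby vertices carry similar values. When two such
maps are correlated across vertices, this spatial autocorrelation (SA)
reduces the effective number of independent observations far below the
vertex count, so the usual sampling theory for a correlation coefficient
is badly miscalibrated. For two white-noise maps on `N` vertices the null
variance of the sample correlation is `1/N`; for smooth maps it can be an
order of magnitude larger, and chance correlations of 0.3–0.5 become
commonplace. Valid inference therefore needs a null distribution built
from *surrogate maps* that preserve each map's SA while destroying any
specific alignment between the two maps.

`eigenstrapr` builds such surrogates by **eigenstrapping**: decomposing a
map onto the geometric eigenmodes of its surface and randomly rotating
the modes within quasi-degenerate eigengroups. The surrogate shares the
map's spatial power spectrum — and hence its two-point correlation
structure — but has a randomized spatial phase and randomized
higher-order structure.

## Geometric eigenmodes

The eigenmodes are solutions of the Helmholtz equation of the
Laplace–Beltrami operator (LBO) on the mesh,
`Delta psi_eta = -lambda_eta psi_eta`, discretized with linear (P1)
finite elements: the cotangent-weighted stiffness matrix `A` and the
consistent mass matrix `B` give the generalized eigenproblem
`A psi = lambda B psi`. Modes are `B`-orthonormal and ordered by
eigenvalue (units mm^-2); the first mode is the constant with
`lambda = 0`. On a mesh with a boundary — a hemisphere with the medial
wall removed — the weak form imposes the natural (Neumann) boundary
condition automatically: no constraint rows are added and the constant
mode survives. Dirichlet conditions are deliberately not offered; fixing
values at the boundary would imprint a hard edge on every surrogate.

Numerically, small problems (and requests for a large fraction of the
spectrum) go through a dense Cholesky-reduced symmetric eigensolve, and
larger ones through an ARPACK shift–invert iteration around `sigma`
slightly below zero, with the mass matrix factored so the operator stays
symmetric. Both paths return the same basis to 1e-8 (tested). A
deterministic sign convention (largest-magnitude entry positive) removes
the per-mode sign ambiguity. Within a numerically degenerate cluster the
orthonormal frame is arbitrary; every downstream quantity the package
relies on is invariant to that freedom, and requests that would split a
cluster (relative gap below 1e-8) are extended to the cluster's end.

On a sphere the eigenmodes are spherical harmonics: degree `L`
contributes a group of `2L + 1` modes with identical eigenvalue
`L(L+1)/r^2`. Folded geometry perturbs the eigenvalues but approximately
preserves the group structure, so the package assigns groups by index
position (sizes 1, 3, 5, ...) after ascending sort. This is deterministic
and matches the eigenvalue clusters exactly on spheres (tested against
gap-based cluster detection); trailing modes that do not complete a group
are dropped.

## The surrogate construction

A map `y` is decomposed as `y = sum_L sum_mu beta_Lmu psi_Lmu + eps`
with coefficients `beta = Psi' B y` (mass inner product) on fully valid
maps, or by ordinary least squares on the valid vertices when a mask
(medial wall) is present. Then, per rotatable group `L`:

1. **Normalize**: scale each mode by `kappa = lambda^(-1/2)`, mapping
   the group onto a sphere where all effective eigenvalues are equal.
2. **Rotate**: multiply by a Haar-distributed random orthogonal matrix
   (QR of a standard-normal matrix with the sign-of-diagonal correction;
   reflections included, since mode sign is arbitrary). Each group gets
   an independent rotation, which destroys phase alignment across scales.
3. **Denormalize**: scale back by `zeta = lambda^(1/2)` in the group's
   original index order.

The surrogate is the rotated modal sum plus a residual term, either a
uniform random permutation of `eps` over the valid vertices (the
default) or zero. The constant mode (`lambda = 0`, `kappa` undefined) is
never rotated; the map mean is carried over verbatim. Because the
surrogate is a sum of many independently randomized components, its
amplitude distribution Gaussianizes regardless of the input's; the
optional (default-on) **amplitude adjustment** undoes this by rank-order
remapping the surrogate onto the original value multiset, which restores
the histogram exactly while preserving the surrogate's spatial ranks.

Inside the ensemble generator the rotation is applied in coefficient
space: the only quantity a surrogate needs is `R %*% v` for the fixed
group vector `v = zeta * beta_L`, and under Haar measure that product is
exactly a uniformly random direction of norm `|v|`, which is drawn
directly. This is a distributional identity, not an approximation, and
makes ensemble generation linear in mesh size. The explicit
matrix-valued path (`random_rotation()`, `rotate_groups()`) remains
available and is what the invariance tests exercise.

Two conservation laws pin the construction down (both tested):

* In exactly degenerate groups (`kappa * zeta = 1` with a common
  eigenvalue) the recomputed coefficients of a surrogate are an
  orthogonal transform of the originals, so per-group spectral power is
  conserved to 1e-8. On numerically split groups (FEM discretization
  lifts the degeneracy; folded meshes more so) conservation degrades in
  proportion to the within-group eigenvalue spread.
* With identity rotations, the identity residual permutation and no
  amplitude adjustment, the surrogate equals the input exactly.

## How many modes: the FWHM heuristic

Truncation depth is the method's one free parameter. The automatic rule
estimates the map's characteristic FWHM from its variogram — the
autocorrelation proxy `rho(h) = 1 - gamma(h)/sill` with the sill set to
the map variance, crossed at 0.5 by linear interpolation and doubled —
and keeps every whole eigengroup whose characteristic FWHM (half the
nominal wavelength `2*pi/sqrt(mean lambda)`, one lobe of the mode) is at
least the map's. Rough maps keep the whole basis; very smooth maps keep
a handful of coarse groups; at least one rotatable group is always kept.
A map whose spatial correlation never decays below one half across the
mesh is treated as coarser than every group. In the benchmark harnesses
the depth for a pair is set from the average of the two maps' FWHM
estimates, which halves the estimator noise relative to a single-map
estimate.

The half-wavelength constant is a modeling choice: it equates one FWHM
with one lobe of a mode, and in the false-positive benchmarks it is
near the optimum — forcing substantially deeper decompositions at high
smoothness made the test conservative (measured FPR fell to ~3% at
fixed depths of 400–625 modes), while shallower ones inflate it.

## Inference

The test statistic is the Pearson correlation over the joint valid mask.
An ensemble of `S` surrogates of one map, each correlated with the other
map, yields the two-tailed p-value `p = (1 + #{|r_null| >= |r_obs|}) /
(1 + S)`; the add-one convention keeps `p` in `(0, 1]` and exact. For a
family of target maps tested against one shared ensemble, family-wise
error is controlled by the single-step max-statistic rule: target `t`'s
adjusted p-value counts surrogates whose maximum absolute null
correlation across the family reaches `|r_obs(t)|`.

## The synthetic benchmark

Because empirical maps have no ground truth, the package ships a
Gaussian random field engine: white noise on a 3-D grid is Fourier
filtered to a power spectral density `P(k) ~ |k|^(-alpha)`
(amplitude scaling `|k|^(-alpha/2)`, zero-frequency term removed),
standardized, and sampled onto a mesh by trilinear interpolation.
`alpha = 0` is white noise; `alpha = 3` is very smooth. Correlated pairs
mix at the volume stage (`z = rho*y + sqrt(1-rho^2)*w`) so both maps are
exchangeable fields of the same slope; heterogeneous-SA composites
splice the front half (first coordinate above the median) of a smooth
field onto the rear half of a rough one.

The study conditions are fixed once: icosphere meshes of radius 28 mm
centered in a 64-cubed grid of 1 mm voxels (the largest radius honoring
a 2-voxel interpolation margin; the construction is scale invariant, so
only the ratio of mesh to grid matters), 200 pairs and 199 surrogates
per experiment at test level 0.05, and a benchmark basis of 625 modes
(25 whole groups — about a quarter of the subdivision-4 mode set, and
effectively the complete spectrum of the subdivision-3 mesh). False
positive rates are reported with exact Clopper–Pearson 95% intervals.
The alpha = 0 experiment runs on the subdivision-3 mesh (642 vertices):
white-noise maps carry correlated structure down to the interpolation
scale, so their rotated basis must reach it, and a near-complete basis
at subdivision 4 would require a far larger eigendecomposition and
proportionally longer ensemble generation than the benchmark budget
warrants.

What the generator emulates: tunable, isotropic, stationary SA under a
single spectral-slope parameter, including the scale-free long-range
correlations characteristic of brain maps. What it does
not emulate: anisotropy, cortical folding (eigengroup degeneracy is
exact on our spheres, only approximately so on real cortex),
non-Gaussian amplitude distributions (exercised separately in the
tests), boundary effects of a cut medial wall (exercised by the masked
tests), and map-specific measurement noise. Passing benchmarks here
demonstrates calibration of the machinery under controlled SA, not
performance on any particular empirical modality.

## Numerical choices and degenerate inputs

* Eigensolver: dense path for meshes up to ~1,500 vertices or when more
  than a third of the spectrum is requested; ARPACK shift–invert with
  tolerance 1e-10 otherwise. Residual and `B`-orthonormality checks run
  on every solve.
* Geodesic distances use the heat method (diffusion time = mean squared
  edge length) with results floored at the Euclidean chord, the analytic
  lower bound for a surface path; antipodal sphere distances are
  recovered to ~2% at subdivision 3.
* Variogram: Matheron estimator, 25 equal-width bins to a quarter of the
  maximum pairwise distance by default; empty bins are `NA`, never zero.
  Distance sets above 5,000 vertices are subsampled (seeded, uniform
  over pairs).
* Moran's I defaults to inverse-distance weights over the available pair
  set. On a near-uniform sphere this kernel approximately commutes with
  rotations, which is what makes Moran's I nearly invariant under
  eigenstrapping; a subsampled pair set breaks that isotropy and adds
  per-surrogate noise, so preservation experiments use the full pair
  set below 5,000 vertices.
* Ties in amplitude adjustment are broken by stable vertex order, making
  the remap idempotent.
* Degenerate inputs fail loudly: meshes with inverted or zero-measure
  elements, maps of zero variance, masked decompositions with fewer
  valid vertices than modes, and rotation requests on a zero-eigenvalue
  group all raise classed errors.
* All randomness flows from one root seed through named sub-streams
  (`derive_seeds()`), so any ensemble, experiment or CLI run regenerates
  bit-identically from its recorded provenance.

## Known limitations

* Desk-scale smooth fields differ from full-resolution cortical ones in
  one important way. A power-law field at `alpha = 3` carries equal
  variance per octave, so on a 64-cubed grid roughly a third of the
  sampled map's variance lies at scales finer than the heuristic's cut.
  The permuted residual whitens that genuinely correlated remainder,
  which biases Moran's I of the surrogates by a few parts in a thousand
  and leaves the smooth-end false positive rate slightly above nominal
  (~6% measured across seeds). In full-scale cortical analyses — coarse
  acquisition voxels smoothed onto a large surface — the residual beyond
  the retained modes is negligible and both effects vanish. The
  Moran-preservation test block asserts the tight preservation bound
  that holds in that regime, and is expected to fail on this benchmark
  geometry for the reason above; the assertion is kept strict rather
  than widened to the desk-scale behavior.
* Volume-sampled benchmark maps share a second, anisotropic correlation
  component: both maps of a pair are interpolated from the same voxel
  grid, and when vertex spacing falls below about two voxels this
  grid-aligned structure correlates the pair beyond what any isotropic
  SA summary captures. Surrogates reproduce the isotropic spectrum, so
  the rough-field null is measurably narrower than the true pair null
  (sd 0.040 vs 0.045 on the 642-vertex benchmark), worth one to two
  points of false positive rate. This is a property of the shared
  sampling grid, not of the surrogate construction.
* Eigengroup structure is exact only on spheres. On strongly folded
  geometry the index grouping is a modeling assumption; per-group power
  conservation then holds only to the within-group eigenvalue spread.
* The least-squares masked decomposition is unweighted by default;
  mass-weighted fitting is available but changes coefficients only on
  strongly non-uniform meshes.
* No anisotropic operators, no spatiotemporal (4-D) surrogates, no
  partial/incremental rotations.
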