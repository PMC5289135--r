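---
title: "Mapping, clustering and screening conformer databases with conformap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping, clustering and screening conformer databases with conformap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformap)
```

## The problem

Structure-search campaigns for flexible molecules produce databases of
thousands of locally-minimized conformers.  Navigating such a database —
which structural motifs exist, how they relate, which structures represent
them, and whether any entries are erroneous — requires three ingredients:
a metric between whole molecular configurations, low-dimensional maps and
hierarchical classifications built on that metric, and automated
diagnostics that cross the metric against a scalar property such as the
conformational energy.  `conformap` implements this toolbox end to end and
ships a synthetic conformer generator so every stage can be exercised and
tested without any external data.

All atom indices in the API are 1-based, following R convention.

## The metric: SOAP environments and the REMatch kernel

Each atom is described by its local neighbor density: a sum of Gaussians
of width `atom_sigma` (default 0.3 Å) placed at every atom within the
cutoff `r_c` (default 4 Å), partitioned by chemical species, taken
smoothly to zero at the cutoff by a cosine switching function, with the
central atom included so isolated atoms remain well-defined.  The density
is expanded in `n_max` radial basis functions times real spherical
harmonics up to `l_max` (defaults 8 and 6), and the rotation-invariant
power spectrum over species pairs is flattened in a fixed documented
order and normalized to unit length.  Concretely the radial basis is the
shifted-Legendre system, orthonormal under unit weight on `[0, r_c]`,
and the projection integrals (which carry the `r²` Jacobian and a
modified-spherical-Bessel angular factor) are evaluated by Gauss–Legendre
quadrature with exponentially-scaled Bessel functions, so no intermediate
overflow can occur.  Any rotation-invariant completion with these
invariance properties yields the same downstream method; the tests assert
the invariances (rotation, translation, permutation, smoothness at the
cutoff, masking consistency), not one particular basis.

The similarity of two environments is the descriptor dot product, clamped
to `[0, 1]`, raised to the power ζ (default 2).  Two structures A and B
are then compared through their environment-pair similarity matrix
`C_ij = k(X^A_i, X^B_j)` and the regularized-entropy-match kernel

$$\hat K^\gamma(A,B) = \mathrm{Tr}\, \mathbf P^\gamma \mathbf C(A,B),$$

where the coupling P minimizes `Σ_ij P_ij (1 − C_ij + γ ln P_ij)` over
matrices with row sums `1/N_A` and column sums `1/N_B`.  That marginal
convention keeps the kernel a weighted mean of `C` in `[0, 1]` and extends
naturally to molecules of different sizes.  γ interpolates between two
limits: γ → ∞ gives the average kernel `mean(C)`, γ → 0 the best-match
(optimal-assignment) kernel.  The default γ = 0.1 sits between the two.
The coupling is computed by Sinkhorn scaling of `exp(C/γ)`, in the log
domain whenever the exponent range could overflow, to a marginal
tolerance of 1e-6 with a generous sweep cap (5×10⁵): sweeps on
molecule-sized matrices cost microseconds, and the small-γ regime
genuinely needs ~10⁵ sweeps, so a small cap would be a false economy.
One numerical caveat worth knowing: at finite γ the kernel value
undershoots the exact assignment value by an entropic gap of order γ when
the assignment problem has near-ties; agreement with the brute-force
best match to three decimals is reached by γ ≈ 0.002, not at γ = 0.01.

Distances come from the kernel metric
`D(A,B) = sqrt(K(A,A) + K(B,B) − 2 K(A,B))` after cosine normalization of
the kernel (the default), so D measures shape rather than size.  The
REMatch kernel is not guaranteed positive semidefinite; rare negative
radicands are clamped to zero and counted in a warning — raise γ if they
become frequent.  When all structures have the same environment count the
kernel matrix is computed by a batched Sinkhorn that runs every pair in
lockstep (one descriptor Gram, array-vectorized scaling), which makes the
200-structure study below take about a minute on one core.

## Sketch-map embedding

The 2-D map minimizes the stress
`S² = Σ_{i<j} w_ij [F(D_ij) − f(d_ij)]²` where F and f are the sigmoid
transforms `F(r) = 1 − (1 + (2^{a/b} − 1)(r/σ)^a)^{−b/a}` of the input
and map distances.  The exponents default to A = a = 1 and B = b = 4 —
short-range distances are represented near-faithfully, long-range ones
saturate — which suits databases of energy minima with no thermal noise
to filter out.  The switching distance σ is the sensitive parameter; the
automatic choice histograms the off-diagonal distances into 100
equal-width bins (fixed for reproducibility, configurable) and returns
0.8 times the center of the most populated bin (leftmost on ties).

Minimization is deterministic: classical metric scaling of D seeds a
quasi-Newton (L-BFGS) descent with an analytic gradient, plus seeded
randomly-perturbed restarts (default 5); the best restart is returned
and the recorded `final_stress` is the true objective at the solution.
Large sets are handled by landmarking: `min(N, 500)` landmarks chosen by
farthest point sampling (greedy max-min, lowest-index tie-break), the map
fitted on the landmarks, and the remaining structures placed by
out-of-sample projection — a 64×64 grid search over the landmark bounding
box padded by 25 % per side, refined by gradient descent from the best
cell.  The same projection places *new* structures (e.g. a perturbed
variant of the database) on a reference map; a species mask in the SOAP
parameters lets the metric ignore the perturbing species, so the
projection isolates the perturbation's structural effect.  Because a
distance-matrix-derived model cannot contain the landmark geometries,
the projection command takes the reference structure file alongside the
model file.

## Clustering, representatives, spreads

Agglomerative clustering uses the root-mean-square linkage
`Δ(X,Y) = sqrt(mean over cross pairs of D²)`, implemented through the
exact update
`Δ²(X∪Y, Z) = (N_X Δ²(X,Z) + N_Y Δ²(Y,Z)) / (N_X + N_Y)` — the update is
an identity, not an approximation, and a brute-force re-evaluation test
checks the whole merge sequence to 1e-10.  Equal linkages are broken by
the smallest (left node, right node) creation-index pair so the tree is
identical across platforms.  RMS linkage is not guaranteed monotone;
inversions are counted and reported rather than hidden, and the cut
criterion is defined subtree-wise (a cluster is a maximal subtree whose
internal merges all sit at or below the threshold), which stays
well-defined under inversions.  Each cluster is summarized by its
*representative* — the member with minimum mean squared distance to all
members — and its *spread* σ_D, the RMS distance of members to the
representative (zero for singletons, `d/√2` for a pair at distance d).
`suggest_cut()` offers an automatic threshold (midpoint of the largest
gap between sorted merge heights) when no domain-motivated value such as
the conventional 0.1 for normalized kernel distances is preferred.

## Diagnostics: outliers and structure/property consistency

Outlier branches are found by scanning from the root for maximal branches
of at most `max_size` leaves that attach to the rest of the tree at a
linkage height of at least `min_height` — small groups that only join
everything else near the top of the dendrogram.

The consistency screen cuts the tree, and for every cluster with at least
two members compares the structural spread σ_D with the property spread
σ_E, the population standard deviation of the property over the cluster
(an RMS-about-the-representative variant is available; the SD keeps σ_E
in the property's units).  Clusters that are structurally tight but
property-wild — σ_D below one threshold, σ_E above another — are flagged
`inconsistent`: the metric cannot see whatever drives the property, the
signature of mixed-provenance or corrupted entries.  No universal
thresholds exist; the screen exposes both and returns the full
(σ_D, σ_E) table so they can be chosen from the scatter
(`plot_consistency()`).

## The synthetic study conditions

The generator builds a small chain molecule (C–C–N–C–C–O backbone plus
two hydrogens, 8 atoms) by internal-coordinate placement, with two
rotatable backbone torsions drawn from basin centers plus Gaussian noise.
The defaults define the study conditions used throughout the tests and
the acceptance script: 200 structures, two basins at (180°, 180°) and
(0°, 180°) — a trans/trans versus cis/trans pair, the smallest landscape
with the bimodal torsional structure that dominates peptide conformer
sets — 5° torsional noise, energies
`E = basin_offset + Σ_t k (1 − cos(θ_t − θ_t⁰)) + N(0, 0.02 eV)` with
k = 0.3 eV and offsets (0, 0.1) eV, giving a smooth structure–energy
relation.  A 1 % outlier fraction plants conformers with torsions far
from every center; an optional inconsistent fraction receives a constant
+1 eV offset, mimicking entries computed at a different level of theory.
Geometries with interatomic clashes below 0.5 Å are resampled.  The
"generator-matched" screen thresholds used in the checks are derived by
formula from the generator, not fitted: σ_E threshold = offset/4, σ_D
threshold = 1.5× the largest within-basin spread.

What the generator does *not* emulate: real conformer sets have many
coupled degrees of freedom, anharmonic basins, continuous pathways
between motifs and property noise that correlates with structure.
Passing the recovery tests therefore shows the pipeline's machinery is
correct on well-separated torsional basins; it does not certify
performance on landscapes where basins overlap in descriptor space.

## Numerical choices and degenerate inputs

* Sinkhorn: marginal tolerance 1e-6, automatic log-domain switch,
  non-convergence is an error carrying the residual, never a silent
  truncation.
* Sigmoids: `F(0) = 0` and `F(σ) = 0.5` hold to machine precision by
  construction; negative distances are rejected.
* `auto_sigma`: an all-equal distance matrix is the single-occupied-bin
  case (σ = 0.8 d); an all-zero one is an error.
* Optimizer: divergent restarts are discarded; if every restart fails the
  fit errors out.  Stress is invariant under rigid motions of the map, so
  two fits agree only up to rotation/reflection — comparisons in the
  tests are Procrustes-aligned.
* Distance matrices are validated (symmetry, finiteness, non-negativity)
  at every entry point; degenerate duplicate structures are legal and
  produce zero distances.
* Worked sizes: the default test and acceptance runs use 200-structure
  kernels, 50-point sketch-map recoveries and 30–60-structure command
  workflows, sized so the whole suite completes in a few minutes on one
  core while still exercising the batched code paths.

## Persistence and interfaces

Kernel and distance matrices, embeddings, linkage tables and screens are
written as TSV with structure ids; sketch-map models and descriptor sets
as JSON containers carrying their parameters (the model label uses the
conventional `σ-A_B-a_b` notation).  Plain-text containers keep every
artifact diff-able and dependency-free; an optional Newick export of the
cluster tree interoperates with phylogenetic tooling.  The `cmd_*`
functions (and the `inst/cli/conformap` script that dispatches to them)
wire the stages together, each writing its resolved configuration and a
run log beside its outputs so any result can be reproduced from the
output directory alone.
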