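---
title: "Methods: evolutionary modularity and planarity of skull linkage systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary modularity and planarity of skull linkage systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkmod)
```

## The scientific problem

Fish skulls contain three biomechanical 4-bar linkage systems — anterior
jaw, opercular, and hyoid — each a loop of four rigid links turning about
four joints. Because a linkage functions as a unit, its bones are expected
to coevolve; whether they do, whether the three linkages form one integrated
complex or three separate modules, and whether modular organisation comes
with faster shape evolution are comparative questions. `linkmod` implements
the full analysis chain for 3D landmark data on a time-calibrated phylogeny,
together with a synthetic-data generator so every estimator can be validated
against known truth.

The unit of data is a *configuration*: an ordered block of 3D points per
specimen, each point assigned to one of sixteen bone elements (premaxilla,
maxilla, dentary, angular, palatine, neurocranium, nasals, upper and lower
pharyngeal jaws, ceratohyal, hypohyal, urohyal, hyomandibula, opercular
series, suspensorium, pectoral girdle). The packaged default scheme has 200
points — 83 fixed landmarks and 117 semi-landmarks on sliding curves — but
only the counts, bone assignments, and curve topology are fixed by the
package; anatomical point definitions belong to the digitisation protocol of
a given study.

## Superimposition

`gpa()` removes translation, scale, and rotation: each configuration is
centered on its centroid, scaled to unit centroid size (root summed squared
distances to the centroid), and iteratively rotated to the evolving
consensus by the proper-rotation Procrustes solution (reflections are
excluded throughout, appropriate for bilateral anatomy digitised on one
side). Convergence is declared when the consensus sum of squares changes by
less than `tol` (default 1e-10, at most 100 iterations; non-convergence is a
flag, not an error).

Semi-landmarks slide along their curves to minimize the Procrustes chord
distance to the consensus. The tangent at a semi-landmark is the normalized
chord between its two curve neighbours; the point moves by the tangential
component of its offset from the reference, which never increases the chord
distance. Two numerical choices matter:

* *Two-phase iteration.* Positions along a curve are a nearly neutral
  direction — the whole curve can drift in its own parametrization with
  almost no change in fit — so interleaved sliding does not settle at
  1e-10. Sliding therefore runs first, until the consensus is stable at a
  coarser tolerance (1e-8, at most 20 passes), after which semi-landmarks
  freeze and plain alignment iterates to `tol`. A `slide_once` flag gives
  the single-pass variant.
* *Canonical orientation.* A GPA seeded by the first specimen is only
  defined up to a global rotation. The final solution is rotated to the
  consensus' principal axes, with axis signs fixed by functionals of the
  projected coordinates (not of the eigenvectors) and the third axis taken
  as the cross product of the first two. This makes the output exactly
  invariant to a common similarity transform of all inputs and
  deterministic given specimen order.

The reported consensus is the arithmetic mean of the aligned specimens.
Bending-energy sliding is deliberately not offered: tangent/chord-distance
sliding avoids the spatial autocorrelations that minimum-bending-energy
sliding can introduce.

## Phylogenetic machinery

Under Brownian motion the tip covariance is `C[i,j]` = shared root-to-MRCA
path length (`bm_covariance()`, via `ape`). `phylo_transform()` whitens tip
data: `U = C^{-1/2}(X - 1a')` with the GLS phylogenetic mean
`a = (1'C^-1 1)^-1 1'C^-1 X`. The inverse square root is the *symmetric*
(eigendecomposition) root rather than a Cholesky factor, so the transform
introduces no arbitrary rotation and is platform-stable; eigenvalues below
1e-12 of the maximum are an error rather than silently clipped. The
evolutionary covariance is `U'U/(N-1)` (denominator `N-1` by convention),
which equals the GLS form `(X-1a')'C^{-1}(X-1a')/(N-1)` — an identity the
test suite asserts as a cross-module check.

Ancestral states (`ancestral_states()`) are the maximum-likelihood BM
estimates, computed by solving the branch-length-weighted least-squares
system over internal nodes; the root estimate equals the GLS mean.
`phylomorphospace()` fits the PCA on tips only (covariance PCA of
mean-centered vectorized coordinates) and projects ancestors onto those axes
afterwards — ancestors inform the picture but not the axes. Squared-change
parsimony ancestors are not separately implemented: on a tree with branch
lengths the ML-BM solution is the weighted squared-change optimum, which is
the variant used here.

## Covariance-ratio modularity

For a partition of landmarks into modules, the covariance ratio on the
evolutionary covariance `S` is, per module pair,
`CR_ij = sqrt( tr(S_ij S_ji) / sqrt( tr(S*_ii S*_ii) tr(S*_jj S*_jj) ) )`,
where `S*` zeroes the diagonal of a within-module block; the overall
statistic for more than two modules is the arithmetic mean of the pairwise
values. CR is invariant to common rescaling of `S` and is small when
between-module covariation is weak relative to within-module covariation.

The null distribution permutes the landmark-to-module labels, always moving
a landmark's three coordinates as one unit (permuting single axes would
destroy within-point covariance and bias the null). The p-value is the
one-tailed `Pr(CR_perm <= CR_obs)` with the `(1+k)/(n_perm+1)` convention so
p is never zero, and the effect size is
`Z = (CR_obs - mean(CR_perm))/sd(CR_perm)` with the observed value excluded
from the null moments; strongly negative Z = strongly modular. Defaults:
999 permutations, seed mandatory, results bit-reproducible given the seed.

`compare_cr()` both ranks hypotheses by effect size (the best-fitting
hypothesis is the lowest Z) and reports pairwise two-sample z statistics.
Since each effect size is a permutation z-score whose null distribution has
unit standard deviation by construction, the difference of two is referred
to `sqrt(2)`; both the ranking and the test are returned because either
style of comparison may be wanted.

## Distance-matrix / graphical-model modularity

The second, conceptually different test asks which partitions are
*conditionally independent*. Nodes are the sixteen bone elements. For each
bone, a specimen-by-specimen distance matrix is computed in one of two
modes: `shape_only` (each bone's landmarks superimposed independently, so
only the bone's own shape counts — pairwise Procrustes distances) and
`position_and_shape` (bone blocks taken verbatim from the
whole-configuration alignment, so relative position and size count —
Euclidean distances). The two modes coincide when a block is already
independently aligned. Matrix correlations (Pearson, strictly lower
triangle) between bones give a 16 x 16 correlation matrix. With a tree
supplied, distances are computed between rows of the whitened block
coordinates (same `C^{-1/2}` for every block; per-block GPA first in
`shape_only` mode), removing shared-ancestry correlation before the
conditional-independence analysis.

Each hypothesis H1–H13 maps to a conditional-independence graph: edges
between bones that share a module, no edges across modules (H1, the
each-bone-separate control, is the empty graph). The Gaussian graphical
model is fitted by iterative proportional scaling on the concentration
matrix over the maximal cliques of the graph (via `igraph`); for the
union-of-disjoint-cliques graphs of the registry one sweep is exact, and
general user graphs iterate to a 1e-10 clique-marginal tolerance. Deviance
is `n (tr(RK) - log det(RK) - p)`; hypotheses are ranked by
`IC = deviance + 2k` with `k` = free parameters (edges + diagonal). The
ranking, not the absolute IC, is the contract: deviance-based criteria
differ in additive constants and sample-size corrections, so only order is
interpreted. A non-positive-definite correlation matrix is an error
(collect more specimens) rather than being shrunk — silent regularization
could change rankings.

## Evolutionary rates

`module_rates()` estimates, for module *i* with `p_i` landmarks,
`sigma^2_i = sum(U[, module coords]^2) / (N p_i)` — summed squared whitened
residuals normalized by specimens times *landmark* count. Normalizing by
landmarks (not by `3 p_i` coordinates) keeps rates comparable across modules
and matches the multivariate-rate convention, but scales every reported rate
by 3 relative to a per-coordinate definition; this is stated prominently
because absolute rates are convention-dependent while ratios are not. The
rate of a concatenation of modules is the landmark-count-weighted mean of
the module rates (asserted numerically in the tests).

`rate_ratio_test()` compares the highest to the lowest module rate and
calibrates the ratio by simulating multivariate BM on the same tree under
the pooled common rate with isotropic coordinate covariance — the null must
pick some trait covariance, and isotropy is the neutral choice;
`p = Pr(ratio_sim >= ratio_obs)`. `group_rates()` does the clade-wise
analogue from group-restricted residual sums, with an option
(`prune_per_group`) to whiten each group on its pruned subtree instead of
the full tree — both readings of "group-wise rates" are defensible, so both
are provided, with the full-tree version as default.

## Linkage planarity

For four joints J1–J4 of a 4-bar linkage, `align_to_plane()` applies the
rigid motion putting J1 at the origin, J2 on the +X axis, and J3 in the
Z = 0 plane with positive Y; J4 keeps its full 3D position. The 3D area is
the sum of the two triangles split along the J1–J3 diagonal (half
cross-product norms); J4 is then projected to Z = 0 and the area recomputed.
Planarity = projected/3D area, in (0, 1], equal to 1 exactly at coplanarity,
invariant to rigid motion and uniform scale, and monotonically decreasing in
the out-of-plane offset for the lifted-square family (at lift 1 on a unit
square the closed form is `2/(1+sqrt(3))`).

Two conventions are explicit parameters rather than buried defaults, because
they change the value: *which* mobile joint is J3 (the joint adjacent to the
fixed link, by default, configurable per system), and the triangulation
diagonal (fixed as J1–J3; the two diagonals agree only for planar convex
quadrilaterals). Joint-to-landmark maps are user configuration
(`extract_linkage_joints()`), as are the gape and skull-length landmarks of
the `gape_ratio()` preservation QC (threshold 0.10 by default).

## The synthetic-data generator

`simulate_tree()` draws pure-birth trees rescaled to unit depth.
`simulate_modular_shapes()` draws tip configurations from
`vec(X) ~ MVN(1 (x) mu, C (x) Sigma)` with `Sigma` block-structured by a
true bone-to-module map: per-landmark correlation `within_corr` inside a
module and `between_corr` across modules (defaults 0.7 / 0.1, a clearly
modular regime), per-landmark variance equal to the module's rate, and the
three coordinates of a landmark independent with variance rate/3 — so
`module_rates()` is calibrated directly against `rate_per_module`.
Positive-definiteness of the implied covariance is checked at construction.
The default scale for validation runs is 64 tips and 48 landmarks (3 per
bone), with 99 permutations/simulations per test and 50–200 replicates per
property — sizes chosen so the estimators' behaviour (calibration, power,
ranking) is measurable with tight Monte-Carlo error while the whole suite
runs on a desktop.

Data are generated directly in aligned tangent-space coordinates around a
seeded mean shape. That is sufficient to exercise the CR, GM, and rate
machinery, but deliberately omits one feature of real data:
Procrustes-induced correlations. Superimposition redistributes variation
(centering removes any common displacement, so a coherently varying large
block loses proportionally more variance than a small one), which can
perturb rates and rankings estimated from aligned data. The generator's
`nuisance = TRUE` mode therefore applies random rotations, translations, and
scalings per specimen so the full GPA path is exercised end-to-end; but
calibration and recovery checks are run on the tangent-space data, where the
planted truth is exact. Passing tests demonstrate correctness of the
estimators under their model, not immunity to superimposition artefacts in
real data. Linkage batches (`simulate_linkage_batch()`) are unit squares
with a per-system J4 lift plus Gaussian jitter; an ordering of lifts implies
the same ordering of mean planarities.

## Degenerate inputs and tie-breaks

Coincident points (zero centroid size), collinear J1–J2–J3, zero-area
triangles, constant distance matrices, single-trait modules, empty modules,
non-positive-definite covariances, missing branch lengths, and duplicate tip
labels are all hard errors with messages naming the offending object.
Permutation and simulation p-values use the `(1+k)/(n+1)` convention and so
lie in (0, 1]. All stochastic functions require a seed and are
bit-reproducible given it; file round trips are coordinate-exact at 17
significant digits.

## Known limitations

* Brownian motion everywhere: no OU or early-burst rate models, by design.
* The GM criterion is a deviance-plus-penalty ranking; absolute values are
  not comparable across data sets or to other software's criteria.
* Only the ranking-oriented conditional-independence graphs of the
  hypothesis registry (unions of cliques) are fitted in one sweep;
  arbitrary graphs rely on IPS convergence.
* No missing-landmark estimation, mesh handling, or kinematic (transmission
  coefficient) modelling; planarity is a static rest-position geometry.
* The packaged 200-point scheme fixes counts and topology, not anatomy.
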