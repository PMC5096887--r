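---
title: "Structural covariance networks from regional cortical thickness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from regional cortical thickness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the statistical model, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
numerical conventions, and known limitations. Code chunks are illustrative
and not evaluated at build time; every empirical statement below is
computed by the test suite or the acceptance script, not asserted here.

## The structural covariance model

Structural covariance treats the *inter-subject* correlation of a
morphometric measure — here regional mean cortical thickness in mm — as a
proxy for connectivity between brain regions. The analysis is group-level:
one network per group, not per subject, because a correlation across
subjects is only defined for a sample. The pipeline is:

1. **Residualization.** For each region, thickness is regressed by OLS on
   nuisance covariates (default: age, gender, an illness-burden score, and
   mean cortical thickness; a white-matter-hyperintensity volume can be
   added for a sensitivity variant). Residuals replace the raw values. The
   regression is fitted *within each group* by default, so each group's
   covariance reflects only its own covariate-adjusted variation; a pooled
   fit is available (`per_group = FALSE`). The within-group default was a
   genuinely open choice — pooled fitting shares covariate slopes but lets
   one group's slope bias the other's residuals; per-group is the more
   conservative reading of "adjusted within each network".
2. **Association.** The R × R Pearson correlation matrix of residuals
   across the subjects of one group, diagonal set to 0.
3. **Density thresholding.** At density d the `round(d·R(R−1)/2)` largest
   *signed* correlations become the edges of a binary undirected graph.
   Signed ranking (negative correlations are never edges) follows the
   reading of thresholding as keeping the strongest positive associations;
   magnitude ranking is available behind `rank_absolute = TRUE`. Rounding
   is half-away-from-zero and ties are broken by lexicographic node-pair
   order, so thresholding is deterministic and seed-free, and edge sets are
   nested across densities.
4. **Minimum density.** `find_min_density()` returns the first grid point
   at which *every* group's network is a single connected component
   ("connected" means one component containing all R nodes, not merely the
   absence of isolated nodes). Resilience, nodal comparison and hub
   analyses conventionally run there.

## Graph measures and normalization

Integration: characteristic path length `Lp` (mean shortest-path length
over connected pairs) and global efficiency (mean inverse shortest-path
length, with 1/∞ = 0). Segregation: mean nodal clustering `Cp`, local
efficiency, transitivity `T` (whole-network triangle density, insensitive
to low-degree nodes), and Newman modularity `Q` maximized by deterministic
greedy agglomeration. Centrality: unnormalized shortest-path betweenness.
Standard shortest-path machinery, rewiring and the greedy modularity
optimizer are delegated to igraph; clustering and transitivity use direct
adjacency algebra. Every measure is validated against independent
brute-force implementations (hand-written BFS, triple enumeration, path
counting, exhaustive partition search) on randomized batteries of graphs
with ≤ 10 nodes in the test suite; greedy modularity is additionally
bounded against the exhaustive-partition optimum on graphs with ≤ 8 nodes
(observed worst gap well under 0.1; the greedy result is also floored at
the trivial single-module partition, Q = 0, which the raw greedy cut can
fall below on complete graphs).

Small-world indices normalize against **degree-preserving references**:
Maslov–Sneppen double-edge swaps, 100·E swap attempts per reference, 20
references by default (a compromise between normalization variance and
cost; the normalization baseline stabilizes quickly). `gamma = Cp/Cp_rand`
and `lambda = Lp/Lp_rand` use the *ratio of means* over the reference set
(mean-of-ratios weights unstable single references too heavily), and
`sigma = gamma/lambda`.

**Disconnected graphs.** Below D_min a thresholded network can be
fragmented, and at low densities (e.g. 228 edges over 68 nodes) it
routinely contains isolated nodes — in which case *no connected
degree-preserving reference exists at all*. The conventions are: path
length averages over reachable pairs and carries a `disconnected` flag;
efficiency-based measures handle disconnection natively; and
`small_world()` demands connected references exactly when the network
itself is connected, otherwise it compares reachable-pair path lengths
like-for-like on network and references. Within the primary flow these
conventions are invisible (D_min guarantees connectivity); they only
govern off-grid exploration and the full-grid small-world scan.

## Group inference

Permutation tests shuffle group labels across subjects (preserving group
sizes) and recompute the *entire* pipeline — residualization included — for
every permutation, so the null distribution honestly reflects the
covariate adjustment. p-values are two-tailed with the add-one estimator
`(1 + #{|null| ≥ |obs|})/(n_perm + 1)`, which counts the observed labeling
in its own null and can never return 0. The area-under-curve summary
integrates the metric-difference curve over the density grid by the
trapezoidal rule (non-uniform grids are fine) and tests it against the
permutation null of AUC differences; the per-density confidence band is
the 2.5–97.5 percentile band of null differences. If a permuted network
fragments at some density the metric is computed under the disconnection
conventions above and the permutation is kept, so the null sample size
stays fixed. Nodal comparisons (degree, clustering, betweenness at a single
density) are FDR-corrected across regions per metric by Benjamini–Hochberg,
the correction consistent with vertex-wise practice in this literature.

The test suite calibrates the machinery: under a null generator (identical
group covariance) the empirical type-I error of the transitivity AUC test
at α = 0.05 is checked to lie in [0.03, 0.07] over 500 replicates at
n_perm = 200 (the 20-region, 15+15-subject replicate size keeps the
calibration affordable; calibration of a permutation test is not a
function of matrix size). Power is checked with a planted segregation
difference (within-module correlation 0.6 → 0.8 in one group, realistic
group sizes of 25 and 33, 60 replicates): the planted group shows higher
transitivity and modularity in the majority of replicates and the
transitivity AUC test detects it with power above one-half.

## Resilience and hubs

Attack curves remove nodes one at a time and track the size of the largest
remaining component divided by the original node count R (a fixed
denominator keeps equal-sized group networks directly comparable), at every
integer removal count reported as fractions k/R from 0 to 1. Random
failure averages 50 uniformly random removal orders by default (the repeat
count is a variance/cost compromise; curves are seeded and bit-stable).
Targeted attack removes nodes by *descending betweenness computed once on
the intact network* — a static ranking, with ties broken by higher degree
then lexicographic label; a recompute-after-each-removal mode exists for
sensitivity analysis. The largest-component bookkeeping uses reverse node
addition with union-find, O(n + m) per order, verified against direct
component search.

One empirical finding shaped the tests here: "targeted attacks are at
least as damaging as random failure at every fraction" is *not* a theorem.
A static targeted order can plateau late in the attack while random curves
keep falling, and on a *fragmented* modular network random failure spreads
damage across the disjoint modules that define the largest component,
beating a concentrated targeted order outright. The dominance claim is
therefore asserted where it actually lives: per-fraction for hub-dominated
closed forms (a star), and as whole-curve mean degradation for connected
covariance networks at their minimum density — the regime in which the
resilience comparison is defined in the first place. This is also a good
reason the analysis is specified at D_min.

Hubs are regions whose betweenness is at least 2 SD above the network mean,
with the *population* SD over the R nodal values (the network is the whole
population of its nodes, not a sample) and an inclusive boundary ("2SD
greater" read as at-least; the star graph's center sits exactly at
z = 2.0 and is classified as a hub). Both choices are configurable. Hub
membership is invariant under any positive rescaling of betweenness.

## The synthetic generator

`synthetic_spec()`/`generate_cohort()` emulate the data structure the
pipeline assumes: two groups (default 25 and 33 subjects) × 68 regions,
regions partitioned into 4 equal contiguous modules, and per group a
*block-constant* (compound-symmetry) correlation matrix — `within_rho`
inside modules (defaults 0.6 and 0.8, the second group more segregated),
`between_rho` across (default 0.1). Block-constant structure keeps
positive semi-definiteness checkable and makes segregation strength a
single knob; invalid parameter combinations are refused at construction,
never repaired toward the nearest valid matrix. Optional hub regions get
elevated cross-module correlation (bounded by PSD at roughly
`sqrt(between + (1 − between)/n_cross)`). Thickness is
`2.3 mm + covariate effects + N(0, 0.1² B + 0.05² I)` per subject: the
structured regional SD of 0.1 mm matches typical inter-subject spread of
regional thickness, and the 0.05 mm independent noise gives a
structured-to-total variance ratio of 0.8, in line with test–retest
reliability of regional thickness estimates. Covariates are drawn from
plausible ranges (age uniform 60–84, binary gender at 26%, right-skewed
gamma illness-burden and WMH-volume scores) with additive linear effects
on thickness (defaults: −0.005 mm/year of age, 0.02 mm for gender,
−0.003 mm per illness point) — exactly the linear confounding model the
residualization step assumes. Ground truth (implied total correlation
matrices, module assignment, slopes, planted hubs) is returned alongside
the cohort for recovery testing.

**What the generator does not emulate.** Real covariance matrices have a
smooth eigenvalue spectrum, spatial autocorrelation, hemispheric symmetry
and a dominant global factor; block-constant matrices have none of these.
One consequence is worth spelling out: regressing out *mean thickness*
from a hard-block generator pushes between-module residual correlations
toward −1/(m−1) ≈ −1/3 (grand-mean compensation), so with signed
thresholding the strongly segregated default group often cannot form a
single connected component anywhere on the 0.10–0.20 grid at realistic
sample sizes — unlike real cortical data, whose covariance gradient
connects at low density. The pipeline handles this honestly:
`find_min_density()` errors with per-group component sizes, and `run_all()`
falls back to the top of the grid with a manifest flag rather than
aborting. Passing tests on the generator therefore validates the
machinery, calibration and effect recovery — not the claim that real
cortices behave like block matrices.

## Numerical conventions and reproducibility

* Edge counts: `round(d·R(R−1)/2)`, half away from zero; ties in the
  correlation ranking broken by ascending (row, column) pair — results are
  seed-free given the association matrix.
* All randomness (simulation, permutation, rewiring, attack orders) flows
  from one master seed through named integer substreams below 2³¹, so each
  component is independently reproducible; reruns are byte-identical.
* Residualization is idempotent to 1e-10 and invariant to affine covariate
  rescaling; both are tested.
* Degenerate inputs: zero-variance regions, rank-deficient covariate
  designs, edgeless graphs, zero betweenness variance and non-PSD
  generator parameters are all refused with named errors rather than
  silently patched (the single exception, documented above, is the
  `run_all()` density fallback).
* Problem sizes in the test suite (500 calibration replicates at 20
  regions with n_perm = 200; 60 power replicates at the full 68-region
  size; 200-graph oracle batteries with ≤ 10 nodes; 60 exhaustive
  modularity comparisons with ≤ 8 nodes) were chosen so the whole suite
  validates every claim at desk scale.

## Known limitations

* Group-level networks only: no per-subject covariance networks, hence no
  correlation of network measures with individual clinical scores.
* Binary undirected graphs only; no weighted, signed or directed variants.
* The greedy modularity optimizer is deterministic but not exact; its gap
  is bounded empirically on small graphs, not proven in general.
* Permutation comparison of the normalized indices (gamma, lambda, sigma)
  is not offered: a per-permutation reference ensemble multiplies cost by
  the reference count, and the unnormalized components carry the same
  information at fixed density and degree sequence. Sigma is reported with
  reference-based normalization in the descriptive metric curves instead.
* The 2SD hub rule is descriptive; no inferential test of hub-set
  differences between groups is performed.
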