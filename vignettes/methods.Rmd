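---
title: "Partitioned joint-constraint optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned joint-constraint optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointpart)
```

## The constraint model

A joint graph is a set of 3D joints `p_i` (each with an initial position
`p_io`, a stiffness ratio `k_i > 0` and an optional destination) and four
families of pairwise constraints:

* **A — absolute distance** (equality): `Dist_ij − |p_i − p_j| = 0`.
* **B — pivot angle** (inequality, degrees): the angle between the
  initial direction `p_io − p_j` and the current direction `p_i − p_j`
  must stay below `θ_ij`; an optional axis lock additionally fixes one
  coordinate of the direction vector.
* **C — flexibility band** (two inequalities): the realized distance must
  stay within `Δd_max` of the rest distance. A pair never carries both an
  A and a C constraint.
* **D — cone** (inequality, created only by splitting): a real joint is
  held inside a cone anchored at a pinned virtual joint, see below.

The objective is `Σ k_l |p_l − p_dest,l|` over joints with a prescribed
motion; joints without one contribute no objective term. All angles are
stored in degrees (converted to radians only inside trig calls), all
coordinates in raw right-handed scene units.

Two printed relations in the source model are degenerate as stated and are
resolved as package design choices: the cone-radius relation is
implemented as the radius formula `r = d · tan(a_ij / 2)`, the unique
choice under which the cone residual `2·arctan(r/d) − a_ij` is exactly
zero on the cone surface; and the anchor distance in the cone residual is
read as `|v_j − p_i|`, the distance from the evaluating joint to its
virtual anchor, because a raw position norm would depend on the origin.
Both choices are locked by tests. The sign term `sgn(·)` treats 0 as +1 so
the residual is continuous from the split instant, where the reference and
anchor directions coincide. Arc-cosine arguments are clamped to [−1, 1]
before evaluation.

The package also exposes the scalar diagnostics of the generalized
distance constraint `C(p) = ½[(p−p₀)² − r²]` with its iteration
derivatives `Ċ = (p−p₀)·ṗ` and `C̈ = ṗ² + (p−p₀)·p̈`, and the
multiplier magnitude `|λ| = √(−(p−p₀)·p̈)`; a trajectory that satisfies
the constraint keeps all three at zero, which the tests verify on an
analytic circular trajectory under finite differences. A negative
radicand (possible off the constraint manifold) is clipped to zero and
flagged rather than propagated as `NaN`.

## Partitioning

Communities are detected on the constraint multigraph (joints = nodes,
every constraint = one edge; parallel constraints count separately):

* **CNM** greedy modularity (Clauset–Newman–Moore), via igraph's
  `cluster_fast_greedy` on the multigraph collapsed to weighted simple
  edges — mathematically the same agglomerative greedy maximization of
  Newman modularity `Q = Σ_c (e_cc − a_c²)`. The package computes `Q`
  itself (`graph_modularity()`), and the tests check it against a
  brute-force evaluation of the definition, so the detector and the
  statistic are independent routes.
* **DBSCAN** on the joints' *initial positions* under Euclidean distance.
  The source protocol uses ε ∈ {5, 10} and MinPts = 2 against a ~40-unit
  scene, which is only meaningful for a spatial metric; whether its
  distance function was spatial or graph-based is ambiguous in the
  source, so Euclidean position distance is the package's choice
  (recorded here, flagged in the docs). Points reachable from no core
  point become singleton communities, because every joint must be owned
  by exactly one partition.
* **k-means** on initial positions, seeded and deterministic; `k` is an
  explicit parameter, with a convenience in `run_benchmark()` to tie it
  to the community count DBSCAN finds at a given ε, mirroring the
  reference protocol.

`split_graph()` then copies every intra-community constraint into its
community's partition unchanged, deletes every cross-community
constraint, and inserts, on each side of a cut pair, a *virtual joint*
pinned at the removed neighbor's split-time position plus one cone
constraint of preset aperture (default 30°, configurable) whose radius is
taken at the split-time pair distance. One virtual joint and one cone are
inserted per distinct (real joint, removed neighbor) pair — virtual
joints represent nodes, not deleted edges — so several parallel cut
constraints share one anchor. Virtual joints never appear in A/B/C
constraints and contribute no optimization variables; partitions are
disjoint over real joints. `validate_partitions()` checks all of these
invariants and reports violations instead of raising.

## The solver

No COBYLA binding is available in this package's dependency envelope, so
the solver implements the same contract natively: a **derivative-free
linear-approximation trust-region method**. Per iteration:

1. Linear models of every objective term and every constraint row are
   built from structured forward differences. Joints are greedy-colored so
   that two joints sharing a constraint never sit in one color class; one
   evaluation per (color, coordinate) then recovers the full sparse
   Jacobian in ~`3 × (max degree)` evaluations instead of `3 × n_joints`.
   The true functions are never differentiated analytically.
2. A trust-region step is computed from the models by a regularized KKT
   solve: equality rows are pinned, violated or boundary inequality rows
   enter a working set (rows with wrong-signed multipliers leave it), and
   the resulting sparse normal system is solved by Cholesky. The
   regularization weight is re-sized so the trust region, not the
   gradient scale, limits the step; the step is finally scaled back into
   the box `|d|_∞ ≤ Δ`.
3. The step is accepted iff it reduces the L1 exact-penalty merit
   `f + μ Σ violations` (μ kept above the observed multiplier scale).
   When constraint curvature eats a meaningful share of the predicted
   gain, a second-order correction — a minimum-norm restoration step on
   the violated rows — is tried first. Rejections halve Δ; high-quality
   boundary steps double it; the run ends when Δ falls below `rhoend`,
   when a near-feasible step is shorter than `rhoend`, or when the merit
   stalls for several iterations at feasibility.

Equalities are relaxed symmetrically to `|e| ≤ τ` (default τ = 1e-6 scene
units), the standard idiom for inequality-only solvers, and strict
inequalities are implemented as `≤ 0` (a measure-zero distinction no
numeric solver can observe). Defaults are scale-aware: the initial trust
radius is 0.1 × the mean rest length of the A/C constraints (fallback
0.5), `maxfun` = 100 evaluations per variable. Exhausting `maxfun`
returns `converged = FALSE`, never an error. Fixed inputs and options
give bit-identical results, so permuting the partition solve order cannot
change the merged solution.

**Limitation.** The method is first-order, like the reference method's
class: near strongly curved active manifolds (many equality constraints,
cones at their boundary) its asymptotic convergence is linear and can be
slow; the stall test then truncates the tail. Solutions are feasible to
`~10·τ` but the objective can sit slightly above the true local minimum;
both solve routes (partitioned and whole-problem) share this behavior,
and the error metrics compare the two routes rather than either against
an unknown exact optimum. Wall-clock speedups are therefore
hardware- and budget-dependent and are reported, never asserted.

## The synthetic generator

No construction procedure for the reference's "random joint sets" is
published, so the generator defines one that reproduces the stated,
observable preconditions of those benchmarks:

* ~4 constraints per joint (a 30-joint model corresponds to ~120
  constraints), sizes 1500–5000;
* strong community structure: every set's final CNM modularity exceeds
  0.3 (defaults give ~0.77);
* a density radius of 5–10 scene units separates clusters against a
  scene magnitude of ~40: six Gaussian clusters of spread 1.5 with
  centers at least 12 apart inside a cube sized to the community count
  give a bounding-box diagonal of roughly 40-50 units;
* a feasible initial state: A/C rest distances are the realized
  distances, `Δd_max = (1 − k_i)·Dist_ij` with `k` drawn from (0.2, 0.8)
  (the source ties `Δd_max` to the stiffness ratio without a formula;
  this is the one-parameter version consistent with `k < 1`), and pivot
  bounds are drawn from 10–90°, trivially satisfied at `p_i = p_io`.
* 95% of constraints fall inside communities (`intra_fraction`), A/C
  conflicts and exact duplicates are rejected at draw time.

Motion commands (`generate_motion()`) move a seeded 10% of joints by 1
scene unit in a uniform random direction — a displacement comparable to
the cluster spread and small against the scene, standing in for
interactive editing commands. What the generator does **not** emulate:
anatomical topology (chains, sheets, attachment patterns), meshes, or
spatially correlated motions. A green test on synthetic data therefore
establishes the partitioning machinery's correctness and its error
behavior under planted community structure, not anatomical fidelity.

## Error metrics and benchmarks

The per-joint error is the Euclidean relative discrepancy
`e_i = |p_part,i − p_nonpart,i| / |p_nonpart,i|`; the percent error is
`mean(e_i) × 100` over all joints (an elementwise reading would divide by
zero on any zero coordinate; joints whose reference norm is below 1e-12
are excluded and reported). The scene-normalized variant divides by the
scene magnitude, implemented as the bounding-box diagonal of the initial
positions — the source states the value (40.86) but not the formula, and
the diagonal is the one scene-level length scale that is
orientation-independent and matches that magnitude for a ~40-unit scene.
Both statistics include every joint, moved or not (the source is silent;
a moved-only restriction is a one-line filter on the per-joint vector).

`run_benchmark()` sweeps sizes × methods with seeded replicates
(averaged, as in the reference protocol's five repetitions), records
communities, modularity, times, errors and convergence fractions, and
fits runtime against size under a linear and an exponential model with
both R² computed on the time scale. The scaling-shape test follows the
protocol of a fixed *mean community size* (~60 joints per community), so
the community count grows with the problem and per-partition cost stays
bounded; with a fixed community count the partitions themselves grow and
the comparison degenerates into solver-budget noise.

## Numerical choices and degenerate inputs

* Satisfaction tolerance τ = 1e-6 scene units (configurable); converged
  solves are checked to `10·τ` on equalities.
* Degenerate angle directions (`p_i = p_j` during a solve) score 180° so
  the solver steers away; the standalone residual raises a
  degenerate-geometry error, as does a zero-distance cone anchor.
* `sgn(0) := +1`; arc-cosine clamping to [−1, 1]; cone radius requires
  `d > 0` and aperture in (0, 180).
* All randomness (generator, motion, k-means restarts) flows through
  explicit seeds; RNG state is restored after each seeded operation, so
  library calls never perturb a caller's RNG stream.
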