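# jointpart

Partitioned constrained optimization for articulated 3D joint graphs.

## The problem

Virtual-anatomy and surgical-simulation tools model articulated structures
as *joints* — 3D nodes attached to meshes — tied together by geometric
constraints: fixed inter-joint distances, bounded pivot angles (optionally
locked to an axis), and flexibility bands that let a pair stretch or
compress within a margin set by a stiffness ratio. Editing such a model
("move the clavicle by 2 units") becomes a constrained nonlinear program:

```
min  Σ_l  k_l · | p_l − p_dest,l |
s.t.  Dist_ij − |p_i − p_j|            = 0      (i,j) ∈ A   distance
      ∠(p_io − p_j , p_i − p_j) − θ_ij < 0      (i,j) ∈ B   pivot angle
      (p_io − p_j)_axis − (p_i − p_j)_axis = 0              axis lock
      Dist_ij − Δd_max − |p_i − p_j|   < 0      (i,j) ∈ C   flexibility
      |p_i − p_j| − Dist_ij − Δd_max   < 0
```

solved with a derivative-free linear-approximation trust-region method
(COBYLA-style). Whole-model solves scale badly with the constraint count.
This package implements the partition-based remedy: detect communities in
the constraint graph (CNM greedy modularity, DBSCAN, or k-means), cut the
graph along community boundaries, and replace each cut edge by a *virtual
joint* — a pinned duplicate of the removed neighbor — plus a *cone
constraint*

```
2 · sgn((p_j − p_i)·(v_j − p_i)) · arctan(r / |v_j − p_i|) − a_ij < 0
```

with preset aperture `a_ij` (default 30°) and radius `r = d·tan(a_ij/2)`
at the split-time distance `d`, so each partition remains a self-contained
program that anticipates its removed neighbors' range of motion. The
partitions are independent sub-problems; the merged solution is compared
against the non-partitioned one with the percent error
`Avg(|p_part,i − p_nonpart,i| / |p_nonpart,i|) × 100` and its
scene-normalized variant (divided by the bounding-box diagonal of the
scene).

## Worked example

```r
library(jointpart)

# a 300-constraint problem: 75 joints in 6 Gaussian communities,
# feasible at its initial state by construction
g <- generate_problem(generator_spec(n_constraints = 300, seed = 1))
g <- generate_motion(g, fraction_moved = 0.1, magnitude = 1, seed = 2)

a <- detect_communities(g, "cnm")
a
#> <community_assignment> cnm: 75 joints in 6 communities, Q=0.7399

full <- solve_graph(g)                       # whole-problem solve
part <- solve_partitioned(g, "cnm", seed = 1)
part
#> <solve_result> 75 joints  objective=1.33394  max violation=4.48e-07  NOT converged
#>   12037 evaluations, 788 iterations, 11.91s

as.numeric(percent_error(part, full))        # average relative error, %
#> [1] 2.576211
normalized_error(part, full, scene_magnitude(g))  # scene-normalized, %
#> [1] 0.05160001
```

The modularity `Q = 0.74` says the constraint graph has strong community
structure (values above 0.3 are conventionally significant). `NOT
converged` means one partition exhausted its default evaluation budget —
a flag, never an error; the returned point is still feasible to
`4.5e-7` scene units. The partitioned solution lands within ~2.6% average
relative position error of the non-partitioned one — about 0.05% of the
50-unit scene — which is the partitioning cost the error metrics
quantify.

Scenes serialize to a documented JSON dialect (`read_scene()` /
`write_scene()`, schema in `inst/extdata/scene-schema.json`), benchmark
sweeps to CSV (`run_benchmark()` / `write_report()`). A CLI wrapper with
`synth`, `partition`, `solve` and `benchmark` subcommands is installed at
`system.file("cli", "jointpart", package = "jointpart")`.

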