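#' Generator specification for synthetic joint-constraint problems
#'
#' Describes a random benchmark problem with planted community structure:
#' joints are placed in Gaussian clusters and constraints are drawn
#' preferentially within clusters, with rest lengths taken from the
#' realized geometry so the initial state is feasible by construction.
#' Defaults emulate the reference benchmark conditions: about 4 constraints
#' per joint, 6 communities, 95% of constraints inside communities, a
#' cluster separation of 12 scene units against a spread of 1.5 (so a
#' density radius of 5-10 units separates clusters), and an overall scene
#' magnitude around 40 units.
#'
#' @param n_constraints target constraint count (>= 0).
#' @param n_communities number of planted clusters.
#' @param constraints_per_joint mean constraints per joint; the joint count
#'   is `ceiling(n_constraints / constraints_per_joint)`.
#' @param kind_mix named fractions for constraint kinds A (absolute
#'   distance), B (pivot angle), C (flexibility); must sum to 1.
#' @param intra_fraction fraction of constraints drawn inside a community.
#' @param community_spread Gaussian spread of each cluster (scene units).
#' @param community_separation minimum distance between cluster centers.
#' @param stiffness_range range for the per-joint stiffness ratio `k`
#'   (kept below 1 so the flexibility band `dmax = (1 - k) * dist` stays
#'   positive).
#' @param axis_lock_fraction fraction of B constraints that carry a random
#'   axis lock.
#' @param seed RNG seed; fully determines the generated problem.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_constraints = 1500L, n_communities = 6L,
                           constraints_per_joint = 4,
                           kind_mix = c(A = 0.5, B = 0.2, C = 0.3),
                           intra_fraction = 0.95,
                           community_spread = 1.5,
                           community_separation = 12,
                           stiffness_range = c(0.2, 0.8),
                           axis_lock_fraction = 0,
                           seed = 1L) {
  spec <- list(n_constraints = as.integer(n_constraints),
               n_communities = as.integer(n_communities),
               constraints_per_joint = constraints_per_joint,
               kind_mix = kind_mix, intra_fraction = intra_fraction,
               community_spread = community_spread,
               community_separation = community_separation,
               stiffness_range = stiffness_range,
               axis_lock_fraction = axis_lock_fraction,
               seed = as.integer(seed))
  if (spec$n_constraints < 0 || spec$n_communities < 1 ||
      spec$constraints_per_joint <= 0) {
    jp_stop("invalid counts in generator spec", "jointpart_invalid_parameter")
  }
  if (!setequal(names(kind_mix), c("A", "B", "C")) ||
      any(kind_mix < 0) || abs(sum(kind_mix) - 1) > 1e-9) {
    jp_stop("kind_mix must be fractions named A, B, C summing to 1",
            "jointpart_invalid_parameter")
  }
  if (intra_fraction < 0 || intra_fraction > 1 ||
      axis_lock_fraction < 0 || axis_lock_fraction > 1) {
    jp_stop("fractions must lie in [0, 1]", "jointpart_invalid_parameter")
  }
  if (community_spread <= 0 || community_separation <= 0 ||
      any(stiffness_range <= 0) || diff(stiffness_range) < 0) {
    jp_stop("scales must be positive", "jointpart_invalid_parameter")
  }
  structure(spec, class = "generator_spec")
}

# cluster centers with pairwise separation >= sep, in a cube scaled to the
# community count so the default 6-community scene spans ~40 units
draw_centers <- function(k, sep) {
  side <- sep * max(2, ceiling(k^(1 / 3)) + 0.5)
  centers <- matrix(NA_real_, nrow = k, ncol = 3)
  for (i in seq_len(k)) {
    for (try in 1:2000) {
      cand <- stats::runif(3, 0, side)
      if (i == 1L) break
      d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3, byrow = TRUE))^2))
      if (all(d >= sep)) break
      if (try == 2000) {
        jp_stop("could not place separated community centers",
                "jointpart_invalid_parameter")
      }
    }
    centers[i, ] <- cand
  }
  centers
}

#' Generate a random joint-constraint problem
#'
#' Realizes a [generator_spec()]: places
#' `ceiling(n_constraints / constraints_per_joint)` joints in
#' `n_communities` Gaussian clusters, then draws constraints with
#' probability `intra_fraction` inside a community and otherwise across two
#' communities. A and C constraints take their rest distance from the
#' realized geometry (so [evaluate_all()] reports zero violations at the
#' initial state), C constraints take `dmax = (1 - k_i) * dist`, and B
#' constraints draw a pivot bound uniformly in 10-90 degrees. A joint pair
#' never receives both an A and a C constraint, and exact same-kind
#' duplicates are rejected. Ground-truth community labels are recorded in
#' `metadata$community_labels`.
#'
#' @param spec a [generator_spec()].
#' @return a [joint_graph()].
#' @export
generate_problem <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n_constraints == 0L) {
    return(joint_graph(NULL, NULL, metadata = list(spec = unclass(spec))))
  }
  n_joints <- as.integer(ceiling(spec$n_constraints /
                                   spec$constraints_per_joint))
  if (spec$n_communities > n_joints) {
    jp_stop("more communities than joints", "jointpart_invalid_parameter")
  }
  with_seed(spec$seed, {
    K <- spec$n_communities
    centers <- draw_centers(K, spec$community_separation)
    labels <- sample(rep(seq_len(K) - 1L, length.out = n_joints))
    P <- centers[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(3L * n_joints, sd = spec$community_spread),
             ncol = 3)
    ids <- sprintf("j%04d", seq_len(n_joints))
    stiffness <- stats::runif(n_joints, spec$stiffness_range[1L],
                              spec$stiffness_range[2L])
    members <- split(seq_len(n_joints), labels)

    kinds <- character(spec$n_constraints)
    ii <- integer(spec$n_constraints)
    jj <- integer(spec$n_constraints)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    kind_levels <- c("A", "B", "C")
    n_placed <- 0L
    for (c_idx in seq_len(spec$n_constraints)) {
      placed <- FALSE
      for (try in 1:200) {
        intra <- stats::runif(1) < spec$intra_fraction || K == 1L
        if (intra) {
          cm <- members[[sample.int(K, 1L,
                                    prob = lengths(members))]]
          if (length(cm) < 2L) next
          pair <- cm[sample.int(length(cm), 2L)]
        } else {
          cs <- sample.int(K, 2L)
          pair <- c(members[[cs[1L]]][sample.int(lengths(members)[cs[1L]], 1L)],
                    members[[cs[2L]]][sample.int(lengths(members)[cs[2L]], 1L)])
        }
        kind <- sample(kind_levels, 1L, prob = spec$kind_mix)
        a <- min(pair); b <- max(pair)
        key <- sprintf("%d|%d|%s", a, b, kind)
        pkey <- sprintf("%d|%d", a, b)
        # reject exact duplicates and A/C conflicts on the same pair
        conflict <- !is.null(seen[[key]]) ||
          (kind == "A" && !is.null(seen[[sprintf("%s|C", pkey)]])) ||
          (kind == "C" && !is.null(seen[[sprintf("%s|A", pkey)]]))
        if (!conflict) {
          seen[[key]] <- TRUE
          n_placed <- n_placed + 1L
          kinds[n_placed] <- kind
          ii[n_placed] <- pair[1L]
          jj[n_placed] <- pair[2L]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        jp_stop("constraint capacity exhausted: spec too dense for its joint count",
                "jointpart_invalid_parameter")
      }
    }

    d_real <- sqrt(rowSums((P[ii, , drop = FALSE] - P[jj, , drop = FALSE])^2))
    isA <- kinds == "A"; isB <- kinds == "B"; isC <- kinds == "C"
    dist <- ifelse(isA | isC, d_real, NA_real_)
    dmax <- ifelse(isC, (1 - stiffness[ii]) * d_real, NA_real_)
    theta <- ifelse(isB, stats::runif(spec$n_constraints, 10, 90), NA_real_)
    axis <- rep(NA_character_, spec$n_constraints)
    lock <- isB & stats::runif(spec$n_constraints) < spec$axis_lock_fraction
    axis[lock] <- sample(c("x", "y", "z"), sum(lock), replace = TRUE)

    joints <- data.frame(id = ids, x = P[, 1], y = P[, 2], z = P[, 3],
                         stiffness = stiffness, stringsAsFactors = FALSE)
    constraints <- data.frame(kind = kinds, i = ids[ii], j = ids[jj],
                              dist = dist, dmax = dmax, theta = theta,
                              axis = axis, stringsAsFactors = FALSE)
    joint_graph(joints, constraints,
                metadata = list(
                  spec = unclass(spec),
                  community_labels = structure(as.integer(labels),
                                               names = ids)))
  })
}

#' Attach random motion commands to a graph
#'
#' Gives a seeded sample of joints a destination
#' `p_dest = p_io + magnitude * u` with `u` a uniform random unit vector;
#' all other joints keep no destination (and are therefore dropped from the
#' objective). The defaults move 10% of the joints by 1 scene unit, i.e. a
#' displacement comparable to the cluster spread and small against the
#' ~40-unit default scene.
#'
#' @param graph a [joint_graph()].
#' @param fraction_moved fraction of (real) joints to move, in (0, 1].
#' @param magnitude displacement length in scene units (>= 0).
#' @param seed RNG seed.
#' @return the graph with destinations set; `metadata$motion` records the
#'   parameters.
#' @export
generate_motion <- function(graph, fraction_moved = 0.1, magnitude = 1,
                            seed = 1L) {
  stopifnot(inherits(graph, "joint_graph"))
  if (fraction_moved <= 0 || fraction_moved > 1) {
    jp_stop("fraction_moved must be in (0, 1]", "jointpart_invalid_parameter")
  }
  if (magnitude < 0) {
    jp_stop("magnitude must be >= 0", "jointpart_invalid_parameter")
  }
  real <- which(!graph$joints$virtual)
  n_move <- max(1L, round(fraction_moved * length(real)))
  with_seed(seed, {
    chosen <- real[sample.int(length(real), n_move)]
    u <- matrix(stats::rnorm(3L * n_move), ncol = 3)
    u <- u / pmax(sqrt(rowSums(u * u)), 1e-12)
    graph$joints$dx[chosen] <- graph$joints$x0[chosen] + magnitude * u[, 1]
    graph$joints$dy[chosen] <- graph$joints$y0[chosen] + magnitude * u[, 2]
    graph$joints$dz[chosen] <- graph$joints$z0[chosen] + magnitude * u[, 3]
  })
  graph$metadata$motion <- list(fraction_moved = fraction_moved,
                                magnitude = magnitude, seed = seed,
                                moved = graph$joints$id[chosen])
  graph
}
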