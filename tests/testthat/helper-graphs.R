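# small graph builders shared across test files

# two k-cliques of A constraints joined by a single bridge edge; rest
# distances are the realized distances so the initial state is feasible
clique_bridge_graph <- function(k = 3L, gap = 10) {
  n <- 2L * k
  ids <- sprintf("j%02d", seq_len(n))
  pos <- rbind(
    matrix(stats::rnorm(3 * k, sd = 0.5), ncol = 3),
    matrix(stats::rnorm(3 * k, sd = 0.5), ncol = 3) +
      matrix(c(gap, 0, 0), k, 3, byrow = TRUE)
  )
  pairs <- rbind(
    t(utils::combn(seq_len(k), 2)),
    t(utils::combn(seq_len(k), 2)) + k,
    c(k, k + 1L)  # bridge
  )
  d <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                       pos[pairs[, 2], , drop = FALSE])^2))
  joint_graph(
    data.frame(id = ids, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    data.frame(kind = "A", i = ids[pairs[, 1]], j = ids[pairs[, 2]], dist = d)
  )
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

small_problem <- function(n_constraints = 60L, n_communities = 3L, seed = 1L,
                          moved = TRUE, ...) {
  g <- generate_problem(generator_spec(
    n_constraints = n_constraints, n_communities = n_communities,
    constraints_per_joint = 3, seed = seed, ...))
  if (moved) g <- generate_motion(g, 0.15, 0.5, seed = seed + 500L)
  g
}
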