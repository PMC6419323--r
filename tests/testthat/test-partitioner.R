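# brute-force modularity oracle: evaluate Q directly from its definition
# on an explicit edge list
modularity_oracle <- function(edges, labels) {
  m <- nrow(edges)
  li <- labels[edges[, 1]]
  lj <- labels[edges[, 2]]
  comms <- unique(c(li, lj))
  sum(vapply(comms, function(c) {
    e_cc <- sum(li == c & lj == c) / m
    a_c <- (sum(li == c) + sum(lj == c)) / (2 * m)
    e_cc - a_c^2
  }, 0))
}

test_that("modularity matches direct evaluation and known values", {
  set.seed(7)
  g <- clique_bridge_graph(3)
  ids <- g$joints$id
  # all joints in one community: e = 1, a^2 = 1
  one <- stats::setNames(rep(0L, 6), ids)
  expect_equal(graph_modularity(g, one), 0)
  # split at the bridge: 2 * (3/7 - (7/14)^2) = 5/14
  split2 <- stats::setNames(rep(0:1, each = 3), ids)
  expect_equal(graph_modularity(g, split2), 5 / 14)
  # singletons on a simple graph have no internal edges: Q < 0
  singl <- stats::setNames(seq_along(ids) - 1L, ids)
  expect_lt(graph_modularity(g, singl), 0)
  # agreement with the oracle on random labellings
  edges <- cbind(match(g$constraints$i, ids), match(g$constraints$j, ids))
  for (i in 1:20) {
    lab <- sample(0:2, length(ids), replace = TRUE)
    expect_equal(graph_modularity(g, stats::setNames(lab, ids)),
                 modularity_oracle(edges, lab))
  }
  expect_error(graph_modularity(joint_graph(g$joints), one),
               class = "jointpart_undefined")
})

test_that("CNM splits two bridged cliques at the bridge", {
  set.seed(11)
  g <- clique_bridge_graph(3)
  a <- detect_communities(g, "cnm")
  expect_s3_class(a, "community_assignment")
  expect_equal(length(unique(a$labels)), 2L)
  # the two cliques are the two communities
  expect_equal(length(unique(a$labels[1:3])), 1L)
  expect_equal(length(unique(a$labels[4:6])), 1L)
  expect_false(a$labels[[1]] == a$labels[[4]])
  # exhaustive search over all 2-labellings confirms CNM found the best
  ids <- g$joints$id
  best <- -Inf
  for (mask in 0:(2^6 - 1)) {
    lab <- as.integer(intToBits(mask)[1:6])
    q <- graph_modularity(g, stats::setNames(lab, ids))
    best <- max(best, q)
  }
  expect_equal(a$modularity, best)
  expect_equal(a$modularity, 5 / 14)
})

test_that("DBSCAN separates distant clouds and singles out noise", {
  pos <- rbind(
    cbind(seq(0, 4), 0, 0),
    cbind(seq(100, 104), 0, 0),
    c(50, 0, 0)  # isolated noise point
  )
  g <- joint_graph(data.frame(id = sprintf("p%02d", 1:11),
                              x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  a <- detect_communities(g, "dbscan", eps = 5, minpts = 2)
  expect_equal(length(unique(a$labels)), 3L)
  expect_equal(length(unique(a$labels[1:5])), 1L)
  expect_equal(length(unique(a$labels[6:10])), 1L)
  expect_equal(a$noise_policy, "singleton")
  # the noise point is alone in its community
  expect_equal(sum(a$labels == a$labels[[11]]), 1L)
  expect_error(detect_communities(g, "dbscan", eps = -1),
               class = "jointpart_invalid_parameter")
})

test_that("k-means is seeded, deterministic, and respects k", {
  g <- small_problem(60, 3, seed = 2, moved = FALSE)
  one <- detect_communities(g, "kmeans", k = 1)
  expect_equal(length(unique(one$labels)), 1L)
  a <- detect_communities(g, "kmeans", k = 3, seed = 10)
  b <- detect_communities(g, "kmeans", k = 3, seed = 10)
  expect_identical(a$labels, b$labels)
  expect_error(detect_communities(g, "kmeans", k = 10000),
               class = "jointpart_invalid_parameter")
  expect_error(detect_communities(g, "kmeans"),
               class = "jointpart_invalid_parameter")
})

test_that("split keeps a single community intact", {
  g <- small_problem(40, 2, seed = 3, moved = FALSE)
  lab <- stats::setNames(rep(0L, n_joints(g)), g$joints$id)
  ps <- split_graph(g, lab)
  expect_length(ps$partitions, 1L)
  p <- ps$partitions[[1]]
  expect_equal(sum(p$joints$virtual), 0L)
  expect_equal(nrow(p$constraints), n_constraints(g))
  expect_length(validate_partitions(ps), 0L)
})

test_that("a single cut edge produces twin virtual joints and cones", {
  g <- joint_graph(
    data.frame(id = c("a1", "a2", "b1", "b2"),
               x = c(0, 1, 10, 11), y = 0, z = 0),
    data.frame(kind = "A", i = c("a1", "a2", "b1"),
               j = c("a2", "b1", "b2"), dist = c(1, 9, 1))
  )
  lab <- c(a1 = 0L, a2 = 0L, b1 = 1L, b2 = 1L)
  ps <- split_graph(g, lab, cone_angle = 30)
  expect_length(ps$partitions, 2L)
  nvirt <- vapply(ps$partitions, function(p) sum(p$joints$virtual), 1L)
  expect_equal(unname(nvirt), c(1L, 1L))
  ncone <- vapply(ps$partitions,
                  function(p) sum(p$constraints$kind == "D"), 1L)
  expect_equal(unname(ncone), c(1L, 1L))
  # the cross constraint is gone from both partitions
  for (p in ps$partitions) {
    expect_false(any(p$constraints$kind == "A" &
                       ((p$constraints$i == "a2" & p$constraints$j == "b1") |
                          (p$constraints$i == "b1" & p$constraints$j == "a2"))))
  }
  # virtual joints are pinned at the twin's split-time position
  p1 <- ps$partitions[[1]]
  v <- p1$joints[p1$joints$virtual, ]
  expect_equal(v$twin, "b1")
  expect_equal(c(v$x, v$y, v$z), c(10, 0, 0))
  # cone radius comes from the split-time pair distance
  expect_equal(p1$constraints$cone_radius[p1$constraints$kind == "D"],
               cone_radius(9, 30))
  expect_length(validate_partitions(ps), 0L)
})

test_that("split conserves constraints and joints on random graphs", {
  set.seed(20)
  for (case in 1:100) {
    nc <- sample(30:80, 1)
    k <- sample(2:4, 1)
    g <- generate_problem(generator_spec(
      n_constraints = nc, n_communities = k, constraints_per_joint = 3,
      intra_fraction = 0.85, seed = 1000L + case))
    a <- detect_communities(g, "cnm")
    ps <- split_graph(g, a)
    expect_length(validate_partitions(ps), 0L)
    ids <- g$joints$id
    labels <- a$labels
    li <- labels[g$constraints$i]
    lj <- labels[g$constraints$j]
    n_cross <- sum(li != lj)
    intra_abc <- sum(vapply(ps$partitions, function(p) {
      sum(p$constraints$kind %in% c("A", "B", "C"))
    }, 1L))
    # conservation: intra + deleted cross = original count
    expect_equal(intra_abc + n_cross, n_constraints(g))
    # virtual joints = 2 x distinct cut pairs; one cone per virtual joint
    cut_pairs <- unique(paste(pmin(g$constraints$i, g$constraints$j),
                              pmax(g$constraints$i, g$constraints$j))[li != lj])
    n_virt <- sum(vapply(ps$partitions,
                         function(p) sum(p$joints$virtual), 1L))
    n_cone <- sum(vapply(ps$partitions,
                         function(p) sum(p$constraints$kind == "D"), 1L))
    expect_equal(n_virt, 2L * length(cut_pairs))
    expect_equal(n_cone, n_virt)
    # real-joint ownership is a partition of the joint set
    owned <- unlist(lapply(ps$partitions,
                           function(p) p$joints$id[!p$joints$virtual]))
    expect_setequal(owned, ids)
    expect_equal(anyDuplicated(owned), 0L)
  }
})

test_that("validate_partitions reports hand-built violations", {
  g <- small_problem(40, 2, seed = 4, moved = FALSE)
  a <- detect_communities(g, "cnm")
  ps <- split_graph(g, a)
  # shared real joint
  bad <- ps$partitions
  shared <- bad[[1]]$joints[1, ]
  bad[[2]]$joints <- rbind(bad[[2]]$joints, shared)
  expect_length(grep("owned by more than one", validate_partitions(bad)), 1L)
  # virtual joint inside an A constraint
  p <- ps$partitions[[1]]
  virt_id <- p$joints$id[p$joints$virtual][1]
  real_id <- p$joints$id[!p$joints$virtual][1]
  p$constraints <- rbind(
    p$constraints,
    data.frame(kind = "A", i = real_id, j = virt_id, dist = 1,
               dmax = NA_real_, theta = NA_real_, axis = NA_character_,
               cone_angle = NA_real_, cone_radius = NA_real_)
  )
  expect_length(grep("inside an A constraint",
                     validate_partitions(list(p))), 1L)
})

test_that("detection is deterministic for identical inputs", {
  g <- small_problem(80, 3, seed = 5, moved = FALSE)
  for (alg in list(list(algorithm = "cnm"),
                   list(algorithm = "dbscan", eps = 5),
                   list(algorithm = "kmeans", k = 3))) {
    a <- do.call(detect_communities, c(list(graph = g, seed = 77), alg))
    b <- do.call(detect_communities, c(list(graph = g, seed = 77), alg))
    expect_identical(a$labels, b$labels)
    expect_identical(a$modularity, b$modularity)
  }
})

test_that("CNM modularity is at least the single-community baseline", {
  for (seed in 1:5) {
    g <- small_problem(70, 3, seed = 100 + seed, moved = FALSE)
    a <- detect_communities(g, "cnm")
    expect_gte(a$modularity, 0)
  }
})
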