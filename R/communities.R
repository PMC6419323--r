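#' Detect joint communities
#'
#' Groups the joints of a constraint graph into communities that become
#' independent optimization sub-problems after [split_graph()]. Three
#' detectors are available:
#'
#' * `"cnm"` — Clauset-Newman-Moore agglomerative greedy modularity
#'   maximization on the constraint multigraph (every joint starts as its
#'   own community; the merge with the largest modularity gain is applied
#'   until no gain is positive). Parallel constraints between a pair count
#'   as edge weight.
#' * `"dbscan"` — density clustering of the joints' initial positions under
#'   Euclidean distance with radius `eps` and density threshold `minpts`
#'   (a point's eps-neighborhood, itself included, must reach `minpts` to be
#'   a core point). Noise points become singleton communities so that every
#'   joint is owned by a partition.
#' * `"kmeans"` — seeded Lloyd-style clustering of the initial positions
#'   into `k` clusters minimizing within-cluster sum of squares;
#'   deterministic given `seed`.
#'
#' The Newman modularity of the final labelling on the constraint graph is
#' always computed and recorded.
#'
#' @param graph a [joint_graph()] (non-empty).
#' @param algorithm `"cnm"`, `"dbscan"` or `"kmeans"`.
#' @param eps DBSCAN neighborhood radius (scene units, > 0).
#' @param minpts DBSCAN density threshold (>= 1; the reference protocol
#'   uses 2).
#' @param k number of k-means clusters (1..number of joints).
#' @param seed RNG seed for k-means restarts.
#' @return A `community_assignment`: list with `labels` (named integer
#'   vector, community indices contiguous from 0), `algorithm`, `params`,
#'   `modularity`, `noise_policy`, `seed`.
#' @examples
#' g <- joint_graph(
#'   data.frame(id = letters[1:4], x = c(0, 1, 10, 11), y = 0, z = 0),
#'   data.frame(kind = "A", i = c("a", "c"), j = c("b", "d"), dist = 1)
#' )
#' detect_communities(g, "dbscan", eps = 2, minpts = 2)$labels
#' @export
detect_communities <- function(graph, algorithm = c("cnm", "dbscan", "kmeans"),
                               eps = NULL, minpts = 2L, k = NULL, seed = 1L) {
  stopifnot(inherits(graph, "joint_graph"))
  algorithm <- match.arg(algorithm)
  if (n_joints(graph) == 0L) {
    jp_stop("graph has no joints", "jointpart_invalid_parameter")
  }
  ids <- graph$joints$id
  noise_policy <- NA_character_
  labels <- switch(
    algorithm,
    cnm = cnm_labels(graph),
    dbscan = {
      if (is.null(eps) || eps <= 0) {
        jp_stop("dbscan requires eps > 0", "jointpart_invalid_parameter")
      }
      if (minpts < 1) {
        jp_stop("dbscan requires minpts >= 1", "jointpart_invalid_parameter")
      }
      noise_policy <- "singleton"
      dbscan_labels(initial_positions(graph), eps, minpts)
    },
    kmeans = {
      if (is.null(k) || k < 1 || k > n_joints(graph)) {
        jp_stop("kmeans requires 1 <= k <= number of joints",
                "jointpart_invalid_parameter")
      }
      kmeans_labels(initial_positions(graph), as.integer(k), seed)
    }
  )
  labels <- relabel_contiguous(labels)
  names(labels) <- ids
  Q <- if (n_constraints(graph)) graph_modularity(graph, labels) else NA_real_
  structure(
    list(labels = labels, algorithm = algorithm,
         params = list(eps = eps, minpts = as.integer(minpts), k = k),
         modularity = Q, noise_policy = noise_policy, seed = seed),
    class = "community_assignment"
  )
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %s: %d joints in %d communities, Q=%.4f\n",
              x$algorithm, length(x$labels), length(unique(x$labels)),
              x$modularity))
  invisible(x)
}

# 0-based contiguous labels in order of first appearance
relabel_contiguous <- function(labels) {
  as.integer(match(labels, unique(labels)) - 1L)
}

# constraint multigraph as an igraph object with multiplicity weights
constraint_igraph <- function(graph) {
  ids <- graph$joints$id
  k <- graph$constraints
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(k)) {
    g <- igraph::add_edges(g, rbind(match(k$i, ids), match(k$j, ids)))
    g <- igraph::simplify(g, edge.attr.comb = list())
    # weight = number of parallel constraints collapsed into each edge
    el <- igraph::as_edgelist(g, names = FALSE)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    mi <- match(k$i, ids); mj <- match(k$j, ids)
    mult <- table(paste(pmin(mi, mj), pmax(mi, mj)))
    g <- igraph::set_edge_attr(g, "weight", value = as.numeric(mult[key]))
  }
  g
}

cnm_labels <- function(graph) {
  if (n_constraints(graph) == 0L) {
    jp_stop("CNM needs a non-empty constraint set", "jointpart_invalid_parameter")
  }
  g <- constraint_igraph(graph)
  fc <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  as.integer(igraph::membership(fc)) - 1L
}

dbscan_labels <- function(P, eps, minpts) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= minpts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    # grow a cluster from core point i by breadth-first expansion
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      if (is.na(labels[q])) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nbrs[[q]])
      }
    }
    cl <- cl + 1L
  }
  # noise points (never reached from a core point) become singletons
  for (i in which(is.na(labels))) {
    labels[i] <- cl
    cl <- cl + 1L
  }
  labels
}

kmeans_labels <- function(P, k, seed) {
  if (k == 1L) return(rep(0L, nrow(P)))
  if (k == nrow(P)) return(seq_len(nrow(P)) - 1L)
  km <- with_seed(seed, stats::kmeans(P, centers = k, nstart = 10L,
                                      iter.max = 100L))
  as.integer(km$cluster) - 1L
}

#' Newman modularity of a joint labelling
#'
#' `Q = sum_c (e_cc - a_c^2)` over communities, where `e_cc` is the fraction
#' of constraint edges with both endpoints in community `c` and `a_c` the
#' fraction of edge endpoints in `c`. Parallel constraints between the same
#' joint pair are counted as separate edges. `Q` lies in `[-0.5, 1]`;
#' values above 0.3 are conventionally read as significant community
#' structure.
#'
#' @param graph a [joint_graph()] with at least one constraint.
#' @param labels community labels covering all joints: either a named
#'   vector or a vector in joint order, or a `community_assignment`.
#' @return scalar modularity Q.
#' @export
graph_modularity <- function(graph, labels) {
  stopifnot(inherits(graph, "joint_graph"))
  if (inherits(labels, "community_assignment")) labels <- labels$labels
  if (n_constraints(graph) == 0L) {
    jp_stop("modularity is undefined on an empty edge set",
            "jointpart_undefined")
  }
  ids <- graph$joints$id
  if (!is.null(names(labels))) {
    labels <- labels[ids]
    if (anyNA(labels)) {
      jp_stop("labels must cover all joints", "jointpart_invalid_input")
    }
  } else if (length(labels) != length(ids)) {
    jp_stop("labels must cover all joints", "jointpart_invalid_input")
  }
  k <- graph$constraints
  li <- labels[match(k$i, ids)]
  lj <- labels[match(k$j, ids)]
  m <- nrow(k)
  comms <- unique(c(li, lj))
  e_cc <- vapply(comms, function(c) sum(li == c & lj == c) / m, 0)
  a_c <- vapply(comms, function(c) (sum(li == c) + sum(lj == c)) / (2 * m), 0)
  sum(e_cc - a_c^2)
}
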