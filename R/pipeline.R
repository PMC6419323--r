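#' Solve a joint graph without partitioning
#'
#' Convenience wrapper: [assemble_program()] on the whole graph followed by
#' [solve_single()].
#'
#' @param graph a [joint_graph()].
#' @param options a [solver_options()] list.
#' @param tau equality relaxation / feasibility tolerance.
#' @return a `solve_result` covering every real joint of the graph.
#' @export
solve_graph <- function(graph, options = solver_options(), tau = 1e-6) {
  solve_single(assemble_program(graph, tau = tau), options = options)
}

#' Partitioned solve of a joint graph
#'
#' The full partition pipeline: [detect_communities()], [split_graph()],
#' then [assemble_program()] + [solve_single()] on every partition, and a
#' final [merge_solutions()]. Partitions are independent sub-problems, so
#' the merged result does not depend on the order in which they are solved;
#' per-partition non-convergence is propagated as a flag, never an error.
#'
#' @inheritParams detect_communities
#' @param cone_angle cone aperture preset for the cut constraints, degrees.
#' @param options a [solver_options()] list.
#' @param tau equality relaxation / feasibility tolerance.
#' @param assignment optional precomputed `community_assignment` (skips
#'   detection).
#' @return a `solve_result` whose `positions` cover all real joints;
#'   `$partitions` carries the `partition_set`, per-partition results and
#'   the community assignment.
#' @export
solve_partitioned <- function(graph, algorithm = c("cnm", "dbscan", "kmeans"),
                              eps = NULL, minpts = 2L, k = NULL, seed = 1L,
                              cone_angle = 30, options = solver_options(),
                              tau = 1e-6, assignment = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(assignment)) {
    assignment <- detect_communities(graph, algorithm, eps = eps,
                                     minpts = minpts, k = k, seed = seed)
  }
  pset <- split_graph(graph, assignment, cone_angle = cone_angle)
  results <- lapply(pset$partitions, function(p) {
    solve_single(assemble_program(p, tau = tau), options = options)
  })
  pos <- merge_solutions(results, pset)
  structure(
    list(positions = pos,
         objective_value = sum(vapply(results, `[[`, 0, "objective_value")),
         max_violation = max(vapply(results, `[[`, 0, "max_violation")),
         n_function_evals = sum(vapply(results, `[[`, 0L,
                                       "n_function_evals")),
         n_iterations = sum(vapply(results, `[[`, 0L, "n_iterations")),
         wall_time = proc.time()[["elapsed"]] - t0,
         converged = all(vapply(results, `[[`, TRUE, "converged")),
         partitions = list(assignment = assignment, set = pset,
                           results = results)),
    class = "solve_result"
  )
}

#' Merge per-partition solve results
#'
#' Each real joint takes the solved position of its owning partition;
#' virtual joints are discarded. Duplicate ownership is an error.
#'
#' @param results list of `solve_result`, one per partition.
#' @param partitions the matching `partition_set` (or list of partitions).
#' @return position matrix covering all real joints.
#' @export
merge_solutions <- function(results, partitions) {
  if (inherits(partitions, "partition_set")) {
    partitions <- partitions$partitions
  }
  stopifnot(length(results) == length(partitions))
  pieces <- mapply(function(res, part) {
    own <- part$joints$id[!part$joints$virtual]
    res$positions[own, , drop = FALSE]
  }, results, partitions, SIMPLIFY = FALSE)
  ids <- unlist(lapply(pieces, rownames))
  if (anyDuplicated(ids)) {
    jp_stop(sprintf("joint '%s' owned by more than one partition",
                    ids[duplicated(ids)][1L]), "jointpart_invalid_partition")
  }
  do.call(rbind, pieces)
}
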