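#' Split a joint graph into partitions along community boundaries
#'
#' Turns a community assignment into disjoint optimization sub-problems:
#' constraints whose endpoints share a community are copied into that
#' community's partition unchanged; every cross-community constraint is
#' deleted and replaced, on each side of the cut, by a pinned virtual twin
#' of the removed neighbor plus one cone constraint (set D) of aperture
#' `cone_angle` tying the remaining real joint to that anchor. The cone
#' radius is [cone_radius()] evaluated at the pair's distance at split time,
#' so the cone surface passes exactly through the pre-split configuration.
#' One virtual joint and one cone constraint are inserted per distinct
#' (real joint, removed neighbor) pair, regardless of how many parallel
#' constraints the cut deleted.
#'
#' @param graph a [joint_graph()] without virtual joints.
#' @param assignment a `community_assignment` from [detect_communities()],
#'   or a named label vector covering the graph.
#' @param cone_angle cone aperture preset in degrees (default 30).
#' @return A `partition_set`: list of `partition` objects (each a
#'   `joint_graph` whose `metadata` records `partition_index` and the owned
#'   real joint ids) plus the assignment and cone angle.
#' @export
split_graph <- function(graph, assignment, cone_angle = 30) {
  stopifnot(inherits(graph, "joint_graph"))
  labels <- if (inherits(assignment, "community_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  ids <- graph$joints$id
  if (is.null(names(labels))) names(labels) <- ids
  labels <- labels[ids]
  if (anyNA(labels)) {
    jp_stop("assignment must cover all joints", "jointpart_invalid_input")
  }
  if (any(graph$joints$virtual)) {
    jp_stop("cannot split a graph that already contains virtual joints",
            "jointpart_invalid_model")
  }
  if (cone_angle <= 0 || cone_angle >= 180) {
    jp_stop("cone_angle must be in (0, 180)", "jointpart_invalid_parameter")
  }
  comms <- sort(unique(as.integer(labels)))
  k <- graph$constraints
  li <- as.integer(labels[k$i])
  lj <- as.integer(labels[k$j])
  cross <- li != lj
  P <- positions(graph)

  # distinct directed cut pairs: (kept real joint, removed neighbor)
  cut <- unique(data.frame(
    real = c(k$i[cross], k$j[cross]),
    gone = c(k$j[cross], k$i[cross]),
    stringsAsFactors = FALSE
  ))

  partitions <- lapply(comms, function(t) {
    own <- ids[labels == t]
    jt <- graph$joints[match(own, ids), , drop = FALSE]
    kt <- k[!cross & li == t, , drop = FALSE]
    ct <- cut[cut$real %in% own, , drop = FALSE]
    if (nrow(ct)) {
      vids <- sprintf(".v|%s|%s", ct$gone, ct$real)
      vpos <- P[ct$gone, , drop = FALSE]
      d0 <- sqrt(rowSums((P[ct$real, , drop = FALSE] - vpos)^2))
      if (any(d0 == 0)) {
        jp_stop("cut pair with coincident joints: cone radius undefined",
                "jointpart_degenerate_geometry")
      }
      vjoints <- data.frame(
        id = vids, x = vpos[, 1], y = vpos[, 2], z = vpos[, 3],
        x0 = vpos[, 1], y0 = vpos[, 2], z0 = vpos[, 3],
        stiffness = graph$joints$stiffness[match(ct$gone, ids)],
        dx = NA_real_, dy = NA_real_, dz = NA_real_,
        virtual = TRUE, twin = ct$gone, mesh = NA_character_,
        stringsAsFactors = FALSE
      )
      dcons <- data.frame(
        kind = "D", i = ct$real, j = vids,
        dist = NA_real_, dmax = NA_real_, theta = NA_real_,
        axis = NA_character_,
        cone_angle = cone_angle, cone_radius = cone_radius(d0, cone_angle),
        stringsAsFactors = FALSE
      )
      jt <- rbind(jt, vjoints)
      kt <- rbind(kt, dcons)
    }
    p <- joint_graph(jt, kt,
                     metadata = list(partition_index = t, owned = own))
    class(p) <- c("partition", class(p))
    p
  })
  structure(
    list(partitions = partitions, assignment = assignment,
         cone_angle = cone_angle),
    class = "partition_set"
  )
}

#' @export
print.partition_set <- function(x, ...) {
  nj <- vapply(x$partitions, function(p) sum(!p$joints$virtual), 1L)
  nv <- vapply(x$partitions, function(p) sum(p$joints$virtual), 1L)
  cat(sprintf("<partition_set> %d partitions (cone %g deg)\n",
              length(x$partitions), x$cone_angle))
  cat(sprintf("  real joints: %s\n  virtual:     %s\n",
              paste(nj, collapse = " "), paste(nv, collapse = " ")))
  invisible(x)
}

#' Validate partition invariants
#'
#' Checks the structural invariants every output of [split_graph()] must
#' satisfy: real-joint sets of distinct partitions are disjoint, every
#' virtual joint names a twin owned by a different partition, virtual joints
#' appear in no A/B/C constraint, and every D constraint ties one real joint
#' to one virtual joint. Violations are reported, not raised.
#'
#' @param partitions a `partition_set` or plain list of `partition` objects.
#' @return character vector of violation messages (empty when valid).
#' @export
validate_partitions <- function(partitions) {
  if (inherits(partitions, "partition_set")) {
    partitions <- partitions$partitions
  }
  out <- character()
  real_sets <- lapply(partitions, function(p) p$joints$id[!p$joints$virtual])
  all_real <- unlist(real_sets)
  dup <- unique(all_real[duplicated(all_real)])
  if (length(dup)) {
    out <- c(out, sprintf("real joint '%s' owned by more than one partition",
                          dup))
  }
  for (t in seq_along(partitions)) {
    p <- partitions[[t]]
    virt <- p$joints$id[p$joints$virtual]
    twins <- p$joints$twin[p$joints$virtual]
    owned_here <- real_sets[[t]]
    bad_twin <- virt[twins %in% owned_here]
    if (length(bad_twin)) {
      out <- c(out, sprintf(
        "partition %d: virtual joint '%s' twins a joint owned by the same partition",
        t, bad_twin))
    }
    lost <- virt[!(twins %in% all_real)]
    if (length(lost)) {
      out <- c(out, sprintf(
        "partition %d: virtual joint '%s' twins a joint owned by no partition",
        t, lost))
    }
    k <- p$constraints
    abc <- k$kind %in% c("A", "B", "C")
    bad <- abc & (k$i %in% virt | k$j %in% virt)
    if (any(bad)) {
      out <- c(out, sprintf(
        "partition %d: virtual joint inside an %s constraint (%s-%s)",
        t, k$kind[bad], k$i[bad], k$j[bad]))
    }
    isD <- k$kind == "D"
    badD <- isD & !((k$i %in% owned_here) & (k$j %in% virt))
    if (any(badD)) {
      out <- c(out, sprintf(
        "partition %d: D constraint must tie a real joint to a virtual joint (%s-%s)",
        t, k$i[badD], k$j[badD]))
    }
  }
  out
}
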