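# Vectorized residual-row evaluation shared by evaluate_all() and the
# solver. Rows are in "model convention": eq rows satisfied iff 0, ineq
# rows satisfied iff <= 0.

# Precompute index structures for all scalar residual rows of a graph.
constraint_row_structure <- function(graph) {
  k <- graph$constraints
  ids <- graph$joints$id
  n <- nrow(k)
  if (n == 0L) {
    return(list(
      n_rows = 0L,
      bookkeeping = data.frame(constraint = integer(), kind = character(),
                               type = character(), side = character()),
      kinds = list()
    ))
  }
  i_idx <- match(k$i, ids)
  j_idx <- match(k$j, ids)
  rows_per <- ifelse(k$kind == "A", 1L,
              ifelse(k$kind == "B", 1L + !is.na(k$axis),
              ifelse(k$kind == "C", 2L, 1L)))
  row_start <- cumsum(c(0L, rows_per[-n])) + 1L
  n_rows <- sum(rows_per)

  bk_constraint <- integer(n_rows); bk_type <- character(n_rows)
  bk_side <- character(n_rows)
  kinds <- list()

  sel <- which(k$kind == "A")
  if (length(sel)) {
    r <- row_start[sel]
    kinds$A <- list(rows = r, i = i_idx[sel], j = j_idx[sel], dist = k$dist[sel])
    bk_constraint[r] <- sel; bk_type[r] <- "eq"; bk_side[r] <- "dist"
  }
  sel <- which(k$kind == "B")
  if (length(sel)) {
    r <- row_start[sel]
    ax <- match(k$axis[sel], c("x", "y", "z"))  # NA when no lock
    kinds$B <- list(rows = r, i = i_idx[sel], j = j_idx[sel],
                    theta = k$theta[sel], axis = ax,
                    axis_rows = ifelse(is.na(ax), NA_integer_, r + 1L))
    bk_constraint[r] <- sel; bk_type[r] <- "ineq"; bk_side[r] <- "angle"
    ar <- kinds$B$axis_rows[!is.na(ax)]
    if (length(ar)) {
      bk_constraint[ar] <- sel[!is.na(ax)]
      bk_type[ar] <- "eq"; bk_side[ar] <- "axis"
    }
  }
  sel <- which(k$kind == "C")
  if (length(sel)) {
    r <- row_start[sel]
    kinds$C <- list(rows = r, i = i_idx[sel], j = j_idx[sel],
                    dist = k$dist[sel], dmax = k$dmax[sel])
    bk_constraint[r] <- sel; bk_type[r] <- "ineq"; bk_side[r] <- "lower"
    bk_constraint[r + 1L] <- sel; bk_type[r + 1L] <- "ineq"
    bk_side[r + 1L] <- "upper"
  }
  sel <- which(k$kind == "D")
  if (length(sel)) {
    r <- row_start[sel]
    kinds$D <- list(rows = r, i = i_idx[sel], j = j_idx[sel],
                    a = k$cone_angle[sel], radius = k$cone_radius[sel])
    bk_constraint[r] <- sel; bk_type[r] <- "ineq"; bk_side[r] <- "cone"
  }
  list(
    n_rows = n_rows,
    bookkeeping = data.frame(constraint = bk_constraint,
                             kind = k$kind[bk_constraint],
                             type = bk_type, side = bk_side,
                             stringsAsFactors = FALSE),
    kinds = kinds
  )
}

# Evaluate all residual rows at positions P (n_joints x 3, graph row order).
# P0 is the matrix of initial positions (used by angle rows and as the cone
# direction reference). Degenerate angle directions are scored at 180 deg so
# the solver steers away instead of crashing.
eval_residual_rows <- function(struct, P, P0) {
  res <- numeric(struct$n_rows)
  ks <- struct$kinds
  if (!is.null(ks$A)) {
    dvec <- P[ks$A$i, , drop = FALSE] - P[ks$A$j, , drop = FALSE]
    res[ks$A$rows] <- ks$A$dist - sqrt(rowSums(dvec * dvec))
  }
  if (!is.null(ks$B)) {
    u <- P0[ks$B$i, , drop = FALSE] - P[ks$B$j, , drop = FALSE]
    v <- P[ks$B$i, , drop = FALSE] - P[ks$B$j, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    den <- nu * nv
    cosang <- ifelse(den < 1e-300, -1, pmin(1, pmax(-1, rowSums(u * v) / den)))
    res[ks$B$rows] <- rad2deg(acos(cosang)) - ks$B$theta
    has_ax <- which(!is.na(ks$B$axis))
    if (length(has_ax)) {
      ax <- ks$B$axis[has_ax]
      pick <- cbind(seq_len(nrow(u))[has_ax], ax)
      res[ks$B$axis_rows[has_ax]] <- u[pick] - v[pick]
    }
  }
  if (!is.null(ks$C)) {
    dvec <- P[ks$C$i, , drop = FALSE] - P[ks$C$j, , drop = FALSE]
    d <- sqrt(rowSums(dvec * dvec))
    res[ks$C$rows] <- ks$C$dist - ks$C$dmax - d
    res[ks$C$rows + 1L] <- d - ks$C$dist - ks$C$dmax
  }
  if (!is.null(ks$D)) {
    pi_ <- P[ks$D$i, , drop = FALSE]
    v <- P[ks$D$j, , drop = FALSE]          # pinned virtual position
    ref <- P0[ks$D$j, , drop = FALSE]       # pre-split neighbor direction
    dv <- v - pi_
    d <- sqrt(rowSums(dv * dv))
    s <- rowSums((ref - pi_) * dv)
    sgn <- ifelse(s < 0, -1, 1)
    ang <- ifelse(d < 1e-300, 90, rad2deg(atan(ks$D$radius / d)))
    res[ks$D$rows] <- 2 * sgn * ang - ks$D$a
  }
  res
}

#' Evaluate every constraint of a joint graph
#'
#' Dispatches each constraint to its residual and classifies it as satisfied
#' or violated under tolerance `tol`: equality rows require `|residual| <=
#' tol`, inequality rows require `residual <= tol`.
#'
#' @param graph a [joint_graph()].
#' @param positions optional named position matrix / named list of 3-vectors
#'   overriding the graph's current positions (ids not mentioned keep their
#'   stored position).
#' @param tol satisfaction tolerance in scene units (default `1e-6`).
#' @return A `feasibility_report`: list with `rows` (one data frame row per
#'   scalar residual: `constraint`, `kind`, `type`, `side`, `residual`,
#'   `satisfied`), `max_equality_violation`, `max_inequality_violation`,
#'   `n_violations` and `tol`.
#' @export
evaluate_all <- function(graph, positions = NULL, tol = 1e-6) {
  stopifnot(inherits(graph, "joint_graph"))
  if (!is.null(positions)) graph <- set_positions(graph, positions)
  struct <- constraint_row_structure(graph)
  P <- positions(graph)
  P0 <- initial_positions(graph)
  res <- eval_residual_rows(struct, P, P0)
  check_finite(res, "constraint residuals")
  rows <- struct$bookkeeping
  rows$residual <- res
  rows$satisfied <- ifelse(rows$type == "eq", abs(res) <= tol, res <= tol)
  eq <- rows$type == "eq"
  structure(
    list(
      rows = rows,
      max_equality_violation = if (any(eq)) max(abs(res[eq])) else 0,
      max_inequality_violation = if (any(!eq)) max(0, res[!eq]) else 0,
      n_violations = sum(!rows$satisfied),
      tol = tol
    ),
    class = "feasibility_report"
  )
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf(
    "<feasibility_report> %d residual rows, %d violated (tol=%.1g)\n",
    nrow(x$rows), x$n_violations, x$tol))
  cat(sprintf("  max |equality|: %.3g   max inequality: %.3g\n",
              x$max_equality_violation, x$max_inequality_violation))
  invisible(x)
}
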