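#' Assemble the optimization program for a graph or partition
#'
#' Builds the nonlinear program solved by [solve_single()]: variables are
#' the flattened current positions of the partition's real joints (virtual
#' joints are pinned constants and contribute no variables); the objective
#' is `sum_l k_l * |p_l - p_dest,l|` over joints carrying a destination
#' (joints with no prescribed motion are dropped from the objective); every
#' constraint row is converted to the solver convention `g(x) >= 0`:
#' equality rows `e` become the pair `e + tau >= 0`, `tau - e >= 0`, and
#' strict-inequality rows `s < 0` become `-s >= 0` (the measure-zero
#' boundary distinction is irrelevant to a numeric solver).
#'
#' @param graph a [joint_graph()] or `partition`.
#' @param tau equality relaxation half-width in scene units (default
#'   `1e-6`); also the feasibility tolerance used by diagnostics.
#' @return An `optimization_program`: list with `ids` (variable joint ids),
#'   `x0`, `n_var`, `eval_f(x)` returning `list(fterms, g)` (per-joint
#'   objective terms and solver-convention constraint rows), `bookkeeping`
#'   mapping each `g` row back to its source constraint, `row_joints`
#'   (which variable joints each output row touches, for structured finite
#'   differences) and the source `graph`.
#' @export
assemble_program <- function(graph, tau = 1e-6) {
  stopifnot(inherits(graph, "joint_graph"))
  j <- graph$joints
  if (any(j$virtual & !is.na(j$dx))) {
    jp_stop("virtual joints cannot carry a destination",
            "jointpart_invalid_model")
  }
  free <- which(!j$virtual)
  ids <- j$id[free]
  n_var <- 3L * length(free)
  Pbase <- positions(graph)
  P0 <- initial_positions(graph)
  x0 <- as.numeric(t(Pbase[free, , drop = FALSE]))

  struct <- constraint_row_structure(graph)
  bk <- struct$bookkeeping
  # solver rows: eq rows expand to two, ineq rows to one (negated)
  n_model <- struct$n_rows
  eq <- bk$type == "eq"
  g_per <- ifelse(eq, 2L, 1L)
  g_start <- cumsum(c(0L, g_per[-length(g_per)])) + 1L
  if (n_model == 0L) g_start <- integer()
  n_g <- sum(g_per)
  g_book <- data.frame(
    row = seq_len(n_g),
    constraint = rep(bk$constraint, g_per),
    kind = rep(bk$kind, g_per),
    type = rep(bk$type, g_per),
    side = rep(bk$side, g_per),
    stringsAsFactors = FALSE
  )

  obj_joints <- free[!is.na(j$dx[free])]
  obj_local <- match(obj_joints, free)      # local variable-joint index
  obj_k <- j$stiffness[obj_joints]
  obj_dest <- as.matrix(j[obj_joints, c("dx", "dy", "dz"), drop = FALSE])

  free_map <- integer(nrow(j)); free_map[free] <- seq_along(free)

  eval_f <- function(x) {
    P <- Pbase
    P[free, ] <- matrix(x, ncol = 3L, byrow = TRUE)
    res <- eval_residual_rows(struct, P, P0)
    g <- numeric(n_g)
    if (n_model) {
      g[g_start[eq] ] <- res[eq] + tau
      g[g_start[eq] + 1L] <- tau - res[eq]
      g[g_start[!eq]] <- -res[!eq]
    }
    fterms <- if (length(obj_joints)) {
      dv <- P[obj_joints, , drop = FALSE] - obj_dest
      unname(obj_k * sqrt(rowSums(dv * dv)))
    } else {
      numeric()
    }
    list(fterms = fterms, g = g)
  }

  # variable-joint dependencies of each output row (fterms first, then g)
  row_joints_model <- lapply(seq_len(n_model), function(r) {
    ci <- bk$constraint[r]
    ep <- c(graph$constraints$i[ci], graph$constraints$j[ci])
    loc <- free_map[match(ep, j$id)]
    loc[loc > 0L]
  })
  g_row_joints <- rep(row_joints_model, g_per)
  f_row_joints <- as.list(obj_local)

  structure(
    list(ids = ids, x0 = x0, n_var = n_var,
         n_f = length(obj_joints), n_g = n_g,
         eval_f = eval_f, bookkeeping = g_book,
         row_joints = c(f_row_joints, g_row_joints),
         # g-row indices of the e + tau member of each equality pair, and
         # of the single -s row of each strict inequality
         eq_g = g_start[eq], ineq_g = g_start[!eq],
         tau = tau, graph = graph, free = free),
    class = "optimization_program"
  )
}

#' @export
print.optimization_program <- function(x, ...) {
  cat(sprintf(
    "<optimization_program> %d variables (%d joints), %d objective terms, %d inequality rows\n",
    x$n_var, length(x$ids), x$n_f, x$n_g))
  invisible(x)
}
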