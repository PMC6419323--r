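#' Solver options
#'
#' Options for the derivative-free trust-region solver of [solve_single()].
#' Defaults are scale-aware: `rhobeg` (initial trust radius) defaults to
#' 0.1 times the mean rest length of the program's A/C constraints (0.5
#' when there are none), `maxfun` to 100 function evaluations per variable.
#'
#' @param rhobeg initial trust-region radius (scene units), `NULL` for the
#'   scale-aware default.
#' @param rhoend final trust-region radius / convergence threshold.
#' @param maxfun cap on full constraint-vector evaluations, `NULL` for
#'   `100 * n_var`.
#' @param fd_step forward-difference step for the linear models.
#' @param mu0 initial merit penalty weight, `NULL` for an automatic choice.
#' @param mu_max penalty weight cap.
#' @param subproblem_maxit pass cap for the active-set subproblem.
#' @param verbose print a per-iteration trace line.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(rhobeg = NULL, rhoend = 1e-6, maxfun = NULL,
                           fd_step = 1e-6, mu0 = NULL, mu_max = 1e8,
                           subproblem_maxit = 10L, verbose = FALSE) {
  structure(list(rhobeg = rhobeg, rhoend = rhoend, maxfun = maxfun,
                 fd_step = fd_step, mu0 = mu0, mu_max = mu_max,
                 subproblem_maxit = as.integer(subproblem_maxit),
                 verbose = isTRUE(verbose)),
            class = "solver_options")
}

# greedy coloring of the variable-joint conflict graph so that joints in a
# color class never share a constraint row; a color class can then be
# finite-differenced in one evaluation per coordinate
fd_coloring <- function(program) {
  nj <- length(program$ids)
  adj <- vector("list", nj)
  for (dep in program$row_joints) {
    if (length(dep) == 2L) {
      adj[[dep[1L]]] <- c(adj[[dep[1L]]], dep[2L])
      adj[[dep[2L]]] <- c(adj[[dep[2L]]], dep[1L])
    }
  }
  adj <- lapply(adj, unique)
  deg <- vapply(adj, length, 1L)
  color <- integer(nj)
  for (v in order(deg, decreasing = TRUE)) {
    used <- color[adj[[v]]]
    c_try <- 1L
    while (c_try %in% used) c_try <- c_try + 1L
    color[v] <- c_try
  }
  split(seq_len(nj), color)
}

# fixed sparsity pattern of the Jacobian of c(fterms, g): one triplet per
# (output row, variable) pair, laid out in the order fd_jacobian() fills it
fd_pattern <- function(program, groups, rows_of_joint) {
  ii <- vector("list", 0L); jj <- vector("list", 0L)
  by_gc <- vector("list", length(groups))
  pos <- 0L
  for (gi in seq_along(groups)) {
    by_gc[[gi]] <- vector("list", 3L)
    for (coord in 1:3) {
      rows <- unlist(rows_of_joint[groups[[gi]]], use.names = FALSE)
      cols <- rep.int((groups[[gi]] - 1L) * 3L + coord,
                      lengths(rows_of_joint[groups[[gi]]]))
      ii[[length(ii) + 1L]] <- rows
      jj[[length(jj) + 1L]] <- cols
      by_gc[[gi]][[coord]] <- list(at = pos + seq_along(rows), rows = rows)
      pos <- pos + length(rows)
    }
  }
  list(ii = unlist(ii, use.names = FALSE), jj = unlist(jj, use.names = FALSE),
       by_gc = by_gc, nnz = pos)
}

# forward-difference sparse Jacobian using the coloring groups
fd_jacobian <- function(program, x, F0, groups, pattern, h) {
  vals <- numeric(pattern$nnz)
  nev <- 0L
  for (gi in seq_along(groups)) {
    for (coord in 1:3) {
      vars <- (groups[[gi]] - 1L) * 3L + coord
      xp <- x
      xp[vars] <- xp[vars] + h
      Fp <- program$eval_f(xp)
      Fp <- c(Fp$fterms, Fp$g)
      nev <- nev + 1L
      sl <- pattern$by_gc[[gi]][[coord]]
      vals[sl$at] <- (Fp[sl$rows] - F0[sl$rows]) / h
    }
  }
  m <- program$n_f + program$n_g
  J <- Matrix::sparseMatrix(i = pattern$ii, j = pattern$jj, x = vals,
                            dims = c(m, program$n_var))
  list(J = J, nev = nev)
}

#' Solve a single optimization program
#'
#' Derivative-free constrained minimization in the COBYLA spirit: linear
#' models of the objective and every constraint row are built from
#' structured forward differences (no user derivatives), a trust-region
#' step is computed against those models under an L1 exact-penalty merit
#' function, and the trust radius shrinks from `rhobeg` to `rhoend`.
#' Deterministic for fixed inputs and options. Runs from the program's
#' initial positions and returns the best accepted point; exhaustion of
#' `maxfun` returns `converged = FALSE`, never an error.
#'
#' @param program an [assemble_program()] result.
#' @param options a [solver_options()] list.
#' @return A `solve_result`: list with `positions` (matrix, one row per
#'   real joint of the program), `objective_value`, `max_violation` (from
#'   [evaluate_all()] at the solved positions), `n_function_evals`,
#'   `n_iterations`, `wall_time` (seconds, reporting only) and `converged`.
#' @export
solve_single <- function(program, options = solver_options()) {
  stopifnot(inherits(program, "optimization_program"))
  t0 <- proc.time()[["elapsed"]]
  n <- program$n_var
  tau <- program$tau
  opt <- options
  if (is.null(opt$rhobeg)) {
    k <- program$graph$constraints
    rest <- k$dist[k$kind %in% c("A", "C")]
    opt$rhobeg <- if (length(rest) && mean(rest) > 0) 0.1 * mean(rest) else 0.5
  }
  if (is.null(opt$maxfun)) opt$maxfun <- 100L * max(1L, n)

  finish <- function(x, nev, nit, converged) {
    P <- matrix(x, ncol = 3L, byrow = TRUE,
                dimnames = list(program$ids, c("x", "y", "z")))
    Fx <- program$eval_f(x)
    rep <- evaluate_all(program$graph, positions = P, tol = tau)
    structure(
      list(positions = P, objective_value = sum(Fx$fterms),
           max_violation = max(rep$max_equality_violation,
                               rep$max_inequality_violation),
           n_function_evals = nev, n_iterations = nit,
           wall_time = proc.time()[["elapsed"]] - t0, converged = converged),
      class = "solve_result"
    )
  }

  if (n == 0L) return(finish(numeric(), 0L, 0L, TRUE))

  x <- program$x0
  F0l <- program$eval_f(x)
  F0 <- c(F0l$fterms, F0l$g)
  nev <- 1L
  nf <- program$n_f
  f_rows <- seq_len(nf)
  g_rows <- nf + seq_len(program$n_g)
  viol <- function(g) sum(pmax(0, -g))
  f_cur <- sum(F0[f_rows])
  v_cur <- viol(F0[g_rows])

  groups <- fd_coloring(program)
  rows_of_joint <- vector("list", length(program$ids))
  for (r in seq_along(program$row_joints)) {
    for (jt in program$row_joints[[r]]) {
      rows_of_joint[[jt]] <- c(rows_of_joint[[jt]], r)
    }
  }
  pattern <- fd_pattern(program, groups, rows_of_joint)

  mu_merit <- opt$mu0 %||% 10
  delta <- opt$rhobeg
  nit <- 0L
  stall <- 0L
  need_jac <- TRUE
  gf <- NULL; Jg <- NULL; g0 <- NULL
  converged <- FALSE

  while (nev < opt$maxfun) {
    nit <- nit + 1L
    if (need_jac) {
      fd <- fd_jacobian(program, x, F0, groups, pattern, opt$fd_step)
      nev <- nev + fd$nev
      need_jac <- FALSE
      gf <- if (nf) {
        as.numeric(Matrix::colSums(fd$J[f_rows, , drop = FALSE]))
      } else {
        numeric(n)
      }
      Jg <- fd$J[g_rows, , drop = FALSE]
      g0 <- F0[g_rows]
      if (max(abs(gf)) < 1e-14 && viol(g0) <= 1e-12) {
        # feasible stationary start (e.g. zero motion): nothing to do
        converged <- TRUE
        break
      }
      mu_merit <- max(mu_merit, opt$mu0 %||% (10 * max(1, max(abs(gf)))))
      if (nev >= opt$maxfun) break
    }

    # trust-region subproblem on the linear models: a projected-gradient /
    # Newton KKT step. Equality rows are always pinned; inequality rows
    # enter the working set when violated or at their boundary, and leave
    # it when their multiplier takes the wrong sign. The regularized system
    #   min  gf.d + |d|^2 / (2 lambda)   s.t.  M d = b
    # has the closed form d = lambda (M' y - gf) with
    # (lambda M M' + eps I) y = b + lambda M gf, one sparse Cholesky per
    # pass. The true functions are never differentiated: M comes from the
    # forward-difference models.
    vm0 <- viol(g0)
    model_pred <- function(d) {
      mu_merit * vm0 - (sum(gf * d) +
                          mu_merit * viol(g0 + as.numeric(Jg %*% d)))
    }
    e_idx <- program$eq_g          # g rows e + tau of each equality
    s_idx <- program$ineq_g        # g rows -s of each strict inequality
    e0 <- g0[e_idx] - tau
    s0 <- -g0[s_idx]
    y_abs_max <- 0
    solve_kkt <- function(lambda) {
      act <- which(s0 >= -1e-12)   # violated or at the boundary
      d <- rep(0, n)
      for (pass in seq_len(max(2L, opt$subproblem_maxit))) {
        keep <- c(e_idx, s_idx[act])
        if (length(keep) == 0L) return(-lambda * gf)
        M <- Jg[keep, , drop = FALSE]
        # drive pinned rows to their boundary: g_lin = g0 + M d -> target
        # (0 for equalities means e -> 0, i.e. g -> tau)
        b <- c(-e0, pmax(0, s0[act]))
        K <- lambda * Matrix::tcrossprod(M)
        dg <- Matrix::diag(K)
        Matrix::diag(K) <- dg + max(1e-12, 1e-10 * max(dg, 0))
        y <- tryCatch(
          as.numeric(Matrix::solve(K, b + lambda * as.numeric(M %*% gf))),
          error = function(e) NULL
        )
        if (is.null(y)) return(-lambda * gf)
        d <- lambda * (as.numeric(Matrix::crossprod(M, y)) - gf)
        y_abs_max <<- max(y_abs_max, if (length(y)) max(abs(y)) else 0)
        # rows of M are gradients of g = -s >= 0; a correctly active row
        # carries a nonnegative multiplier, others leave the working set
        y_in <- y[length(e0) + seq_along(act)]
        drop_rows <- which(y_in < -1e-12)
        new_viol <- which(s0 - as.numeric(Jg[s_idx, , drop = FALSE] %*% d) >
                            1e-12)
        new_act <- sort(union(setdiff(act, act[drop_rows]), new_viol))
        if (identical(new_act, act)) break
        act <- new_act
      }
      d
    }
    # size lambda so that the trust region, not the gradient scale, limits
    # the step: re-solve with a larger lambda while the step stays well
    # inside the box
    lambda <- delta / max(1e-12, max(abs(gf)), vm0 / delta)
    d <- solve_kkt(lambda)
    for (resize in 1:3) {
      step <- max(abs(d))
      if (step >= 0.5 * delta || step < 1e3 * .Machine$double.eps) break
      lambda <- lambda * min(delta / step, 100)
      d <- solve_kkt(lambda)
    }
    # trust region: scale the whole step back into the box
    step <- max(abs(d))
    if (step > delta) {
      d <- d * (delta / step)
      step <- delta
    }
    # multiplier estimates bound the merit weight needed for exactness
    mu_merit <- min(opt$mu_max, max(mu_merit, 2 * y_abs_max))
    pred <- model_pred(d)

    step <- max(abs(d))
    if (step < .Machine$double.eps || pred <= 0) {
      # no model descent available: either done, or the region is too big
      if (delta <= opt$rhoend) { converged <- v_cur <= 10 * tau; break }
      delta <- max(opt$rhoend, delta / 2)
      next
    }

    F1l <- program$eval_f(x + d)
    F1 <- c(F1l$fterms, F1l$g)
    nev <- nev + 1L
    f_new <- sum(F1[f_rows])
    v_new <- viol(F1[g_rows])

    # second-order correction: restore feasibility lost to constraint
    # curvature with a minimum-norm step on the violated rows, whenever
    # that loss eats a meaningful share of the predicted merit gain
    if (v_new > 10 * tau && mu_merit * v_new > 0.1 * max(pred, 0) &&
        nev < opt$maxfun) {
      act <- which(F1[g_rows] < 0)
      if (length(act) && length(act) <= 2000L) {
        A <- Jg[act, , drop = FALSE]
        M <- Matrix::tcrossprod(A)
        Matrix::diag(M) <- Matrix::diag(M) + 1e-10
        y <- tryCatch(as.numeric(Matrix::solve(M, -F1[g_rows][act])),
                      error = function(e) NULL)
        if (!is.null(y)) {
          s <- as.numeric(Matrix::crossprod(A, y))
          if (max(abs(s)) <= delta) {
            F2l <- program$eval_f(x + d + s)
            F2 <- c(F2l$fterms, F2l$g)
            nev <- nev + 1L
            f2 <- sum(F2[f_rows]); v2 <- viol(F2[g_rows])
            if (f2 + mu_merit * v2 < f_new + mu_merit * v_new) {
              d <- d + s; F1 <- F2; f_new <- f2; v_new <- v2
            }
          }
        }
      }
    }
    ared <- (f_cur + mu_merit * v_cur) - (f_new + mu_merit * v_new)

    if (ared > 0) {
      x <- x + d
      F0 <- F1
      f_cur <- f_new
      v_cur <- v_new
      need_jac <- TRUE
      rho <- ared / pred
      if (rho > 0.7 && step > 0.9 * delta) {
        delta <- min(delta * 2, 1e3 * opt$rhobeg)
      } else if (rho < 0.25) {
        delta <- delta / 2
      }
      if (step <= opt$rhoend && v_cur <= 10 * tau) {
        converged <- TRUE
        break
      }
    } else {
      delta <- delta / 2
      # a rejected step from a genuinely infeasible iterate that reduces
      # violation but grows the objective means the merit weight is
      # dwarfed by the true multipliers
      if (v_cur > 100 * tau && v_new < v_cur && f_new > f_cur &&
          mu_merit < opt$mu_max) {
        mu_merit <- mu_merit * 10
      }
    }
    if (opt$verbose) {
      message(sprintf(
        "it %4d f=%.6g v=%.2e delta=%.2e step=%.2e act=%d pred=%.2e ared=%.2e mu=%.1e nev=%d",
        nit, f_cur, v_cur, delta, step, length(act), pred, ared, mu_merit,
        nev))
    }
    # merit stagnation near feasibility ends the zigzag tail a nonsmooth
    # objective otherwise sustains at full trust radius
    if (ared < max(1e-12, opt$rhoend * max(1, abs(f_cur)))) {
      stall <- stall + 1L
    } else {
      stall <- 0L
    }
    if (stall >= 5L && v_cur <= 10 * tau) {
      converged <- TRUE
      break
    }
    if (delta < opt$rhoend) {
      converged <- v_cur <= 10 * tau
      break
    }
  }
  finish(x, nev, nit, converged)
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(
    "<solve_result> %d joints  objective=%.6g  max violation=%.3g  %s\n",
    nrow(x$positions), x$objective_value, x$max_violation,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d evaluations, %d iterations, %.2fs\n",
              x$n_function_evals, x$n_iterations, x$wall_time))
  invisible(x)
}
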