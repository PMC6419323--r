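as_positions_arg <- function(x) {
  if (inherits(x, "solve_result")) x <- x$positions
  as_position_matrix(x)
}

#' Percent error between a partitioned and a non-partitioned solution
#'
#' Per joint `i`, the relative positional discrepancy
#' `e_i = |p_part,i - p_nonpart,i| / |p_nonpart,i|` (Euclidean norms); the
#' statistic is `mean(e_i) * 100`. Joints whose reference position has
#' near-zero norm (`< 1e-12`) would make the ratio meaningless and are
#' excluded and counted; the per-joint errors and the exclusions are
#' attached as attributes.
#'
#' @param part,nonpart position matrices (rownames = joint ids) or
#'   `solve_result` objects covering the same joints.
#' @return scalar percent error with attributes `per_joint` (named vector)
#'   and `excluded` (ids dropped for a near-zero reference norm).
#' @export
percent_error <- function(part, nonpart) {
  e <- per_joint_errors(part, nonpart)
  out <- mean(e$errors) * 100
  attr(out, "per_joint") <- structure(e$errors, names = e$ids)
  attr(out, "excluded") <- e$excluded
  out
}

per_joint_errors <- function(part, nonpart) {
  part <- as_positions_arg(part)
  nonpart <- as_positions_arg(nonpart)
  ids <- intersect(rownames(part), rownames(nonpart))
  if (!length(ids)) {
    jp_stop("no joints shared between the two solutions",
            "jointpart_undefined")
  }
  dv <- part[ids, , drop = FALSE] - nonpart[ids, , drop = FALSE]
  num <- sqrt(rowSums(dv * dv))
  den <- sqrt(rowSums(nonpart[ids, , drop = FALSE]^2))
  keep <- den >= 1e-12
  if (!any(keep)) {
    jp_stop("all reference positions have near-zero norm",
            "jointpart_undefined")
  }
  list(ids = ids[keep], errors = num[keep] / den[keep],
       excluded = ids[!keep])
}

#' Scene magnitude
#'
#' A single length scale for the scene: the Euclidean length of the
#' diagonal of the axis-aligned bounding box of the initial joint
#' positions. Used to normalize positional error in [normalized_error()].
#'
#' @param graph a [joint_graph()] with at least 2 joints.
#' @return scalar scene magnitude in scene units.
#' @examples
#' g <- joint_graph(data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 1),
#'                             z = c(0, 1)))
#' scene_magnitude(g) # sqrt(3)
#' @export
scene_magnitude <- function(graph) {
  stopifnot(inherits(graph, "joint_graph"))
  P <- initial_positions(graph)
  P <- P[!graph$joints$virtual, , drop = FALSE]
  if (nrow(P) < 2L) {
    jp_stop("scene magnitude needs at least 2 joints", "jointpart_undefined")
  }
  norm3(apply(P, 2, max) - apply(P, 2, min))
}

#' Scene-normalized percent error
#'
#' `mean(e_i / scene_mag) * 100` with the same per-joint relative errors
#' `e_i` as [percent_error()]; equals `percent_error / scene_mag` when
#' computed from the same inputs.
#'
#' @inheritParams percent_error
#' @param scene_mag positive scene magnitude (see [scene_magnitude()]).
#' @return scalar normalized percent error.
#' @export
normalized_error <- function(part, nonpart, scene_mag) {
  if (!is.numeric(scene_mag) || scene_mag <= 0) {
    jp_stop("scene_mag must be > 0", "jointpart_invalid_input")
  }
  e <- per_joint_errors(part, nonpart)
  mean(e$errors / scene_mag) * 100
}

#' Full error report
#'
#' Bundles [percent_error()], [normalized_error()] and the per-joint terms
#' into one object.
#'
#' @inheritParams percent_error
#' @param scene_mag scene magnitude used for normalization.
#' @param speedup optional wall-time ratio (reporting only).
#' @return an `error_report` list.
#' @export
error_report <- function(part, nonpart, scene_mag, speedup = NA_real_) {
  e <- per_joint_errors(part, nonpart)
  pe <- mean(e$errors) * 100
  structure(
    list(percent_error = pe,
         normalized_percent_error = pe / scene_mag,
         scene_magnitude = scene_mag,
         per_joint_errors = structure(e$errors, names = e$ids),
         excluded = e$excluded,
         speedup = speedup),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> %%err=%.4g  normalized=%.4g%%  scene=%.4g  (%d joints, %d excluded)\n",
    x$percent_error, x$normalized_percent_error, x$scene_magnitude,
    length(x$per_joint_errors), length(x$excluded)))
  invisible(x)
}

#' Benchmark sweep over problem sizes and partitioning methods
#'
#' For each size and replicate, generates a synthetic problem with
#' [generate_problem()] + [generate_motion()], solves it non-partitioned
#' (optional) and with every requested partitioning method, and averages the
#' replicates. Per-cell non-convergence is recorded in `converged_frac`,
#' never aborts the sweep. Wall times and speedups are reporting-only
#' quantities (hardware-dependent).
#'
#' @param sizes integer vector of constraint counts.
#' @param methods named list of method specs, each a list with `algorithm`
#'   (`"cnm"`, `"dbscan"`, `"kmeans"`) and its parameters (`eps`, `minpts`,
#'   `k`). A `kmeans` spec may set `k = "dbscan"` plus an `eps` to reuse the
#'   community count DBSCAN finds at that radius.
#' @param replicates replicate problems per size (the reference protocol
#'   averages 5).
#' @param seed base seed; replicate r of size s uses a seed derived from it.
#' @param spec_args overrides passed to [generator_spec()] (besides
#'   `n_constraints` and `seed`).
#' @param motion_args overrides passed to [generate_motion()].
#' @param include_nonpartitioned solve the whole problem too (needed for
#'   the error and speedup columns; expensive at large sizes).
#' @param cone_angle cone aperture for the splits.
#' @param options solver options.
#' @return a `benchmark_result`: list with `table` (one row per size x
#'   method, columns `size, method, communities, modularity, time_s,
#'   speedup, err_pct, err_norm_pct, converged_frac`) and `fits`
#'   (per-method runtime-scaling fits from [fit_runtime_scaling()], when
#'   there are >= 3 sizes).
#' @export
run_benchmark <- function(sizes, methods = list(cnm = list(algorithm = "cnm")),
                          replicates = 1L, seed = 1L, spec_args = list(),
                          motion_args = list(),
                          include_nonpartitioned = TRUE,
                          cone_angle = 30, options = solver_options()) {
  stopifnot(length(sizes) >= 1L, replicates >= 1L)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    jp_stop("methods must be a named list", "jointpart_invalid_parameter")
  }
  cells <- list()
  for (size in sizes) {
    acc <- list()
    for (r in seq_len(replicates)) {
      rseed <- (as.integer(seed) * 1009L + as.integer(size) %% 1009L +
                  r * 31L) %% .Machine$integer.max
      sargs <- utils::modifyList(list(n_constraints = as.integer(size),
                                      seed = rseed), spec_args)
      g <- generate_problem(do.call(generator_spec, sargs))
      g <- do.call(generate_motion,
                   c(list(graph = g, seed = rseed + 1L), motion_args))
      smag <- scene_magnitude(g)
      ref <- NULL
      t_ref <- NA_real_
      if (include_nonpartitioned) {
        t_ref <- system.time(ref <- solve_graph(g, options = options))[[
          "elapsed"]]
      }
      for (mn in names(methods)) {
        ms <- methods[[mn]]
        kk <- ms$k
        if (identical(kk, "dbscan")) {
          da <- detect_communities(g, "dbscan", eps = ms$eps,
                                   minpts = ms$minpts %||% 2L)
          kk <- length(unique(da$labels))
        }
        t_run <- system.time(res <- solve_partitioned(
          g, algorithm = ms$algorithm, eps = ms$eps,
          minpts = ms$minpts %||% 2L, k = kk, seed = rseed,
          cone_angle = cone_angle, options = options))[["elapsed"]]
        asg <- res$partitions$assignment
        acc[[length(acc) + 1L]] <- data.frame(
          size = size, method = mn,
          communities = length(unique(asg$labels)),
          modularity = asg$modularity,
          time_s = t_run,
          speedup = if (is.na(t_ref)) NA_real_ else t_ref / max(t_run, 1e-9),
          err_pct = if (is.null(ref)) NA_real_ else {
            as.numeric(percent_error(res, ref))
          },
          err_norm_pct = if (is.null(ref)) NA_real_ else {
            normalized_error(res, ref, smag)
          },
          converged_frac = mean(vapply(res$partitions$results, `[[`, TRUE,
                                       "converged")),
          stringsAsFactors = FALSE
        )
      }
      if (include_nonpartitioned) {
        acc[[length(acc) + 1L]] <- data.frame(
          size = size, method = "none", communities = 1L,
          modularity = NA_real_, time_s = t_ref, speedup = 1,
          err_pct = 0, err_norm_pct = 0,
          converged_frac = as.numeric(ref$converged),
          stringsAsFactors = FALSE
        )
      }
    }
    acc <- do.call(rbind, acc)
    # average replicates per method
    for (mn in unique(acc$method)) {
      sub <- acc[acc$method == mn, , drop = FALSE]
      cells[[length(cells) + 1L]] <- data.frame(
        size = size, method = mn,
        communities = mean(sub$communities),
        modularity = mean(sub$modularity),
        time_s = mean(sub$time_s),
        speedup = mean(sub$speedup),
        err_pct = mean(sub$err_pct),
        err_norm_pct = mean(sub$err_norm_pct),
        converged_frac = mean(sub$converged_frac),
        stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, cells)
  table <- table[order(table$size, table$method), , drop = FALSE]
  rownames(table) <- NULL
  fits <- list()
  if (length(unique(table$size)) >= 3L) {
    for (mn in unique(table$method)) {
      sub <- table[table$method == mn, , drop = FALSE]
      fits[[mn]] <- fit_runtime_scaling(sub$size, sub$time_s)
    }
  }
  structure(list(table = table, fits = fits), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Linear vs exponential runtime-scaling fits
#'
#' Least-squares fits of runtime against problem size under a linear model
#' `t = a + b * size` and an exponential model `t = exp(a + b * size)`
#' (fitted on the log scale), with both R-squared values computed on the
#' original time scale so the two models are comparable.
#'
#' @param sizes problem sizes.
#' @param times matching runtimes (> 0 for the exponential fit).
#' @return list with `linear` and `exponential`, each holding `coef` and
#'   `r2`.
#' @export
fit_runtime_scaling <- function(sizes, times) {
  stopifnot(length(sizes) == length(times), length(sizes) >= 3L)
  ss_tot <- sum((times - mean(times))^2)
  r2 <- function(pred) 1 - sum((times - pred)^2) / ss_tot
  lin <- stats::lm(times ~ sizes)
  expo <- stats::lm(log(pmax(times, 1e-12)) ~ sizes)
  list(
    linear = list(coef = stats::coef(lin), r2 = r2(stats::fitted(lin))),
    exponential = list(coef = stats::coef(expo),
                       r2 = r2(exp(stats::fitted(expo))))
  )
}
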