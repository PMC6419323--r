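#' Constraint residuals
#'
#' Pure evaluation of the four constraint families of the joint model. All
#' residuals follow the "satisfied iff <= 0 / = 0" convention of the model
#' statement, not the solver's internal `g >= 0` convention (see
#' [assemble_program()] for the mapping).
#'
#' `residual_distance()` evaluates the absolute distance equality
#' `Dist_ij - |p_i - p_j|`; the constraint holds iff the residual is zero
#' (within tolerance).
#'
#' @param p_i,p_j 3-vectors, current joint positions (scene units).
#' @param dist rest distance `Dist_ij` (>= 0).
#' @return A scalar residual.
#' @examples
#' residual_distance(c(0, 0, 0), c(3, 4, 0), 6) # 1: pair is 1 unit short
#' @export
residual_distance <- function(p_i, p_j, dist) {
  p_i <- vec3(p_i, "p_i"); p_j <- vec3(p_j, "p_j")
  check_finite(dist, "dist")
  if (dist < 0) jp_stop("dist must be >= 0", "jointpart_invalid_input")
  dist - norm3(p_i - p_j)
}

#' Pivot-angle residual
#'
#' Angle (in degrees) between the initial direction `p_io - p_j` and the
#' current direction `p_i - p_j`, minus the maximum pivot angle `theta`;
#' satisfied iff negative. With an `axis` lock the second component is the
#' difference of the locked coordinate of the two direction vectors,
#' satisfied iff zero. The normalized dot product is clamped to `[-1, 1]`
#' before `acos` to survive floating-point drift.
#'
#' @param p_i current position of the pivoting joint.
#' @param p_io initial position of the pivoting joint.
#' @param p_j pivot joint position.
#' @param theta maximum pivot angle, degrees, in `(0, 180]`.
#' @param axis optional `"x"`, `"y"` or `"z"` axis lock.
#' @return list with `angle` (degrees, scalar) and `axis` (scalar or `NULL`).
#' @export
residual_angle <- function(p_i, p_io, p_j, theta, axis = NULL) {
  p_i <- vec3(p_i, "p_i"); p_io <- vec3(p_io, "p_io"); p_j <- vec3(p_j, "p_j")
  check_finite(theta, "theta")
  u <- p_io - p_j
  v <- p_i - p_j
  nu <- norm3(u); nv <- norm3(v)
  if (nu == 0 || nv == 0) {
    jp_stop("degenerate direction vector: p_io or p_i coincides with p_j",
            "jointpart_degenerate_geometry")
  }
  cosang <- min(1, max(-1, sum(u * v) / (nu * nv)))
  res <- rad2deg(acos(cosang)) - theta
  axis_res <- NULL
  if (!is.null(axis) && !is.na(axis)) {
    k <- match(axis, c("x", "y", "z"))
    if (is.na(k)) jp_stop("axis must be x, y or z", "jointpart_invalid_input")
    axis_res <- u[k] - v[k]
  }
  list(angle = res, axis = axis_res)
}

#' Flexibility (min-max distance) residual pair
#'
#' Lower and upper band residuals
#' `(Dist_ij - dmax - |p_i - p_j|, |p_i - p_j| - Dist_ij - dmax)`; both
#' satisfied iff negative, i.e. the realized distance stays within
#' `dmax` of the rest distance.
#'
#' @inheritParams residual_distance
#' @param dmax maximum allowed displacement (>= 0).
#' @return numeric vector `c(lower, upper)`.
#' @export
residual_flexibility <- function(p_i, p_j, dist, dmax) {
  p_i <- vec3(p_i, "p_i"); p_j <- vec3(p_j, "p_j")
  check_finite(c(dist, dmax), "dist/dmax")
  if (dist < 0 || dmax < 0) {
    jp_stop("dist and dmax must be >= 0", "jointpart_invalid_input")
  }
  d <- norm3(p_i - p_j)
  c(lower = dist - dmax - d, upper = d - dist - dmax)
}

#' Cone residual for virtual-joint anchors
#'
#' After a split, a real joint `p_i` is tied to the pinned virtual copy
#' `v_j` of its removed neighbor by a cone of aperture `a_ij` (degrees) and
#' radius `r`: the residual is
#' `2 * sgn((p_j_dir - p_i) . (v_j - p_i)) * atan(r / d) - a_ij` with
#' `d = |v_j - p_i|`, satisfied iff negative. `sgn(0)` is taken as `+1`
#' (the reference and anchor directions coincide at the split instant).
#'
#' @param p_i current position of the real joint.
#' @param p_j_dir direction reference: the pre-split position of the removed
#'   neighbor (equals the virtual joint's pinned position right after a
#'   split).
#' @param v_j pinned position of the virtual joint.
#' @param r cone radius (scene units, >= 0).
#' @param a_ij cone aperture, degrees.
#' @return scalar residual in degrees.
#' @export
residual_cone <- function(p_i, p_j_dir, v_j, r, a_ij) {
  p_i <- vec3(p_i, "p_i"); p_j_dir <- vec3(p_j_dir, "p_j_dir")
  v_j <- vec3(v_j, "v_j")
  check_finite(c(r, a_ij), "r/a_ij")
  if (r < 0) jp_stop("r must be >= 0", "jointpart_invalid_input")
  d <- norm3(v_j - p_i)
  if (d == 0) {
    jp_stop("degenerate cone: joint coincides with its virtual anchor",
            "jointpart_degenerate_geometry")
  }
  s <- sum((p_j_dir - p_i) * (v_j - p_i))
  sgn <- if (s < 0) -1 else 1
  2 * sgn * rad2deg(atan(r / d)) - a_ij
}

#' Cone radius at a given anchor distance
#'
#' Radius of the cone of full aperture `a_ij` at distance `d` from its apex:
#' `r = d * tan(a_ij / 2)`. This is the radius at which the cone residual of
#' [residual_cone()] sits exactly on its boundary, and is the radius
#' recorded on the D constraints inserted by [split_graph()].
#'
#' @param d apex distance (> 0, scene units).
#' @param a_ij full cone aperture, degrees, in `(0, 180)`.
#' @return scalar radius, monotone increasing in both arguments.
#' @examples
#' cone_radius(1, 90) # 1
#' @export
cone_radius <- function(d, a_ij) {
  check_finite(c(d, a_ij), "d/a_ij")
  if (any(d <= 0)) jp_stop("d must be > 0", "jointpart_invalid_input")
  if (any(a_ij <= 0 | a_ij >= 180)) {
    jp_stop("a_ij must be in (0, 180)", "jointpart_invalid_input")
  }
  d * tan(deg2rad(a_ij / 2))
}

#' Distance-constraint diagnostics
#'
#' Scalar diagnostics of the generalized distance constraint
#' `C(p) = 1/2 [ (p - p0).(p - p0) - rest^2 ]` and its first two iteration
#' derivatives, plus the Lagrange-multiplier magnitude
#' `|lambda| = sqrt(-(p - p0) . p_ddot)`. On a constraint-satisfying
#' trajectory all of `C`, `C_dot`, `C_ddot` vanish and the displacement
#' stays orthogonal to the velocity. A negative radicand (possible off the
#' constraint manifold or under discretization noise) is clipped to zero and
#' flagged.
#'
#' @param p,p0 current and initial positions (3-vectors).
#' @param rest rest distance (>= 0).
#' @param p_dot,p_ddot first and second iteration derivatives of `p`.
#' @return object of class `constraint_diagnostics` with fields `C`,
#'   `C_dot`, `C_ddot`, `lambda_abs`, `clipped`.
#' @export
distance_constraint_diagnostics <- function(p, p0, rest, p_dot, p_ddot) {
  p <- vec3(p, "p"); p0 <- vec3(p0, "p0")
  p_dot <- vec3(p_dot, "p_dot"); p_ddot <- vec3(p_ddot, "p_ddot")
  check_finite(rest, "rest")
  if (rest < 0) jp_stop("rest must be >= 0", "jointpart_invalid_input")
  d <- p - p0
  C <- 0.5 * (sum(d * d) - rest^2)
  C_dot <- sum(d * p_dot)
  C_ddot <- sum(p_dot * p_dot) + sum(d * p_ddot)
  radicand <- -sum(d * p_ddot)
  structure(
    list(C = C, C_dot = C_dot, C_ddot = C_ddot,
         lambda_abs = sqrt(max(0, radicand)), clipped = radicand < 0),
    class = "constraint_diagnostics"
  )
}

#' @export
print.constraint_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<constraint_diagnostics> C=%.3g  C_dot=%.3g  C_ddot=%.3g  |lambda|=%.3g%s\n",
    x$C, x$C_dot, x$C_ddot, x$lambda_abs,
    if (x$clipped) " (radicand clipped)" else ""))
  invisible(x)
}
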