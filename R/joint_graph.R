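#' Joint-constraint graphs
#'
#' A `joint_graph` bundles a table of joints (3D nodes with an initial and a
#' current position, a stiffness ratio and an optional destination) with a
#' table of pairwise constraints between them. The constraint multigraph over
#' the joints is the structure used for community detection, and the pair
#' (objective over destinations, constraint set) is the nonlinear program
#' solved by [solve_single()] / [solve_partitioned()].
#'
#' Joint columns: `id` (character, unique), `x,y,z` (current position),
#' `x0,y0,z0` (initial position), `stiffness` (k, > 0), `dx,dy,dz`
#' (destination, `NA` if none), `virtual` (logical), `twin` (id of the real
#' joint a virtual joint duplicates, `NA` otherwise), `mesh` (opaque,
#' carried but never interpreted).
#'
#' Constraint kinds: `"A"` absolute distance equality (`dist`), `"B"` pivot
#' angle bound in degrees (`theta`, optional `axis` lock in `"x"/"y"/"z"`),
#' `"C"` flexibility band (`dist`, `dmax`), `"D"` cone constraint between a
#' real joint and a pinned virtual joint (`cone_angle` degrees,
#' `cone_radius` scene units). A joint pair never carries both an A and a C
#' constraint.
#'
#' @param joints data frame of joints; missing optional columns are filled.
#'   Minimal form: `id`, `x`, `y`, `z` (initial positions default to current).
#' @param constraints data frame of constraints with columns `kind`, `i`,
#'   `j` and the kind-relevant parameter columns above.
#' @param metadata free-form provenance list (seed, generator parameters).
#' @return An object of class `joint_graph`.
#' @examples
#' g <- joint_graph(
#'   data.frame(id = c("a", "b"), x = c(0, 1), y = 0, z = 0),
#'   data.frame(kind = "A", i = "a", j = "b", dist = 1)
#' )
#' n_joints(g)
#' @export
joint_graph <- function(joints, constraints = NULL, metadata = list()) {
  joints <- normalize_joints(joints)
  constraints <- normalize_constraints(constraints)
  g <- structure(
    list(joints = joints, constraints = constraints, metadata = metadata),
    class = "joint_graph"
  )
  validate_joint_graph(g)
  g
}

JOINT_COLS <- c("id", "x", "y", "z", "x0", "y0", "z0", "stiffness",
                "dx", "dy", "dz", "virtual", "twin", "mesh")
CONSTRAINT_COLS <- c("kind", "i", "j", "dist", "dmax", "theta", "axis",
                     "cone_angle", "cone_radius")

normalize_joints <- function(joints) {
  if (is.null(joints) || nrow(as.data.frame(joints)) == 0L) {
    joints <- data.frame(id = character(), x = numeric(), y = numeric(),
                         z = numeric())
  }
  joints <- as.data.frame(joints, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(joints))) {
    jp_stop("joints need at least columns id, x, y, z", "jointpart_invalid_model")
  }
  joints$id <- as.character(joints$id)
  if (is.null(joints$x0)) joints$x0 <- joints$x
  if (is.null(joints$y0)) joints$y0 <- joints$y
  if (is.null(joints$z0)) joints$z0 <- joints$z
  if (is.null(joints$stiffness)) joints$stiffness <- rep(1, nrow(joints))
  for (col in c("dx", "dy", "dz")) {
    if (is.null(joints[[col]])) joints[[col]] <- rep(NA_real_, nrow(joints))
  }
  if (is.null(joints$virtual)) joints$virtual <- rep(FALSE, nrow(joints))
  joints$virtual <- as.logical(joints$virtual) & !is.na(joints$virtual)
  if (is.null(joints$twin)) joints$twin <- rep(NA_character_, nrow(joints))
  joints$twin <- as.character(joints$twin)
  if (is.null(joints$mesh)) joints$mesh <- rep(NA_character_, nrow(joints))
  joints$mesh <- as.character(joints$mesh)
  joints <- joints[, JOINT_COLS]
  rownames(joints) <- NULL
  joints
}

normalize_constraints <- function(constraints) {
  if (is.null(constraints) || nrow(as.data.frame(constraints)) == 0L) {
    constraints <- data.frame(kind = character(), i = character(),
                              j = character())
  }
  constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
  need <- c("kind", "i", "j")
  if (!all(need %in% names(constraints))) {
    jp_stop("constraints need at least columns kind, i, j",
            "jointpart_invalid_model")
  }
  constraints$kind <- as.character(constraints$kind)
  constraints$i <- as.character(constraints$i)
  constraints$j <- as.character(constraints$j)
  for (col in c("dist", "dmax", "theta", "cone_angle", "cone_radius")) {
    if (is.null(constraints[[col]])) {
      constraints[[col]] <- rep(NA_real_, nrow(constraints))
    }
    constraints[[col]] <- as.numeric(constraints[[col]])
  }
  if (is.null(constraints$axis)) {
    constraints$axis <- rep(NA_character_, nrow(constraints))
  }
  constraints$axis <- as.character(constraints$axis)
  constraints <- constraints[, CONSTRAINT_COLS]
  rownames(constraints) <- NULL
  constraints
}

validate_joint_graph <- function(g) {
  j <- g$joints
  k <- g$constraints
  if (anyDuplicated(j$id)) {
    jp_stop("duplicate joint ids", "jointpart_invalid_model")
  }
  check_finite(c(j$x, j$y, j$z, j$x0, j$y0, j$z0), "joint positions")
  if (any(!is.finite(j$stiffness) | j$stiffness <= 0)) {
    bad <- j$id[!is.finite(j$stiffness) | j$stiffness <= 0][1L]
    jp_stop(sprintf("joint '%s': stiffness must be > 0", bad),
            "jointpart_invalid_model")
  }
  if (any(j$virtual & is.na(j$twin)) || any(!j$virtual & !is.na(j$twin))) {
    jp_stop("twin id must be present iff joint is virtual",
            "jointpart_invalid_model")
  }
  if (nrow(k)) {
    if (!all(k$kind %in% c("A", "B", "C", "D"))) {
      jp_stop("constraint kind must be one of A, B, C, D",
              "jointpart_invalid_model")
    }
    missing_ep <- setdiff(c(k$i, k$j), j$id)
    if (length(missing_ep)) {
      jp_stop(sprintf("constraint endpoint '%s' is not a joint",
                      missing_ep[1L]), "jointpart_invalid_model")
    }
    if (any(k$i == k$j)) {
      jp_stop("constraint endpoints must differ", "jointpart_invalid_model")
    }
    isA <- k$kind == "A"; isB <- k$kind == "B"
    isC <- k$kind == "C"; isD <- k$kind == "D"
    if (any(isA & (is.na(k$dist) | k$dist < 0)) ||
        any(isC & (is.na(k$dist) | k$dist < 0))) {
      jp_stop("A/C constraints need dist >= 0", "jointpart_invalid_model")
    }
    if (any(isC & (is.na(k$dmax) | k$dmax < 0))) {
      jp_stop("C constraints need dmax >= 0", "jointpart_invalid_model")
    }
    if (any(isB & (is.na(k$theta) | k$theta <= 0 | k$theta > 180))) {
      jp_stop("B constraints need 0 < theta <= 180", "jointpart_invalid_model")
    }
    if (any(isB & !is.na(k$axis) & !(k$axis %in% c("x", "y", "z")))) {
      jp_stop("axis lock must be one of x, y, z", "jointpart_invalid_model")
    }
    if (any(isD & (is.na(k$cone_angle) | k$cone_angle <= 0 |
                   k$cone_angle >= 180))) {
      jp_stop("D constraints need 0 < cone_angle < 180",
              "jointpart_invalid_model")
    }
    if (any(isD & (is.na(k$cone_radius) | k$cone_radius < 0))) {
      jp_stop("D constraints need cone_radius >= 0", "jointpart_invalid_model")
    }
    pair_key <- function(i, jj) paste(pmin(i, jj), pmax(i, jj))
    ac <- intersect(pair_key(k$i[isA], k$j[isA]), pair_key(k$i[isC], k$j[isC]))
    if (length(ac)) {
      jp_stop(sprintf("joint pair (%s) carries both an A and a C constraint",
                      ac[1L]), "jointpart_invalid_model")
    }
    virt <- j$id[j$virtual]
    abc <- k$kind %in% c("A", "B", "C")
    if (any(abc & (k$i %in% virt | k$j %in% virt))) {
      jp_stop("virtual joints may appear only in D constraints",
              "jointpart_invalid_model")
    }
  }
  invisible(g)
}

#' @export
print.joint_graph <- function(x, ...) {
  nv <- sum(x$joints$virtual)
  cat(sprintf("<joint_graph> %d joints (%d virtual), %d constraints\n",
              nrow(x$joints), nv, nrow(x$constraints)))
  if (nrow(x$constraints)) {
    tab <- table(factor(x$constraints$kind, levels = c("A", "B", "C", "D")))
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Basic accessors for joint graphs
#'
#' @param graph a [joint_graph()].
#' @return `n_joints()`/`n_constraints()` return counts; `positions()` and
#'   `initial_positions()` return a numeric matrix with one row per joint
#'   (rownames = joint ids) and columns `x,y,z`; `destinations()` returns the
#'   same for joints that carry a destination.
#' @export
n_joints <- function(graph) nrow(graph$joints)

#' @rdname n_joints
#' @export
n_constraints <- function(graph) nrow(graph$constraints)

#' @rdname n_joints
#' @export
positions <- function(graph) {
  m <- as.matrix(graph$joints[, c("x", "y", "z")])
  rownames(m) <- graph$joints$id
  colnames(m) <- c("x", "y", "z")
  m
}

#' @rdname n_joints
#' @export
initial_positions <- function(graph) {
  m <- as.matrix(graph$joints[, c("x0", "y0", "z0")])
  rownames(m) <- graph$joints$id
  colnames(m) <- c("x", "y", "z")
  m
}

#' @rdname n_joints
#' @export
destinations <- function(graph) {
  has <- !is.na(graph$joints$dx)
  m <- as.matrix(graph$joints[has, c("dx", "dy", "dz"), drop = FALSE])
  rownames(m) <- graph$joints$id[has]
  colnames(m) <- c("x", "y", "z")
  m
}

# replace current positions from a named matrix / named list of 3-vectors
set_positions <- function(graph, pos) {
  pos <- as_position_matrix(pos)
  idx <- match(rownames(pos), graph$joints$id)
  if (anyNA(idx)) {
    jp_stop("positions refer to unknown joint ids", "jointpart_invalid_input")
  }
  graph$joints$x[idx] <- pos[, 1L]
  graph$joints$y[idx] <- pos[, 2L]
  graph$joints$z[idx] <- pos[, 3L]
  graph
}

as_position_matrix <- function(pos) {
  if (is.list(pos) && !is.data.frame(pos)) {
    pos <- do.call(rbind, lapply(pos, vec3))
  }
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L || is.null(rownames(pos))) {
    jp_stop("positions must be a named 3-column matrix or named list of 3-vectors",
            "jointpart_invalid_input")
  }
  storage.mode(pos) <- "double"
  pos
}
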