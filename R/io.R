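#' Read and write the JSON scene format
#'
#' Scenes are stored as JSON with top-level keys `schema_version`, `joints`,
#' `constraints`, `metadata`. Each joint record carries `id`, `pos`
#' (current `[x, y, z]`), optional `pos0` (initial position, omitted when
#' equal to `pos`), `stiffness`, and optional `destination`, `virtual`,
#' `twin`, `mesh`. Each constraint record carries `kind`, `i`, `j` and only
#' its kind-relevant parameter keys (`dist`, `dmax`, `theta`, `axis`,
#' `cone_angle`, `cone_radius`). Angles are serialized in degrees,
#' coordinates in raw right-handed scene units. Unknown keys on records are
#' preserved through a round trip. Writing uses canonical key order and
#' fixed numeric formatting, so identical graphs produce byte-identical
#' files. The schema is documented in
#' `system.file("extdata", "scene-schema.json", package = "jointpart")`.
#'
#' @param path file path.
#' @param graph a [joint_graph()].
#' @return `read_scene()` returns a validated [joint_graph()];
#'   `write_scene()` returns `path` invisibly.
#' @export
read_scene <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      jp_stop(sprintf("cannot parse scene '%s': %s", path,
                      conditionMessage(e)), "jointpart_parse_error")
    }
  )
  if (!is.list(doc) || is.null(doc$joints)) {
    jp_stop("scene document lacks a 'joints' list", "jointpart_parse_error")
  }
  jt_known <- c("id", "pos", "pos0", "stiffness", "destination", "virtual",
                "twin", "mesh")
  ct_known <- c("kind", "i", "j", "dist", "dmax", "theta", "axis",
                "cone_angle", "cone_radius")
  extra <- list(joints = list(), constraints = list())

  joints <- do.call(rbind, lapply(seq_along(doc$joints), function(r) {
    jr <- doc$joints[[r]]
    if (is.null(jr$id) || is.null(jr$pos) || length(jr$pos) != 3L) {
      jp_stop(sprintf("joint record %d needs 'id' and a 3-element 'pos'", r),
              "jointpart_parse_error")
    }
    pos <- as.numeric(jr$pos)
    pos0 <- if (is.null(jr$pos0)) pos else as.numeric(jr$pos0)
    dest <- if (is.null(jr$destination)) {
      c(NA_real_, NA_real_, NA_real_)
    } else {
      as.numeric(jr$destination)
    }
    unknown <- setdiff(names(jr), jt_known)
    if (length(unknown)) {
      extra$joints[[as.character(jr$id)]] <<- jr[unknown]
    }
    data.frame(id = as.character(jr$id), x = pos[1], y = pos[2], z = pos[3],
               x0 = pos0[1], y0 = pos0[2], z0 = pos0[3],
               stiffness = as.numeric(jr$stiffness %||% 1),
               dx = dest[1], dy = dest[2], dz = dest[3],
               virtual = isTRUE(jr$virtual),
               twin = as.character(jr$twin %||% NA_character_),
               mesh = as.character(jr$mesh %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  constraints <- NULL
  if (length(doc$constraints)) {
    constraints <- do.call(rbind, lapply(seq_along(doc$constraints),
                                         function(r) {
      cr <- doc$constraints[[r]]
      if (is.null(cr$kind) || is.null(cr$i) || is.null(cr$j)) {
        jp_stop(sprintf("constraint record %d needs 'kind', 'i', 'j'", r),
                "jointpart_parse_error")
      }
      unknown <- setdiff(names(cr), ct_known)
      if (length(unknown)) {
        extra$constraints[[as.character(r)]] <<- cr[unknown]
      }
      data.frame(kind = as.character(cr$kind), i = as.character(cr$i),
                 j = as.character(cr$j),
                 dist = as.numeric(cr$dist %||% NA_real_),
                 dmax = as.numeric(cr$dmax %||% NA_real_),
                 theta = as.numeric(cr$theta %||% NA_real_),
                 axis = as.character(cr$axis %||% NA_character_),
                 cone_angle = as.numeric(cr$cone_angle %||% NA_real_),
                 cone_radius = as.numeric(cr$cone_radius %||% NA_real_),
                 stringsAsFactors = FALSE)
    }))
  }
  metadata <- doc$metadata %||% list()
  if (length(extra$joints) || length(extra$constraints)) {
    metadata$.extra_keys <- extra
  }
  joint_graph(joints, constraints, metadata = metadata)
}

#' @rdname read_scene
#' @export
write_scene <- function(graph, path) {
  stopifnot(inherits(graph, "joint_graph"))
  extra <- graph$metadata$.extra_keys %||% list(joints = list(),
                                               constraints = list())
  num <- function(x) round(unname(x), 10)
  jrecs <- lapply(seq_len(nrow(graph$joints)), function(r) {
    jr <- graph$joints[r, ]
    rec <- list(id = jr$id, pos = num(c(jr$x, jr$y, jr$z)))
    if (jr$x0 != jr$x || jr$y0 != jr$y || jr$z0 != jr$z) {
      rec$pos0 <- num(c(jr$x0, jr$y0, jr$z0))
    }
    rec$stiffness <- num(jr$stiffness)
    if (!is.na(jr$dx)) rec$destination <- num(c(jr$dx, jr$dy, jr$dz))
    if (jr$virtual) {
      rec$virtual <- TRUE
      rec$twin <- jr$twin
    }
    if (!is.na(jr$mesh)) rec$mesh <- jr$mesh
    c(rec, extra$joints[[jr$id]])
  })
  crecs <- lapply(seq_len(nrow(graph$constraints)), function(r) {
    cr <- graph$constraints[r, ]
    rec <- list(kind = cr$kind, i = cr$i, j = cr$j)
    if (!is.na(cr$dist)) rec$dist <- num(cr$dist)
    if (!is.na(cr$dmax)) rec$dmax <- num(cr$dmax)
    if (!is.na(cr$theta)) rec$theta <- num(cr$theta)
    if (!is.na(cr$axis)) rec$axis <- cr$axis
    if (!is.na(cr$cone_angle)) rec$cone_angle <- num(cr$cone_angle)
    if (!is.na(cr$cone_radius)) rec$cone_radius <- num(cr$cone_radius)
    c(rec, extra$constraints[[as.character(r)]])
  })
  metadata <- graph$metadata
  metadata$.extra_keys <- NULL
  doc <- list(schema_version = 1L, joints = jrecs, constraints = crecs,
              metadata = metadata)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = 2, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write a benchmark table as CSV
#'
#' Fixed column order `size, method, communities, modularity, time_s,
#' speedup, err_pct, err_norm_pct, converged_frac` and deterministic row
#' order (size, then method), so reruns of the same configuration produce
#' byte-identical files.
#'
#' @param table a data frame from [run_benchmark()] (or a
#'   `benchmark_result`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  if (inherits(table, "benchmark_result")) table <- table$table
  cols <- c("size", "method", "communities", "modularity", "time_s",
            "speedup", "err_pct", "err_norm_pct", "converged_frac")
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    jp_stop(sprintf("benchmark table lacks column '%s'", missing[1L]),
            "jointpart_invalid_input")
  }
  table <- table[order(table$size, table$method), cols, drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
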