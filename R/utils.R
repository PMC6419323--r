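# internal helpers shared across modules

jp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "jointpart_error")))
}

#' @noRd
check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    jp_stop(sprintf("non-finite or non-numeric value in %s", what),
            "jointpart_invalid_input")
  }
  invisible(x)
}

vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L) {
    jp_stop(sprintf("%s must have length 3", what), "jointpart_invalid_input")
  }
  check_finite(x, what)
  x
}

norm3 <- function(x) sqrt(sum(x * x))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
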