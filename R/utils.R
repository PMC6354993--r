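# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state on exit, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be captured
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Draw a vector of fan-out seeds from one master seed
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Moore-Penrose pseudoinverse (real or complex) with relative tolerance
#'
#' Singular values below `tol * max(sigma)` are treated as zero; this guards
#' the nearly rank-deficient, tall-skinny matrices produced by grouped
#' snapshot stacking.
#'
#' @noRd
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}

#' Stop with a formatted message
#' @noRd
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

#' Check a scalar is a finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
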