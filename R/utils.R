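# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package functions do not perturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check that a matrix is symmetric within tolerance
#' @noRd
assert_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", what)
  }
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    stopf("%s is not symmetric (max |M - t(M)| = %.3g > %.3g)", what, dev, tol)
  }
  invisible(dev)
}

#' Scalar validity checks
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' @noRd
is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable sigmoid
#' @noRd
sigmoid <- function(z) 1 / (1 + exp(-z))

#' ReLU
#' @noRd
relu <- function(z) {
  z[z < 0] <- 0
  z
}
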