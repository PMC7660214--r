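# Graph signal processing on population graphs.
#
# The combinatorial Laplacian L = D - A of a graph is symmetric positive
# semidefinite, so L = U Lambda U' with orthonormal eigenvectors (the graph
# Fourier modes) and non-negative eigenvalues (the graph frequencies).  The
# graph Fourier transform of a node signal x is xhat = U'x; low-pass
# filtering reconstructs x from its first k modes, U[,1:k] U[,1:k]' x.
# Signals that vary little across strong edges ("smooth" signals)
# concentrate energy at low frequencies, which is what makes low-pass
# filtering useful on well-constructed population graphs.

#' Combinatorial Laplacian of a population graph
#'
#' `L = D - A` with `D` the diagonal matrix of weighted degrees.  Rows sum
#' to zero and `L` is symmetric positive semidefinite.  The identity
#' (fully disconnected) baseline has no edges, so its Laplacian is the zero
#' matrix.
#'
#' @param graph A `population_graph`, or a symmetric weight matrix.
#' @return An `n x n` symmetric matrix.
#' @export
combinatorial_laplacian <- function(graph) {
  w <- if (inherits(graph, "population_graph")) graph$weights else graph
  assert_symmetric(w, tol = 1e-10, what = "weight matrix")
  diag(rowSums(w)) - w
}

#' Eigendecomposition of a graph Laplacian
#'
#' Returns the orthonormal eigenvector matrix `U` (columns ordered by
#' non-decreasing eigenvalue) and the eigenvalues.  For reproducibility
#' across platforms, each eigenvector's sign is fixed so that its
#' largest-magnitude entry (first such entry on ties) is positive.  The
#' all-zero Laplacian of the fully disconnected graph is given the
#' canonical coordinate basis in node order, all eigenvalues zero.
#'
#' @param L Symmetric matrix (tolerance `1e-8`), typically from
#'   [combinatorial_laplacian()].
#' @param source_config Optional `graph_config` recorded on the result.
#' @return An object of class `spectral_basis`: list with `vectors` (U),
#'   `values` (non-decreasing), `source_config`.
#' @export
eigendecompose <- function(L, source_config = NULL) {
  assert_symmetric(L, tol = 1e-8, what = "Laplacian")
  n <- nrow(L)
  if (all(L == 0)) {
    basis <- list(vectors = diag(1, n), values = rep(0, n),
                  source_config = source_config)
    return(structure(basis, class = "spectral_basis"))
  }
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(n))  # eigen() returns decreasing values
  u <- e$vectors[, ord, drop = FALSE]
  vals <- e$values[ord]
  for (j in seq_len(n)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  structure(list(vectors = u, values = vals, source_config = source_config),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> n = %d, eigenvalues in [%.3g, %.3g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @noRd
as_signal_matrix <- function(x, n) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != n) stopf("signal has %d rows but the graph has %d nodes", nrow(x), n)
  x
}

#' Graph Fourier transform and its inverse
#'
#' `gft` maps node-domain signals to spectral coefficients, `Xhat = U'X`;
#' `igft` maps back, `X = U Xhat`.  Both preserve column norms (Parseval).
#'
#' @param basis A `spectral_basis`.
#' @param x Signal: length-n vector or `n x d` matrix (one signal per
#'   column).
#' @return Matrix of the same shape as the (matrix form of the) input.
#' @export
gft <- function(basis, x) {
  stopifnot(inherits(basis, "spectral_basis"))
  x <- as_signal_matrix(x, nrow(basis$vectors))
  crossprod(basis$vectors, x)
}

#' @rdname gft
#' @param xhat Spectral coefficients, length-n vector or `n x d` matrix.
#' @export
igft <- function(basis, xhat) {
  stopifnot(inherits(basis, "spectral_basis"))
  xhat <- as_signal_matrix(xhat, nrow(basis$vectors))
  basis$vectors %*% xhat
}

#' Low-pass filter a graph signal
#'
#' Reconstructs each signal column from its first `k` spectral modes:
#' `U[, 1:k] U[, 1:k]' X`, an orthogonal projection (idempotent, never
#' norm-increasing).  With `k = n` the filter is the identity and the input
#' is returned unchanged.
#'
#' @param basis A `spectral_basis`.
#' @param x Length-n vector or `n x d` matrix.
#' @param k Number of low-frequency modes kept, `1 <= k <= n`.
#' @return Filtered signal, same shape as the matrix form of `x`.
#' @export
lowpass_filter <- function(basis, x, k) {
  stopifnot(inherits(basis, "spectral_basis"))
  n <- nrow(basis$vectors)
  if (!is_count(k) || k < 1 || k > n) stopf("k must be an integer in [1, %d]", n)
  x <- as_signal_matrix(x, n)
  if (k == n) return(x)
  uk <- basis$vectors[, seq_len(k), drop = FALSE]
  uk %*% crossprod(uk, x)
}

#' Spectral coefficient profile of one feature
#'
#' Magnitudes of the graph Fourier coefficients of one feature column,
#' ordered by eigenvalue, with the cumulative fraction of squared
#' coefficient mass ("energy") in the first k modes.  Smooth signals show
#' rapidly saturating energy fractions.
#'
#' @param basis A `spectral_basis`.
#' @param x `n x d` feature matrix (or length-n vector).
#' @param feature_index Column to profile.
#' @return Object of class `spectral_profile`: data-frame-like list with
#'   `eigenvalue_rank`, `eigenvalue`, `coefficient_magnitude`,
#'   `cumulative_energy` (all `NA` with `zero_signal = TRUE` for an
#'   all-zero column).
#' @export
spectral_profile <- function(basis, x, feature_index = 1L) {
  stopifnot(inherits(basis, "spectral_basis"))
  x <- as_signal_matrix(x, nrow(basis$vectors))
  if (!is_count(feature_index) || feature_index > ncol(x)) {
    stopf("feature_index must be in [1, %d]", ncol(x))
  }
  xhat <- drop(crossprod(basis$vectors, x[, feature_index]))
  mag <- abs(xhat)
  total <- sum(mag^2)
  zero_signal <- total == 0
  energy <- if (zero_signal) rep(NA_real_, length(mag)) else cumsum(mag^2) / total
  structure(
    list(eigenvalue_rank = seq_along(mag), eigenvalue = basis$values,
         coefficient_magnitude = mag, cumulative_energy = energy,
         zero_signal = zero_signal),
    class = "spectral_profile"
  )
}

#' Write a spectral profile as CSV
#'
#' Columns: `eigenvalue_rank`, `eigenvalue`, `coefficient_magnitude`,
#' `cumulative_energy`.
#'
#' @param profile A `spectral_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_profile <- function(profile, path) {
  stopifnot(inherits(profile, "spectral_profile"))
  df <- data.frame(eigenvalue_rank = profile$eigenvalue_rank,
                   eigenvalue = profile$eigenvalue,
                   coefficient_magnitude = profile$coefficient_magnitude,
                   cumulative_energy = profile$cumulative_energy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Categorize a graph as low- or high-frequency from its accuracy curve
#'
#' A graph is "low-frequency" when a classifier on its low-pass-filtered
#' features already performs as well as with the full spectrum: the maximum
#' accuracy over thresholds `k <= ceil(low_k_fraction * n)` is within
#' `margin` of the maximum over all evaluated `k`.  Otherwise accuracy
#' keeps improving with high-frequency modes and the graph is
#' "high-frequency".
#'
#' @param accuracy_curve Data frame with columns `k` (increasing grid whose
#'   last entry is `n`) and `accuracy` (in `[0, 1]`).
#' @param n Number of nodes (defaults to the last `k`).
#' @param low_k_fraction Fraction of the spectrum counted as "low";
#'   default 0.2.
#' @param margin Accuracy tolerance; default 0.01.
#' @return `"low_frequency"` or `"high_frequency"`.
#' @export
categorize_frequency_regime <- function(accuracy_curve, n = NULL,
                                        low_k_fraction = 0.2, margin = 0.01) {
  if (is.null(accuracy_curve) || !nrow(accuracy_curve)) {
    stopf("accuracy_curve must be a non-empty data frame")
  }
  if (is.unsorted(accuracy_curve$k, strictly = TRUE)) {
    stopf("accuracy_curve$k must be strictly increasing")
  }
  n <- n %||% max(accuracy_curve$k)
  k_low <- ceiling(low_k_fraction * n)
  low <- accuracy_curve$accuracy[accuracy_curve$k <= k_low]
  if (!length(low)) {
    stopf("no k on the grid falls in the low band [1, %d]", k_low)
  }
  if (max(low) >= max(accuracy_curve$accuracy) - margin) {
    "low_frequency"
  } else {
    "high_frequency"
  }
}
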