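# Learning blocks: one frequency-filtered feed-forward classifier per
# population graph.
#
# A block trains a two-hidden-layer network (512 and 64 ReLU units) on the
# low-pass-filtered feature matrix of its graph and exposes the 64-unit
# hidden activations as the block representation consumed by the ensemble.
# Filtering is transductive: the eigenbasis comes from the full-cohort
# graph and both train and test folds consume the same reconstructed
# features; test labels are never used.

#' Specification of one learning block
#'
#' @param hidden_sizes Hidden layer widths; the standard architecture is
#'   `c(512, 64)` and the last entry is the block-representation width.
#' @param dropout_rate Inverted-dropout rate on hidden layers during
#'   training, in `[0, 1)`; default 0.3.
#' @param k_filter Low-pass filtering threshold (number of spectral modes
#'   kept); clamped to the cohort size at use time. Default 200.
#' @param learning_rate Adam learning rate; default 0.01.
#' @param epochs Full-batch training epochs; default 200 (no early
#'   stopping).
#' @param seed Integer seed covering initialization and dropout.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(hidden_sizes = c(512L, 64L), dropout_rate = 0.3,
                       k_filter = 200L, learning_rate = 0.01,
                       epochs = 200L, seed = 1L) {
  if (length(hidden_sizes) < 1 || any(hidden_sizes < 1)) {
    stopf("hidden_sizes must be positive")
  }
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stopf("dropout_rate must be in [0, 1)")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stopf("learning_rate must be positive")
  }
  if (!is_count(epochs)) stopf("epochs must be a positive integer")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), dropout_rate = dropout_rate,
         k_filter = as.integer(k_filter), learning_rate = learning_rate,
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "block_spec"
  )
}

#' Low-pass filter block input features
#'
#' Thin wrapper over [lowpass_filter()] that clamps `k` to the cohort size
#' (the published default `k = 200` presumes a cohort larger than most
#' simulated ones).
#'
#' @param basis A `spectral_basis` of the block's graph.
#' @param x `n x d` feature matrix.
#' @param k Requested number of modes.
#' @return Filtered `n x d` matrix.
#' @export
filter_features <- function(basis, x, k) {
  n <- nrow(basis$vectors)
  lowpass_filter(basis, x, min(as.integer(k), n))
}

#' Train one learning block
#'
#' Minimizes two-class softmax cross-entropy with full-batch Adam on the
#' training rows of the (already filtered) feature matrix.  Seeded:
#' identical inputs and seed give identical parameters.
#'
#' @param x_filtered `n x d` filtered feature matrix.
#' @param labels Length-n 0/1 labels.
#' @param train_index Row indices used for training (default: all rows).
#' @param spec A [block_spec()].
#' @param graph_config Optional `graph_config` recorded on the model.
#' @return An object of class `block_model` with elements `spec`,
#'   `graph_config`, `params`, `loss_history`, `fitted`.
#' @export
train_block <- function(x_filtered, labels, train_index = NULL,
                        spec = block_spec(), graph_config = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  x_filtered <- as.matrix(x_filtered)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x_filtered)) stopf("labels must match rows of x_filtered")
  train_index <- train_index %||% seq_len(nrow(x_filtered))
  if (!length(train_index)) stopf("train_index must be non-empty")
  y <- labels[train_index]
  if (length(unique(y)) < 2) {
    stopf("training fold contains a single class; cannot train a classifier")
  }
  xtr <- x_filtered[train_index, , drop = FALSE]
  sizes <- c(ncol(xtr), spec$hidden_sizes, 2L)

  fit <- with_seed(spec$seed, {
    pars <- nn_init(sizes)
    st <- adam_init(pars)
    loss_history <- numeric(spec$epochs)
    for (epoch in seq_len(spec$epochs)) {
      fwd <- nn_forward(pars, xtr, dropout = spec$dropout_rate, training = TRUE)
      ce <- softmax_ce(fwd$out, y)
      loss_history[epoch] <- ce$loss
      grads <- nn_backward(pars, fwd, ce$dlogits)
      upd <- adam_step(pars, grads, st, spec$learning_rate)
      pars <- upd$pars
      st <- upd$state
    }
    list(pars = pars, loss_history = loss_history)
  })

  structure(
    list(spec = spec, graph_config = graph_config, params = fit$pars,
         loss_history = fit$loss_history, input_dim = ncol(xtr),
         fitted = TRUE),
    class = "block_model"
  )
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf("<block_model> %s: %d -> %s -> 2, final training loss %.4f\n",
              if (!is.null(x$graph_config)) x$graph_config$name else "?",
              x$input_dim, paste(x$spec$hidden_sizes, collapse = " -> "),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predictions from a fitted block
#'
#' @param object A fitted `block_model`.
#' @param x Feature matrix (same filtering as in training).
#' @param type `"prob"` (probability of class 1), `"class"`, or
#'   `"hidden"` (the 64-unit representation).
#' @param ... Unused.
#' @return Vector of probabilities / classes, or a matrix for `"hidden"`.
#' @export
predict.block_model <- function(object, x, type = c("prob", "class", "hidden"),
                                ...) {
  type <- match.arg(type)
  if (!isTRUE(object$fitted)) stopf("block is not fitted")
  x <- as.matrix(x)
  fwd <- nn_forward(object$params, x, dropout = 0, training = FALSE)
  if (type == "hidden") {
    h <- fwd$a[[length(fwd$a) - 1L]]
    return(h)
  }
  shift <- fwd$out - apply(fwd$out, 1L, max)
  p <- exp(shift)
  p <- p[, 2] / rowSums(p)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' 64-dimensional hidden representation of a block
#'
#' Post-ReLU activations of the last hidden layer with dropout disabled;
#' deterministic across calls.
#'
#' @param block A fitted `block_model`.
#' @param x_filtered Filtered feature matrix.
#' @param index Optional row subset.
#' @return `length(index) x 64` non-negative matrix.
#' @export
hidden_representation <- function(block, x_filtered, index = NULL) {
  index <- index %||% seq_len(nrow(x_filtered))
  predict(block, x_filtered[index, , drop = FALSE], type = "hidden")
}

#' Cross-validated accuracy of a block as a function of the filtering k
#'
#' For each `k` on the grid, filters the features once (full-graph basis,
#' transductive), trains a block per fold on the training subjects, and
#' averages test-fold accuracy.  The resulting curve feeds
#' [categorize_frequency_regime()].
#'
#' @param basis `spectral_basis` of the graph under evaluation.
#' @param x Unfiltered `n x d` feature matrix.
#' @param labels Length-n 0/1 labels.
#' @param k_grid Increasing integer grid whose last value is `n`.
#' @param folds A `fold_plan` from [stratified_kfold()].
#' @param spec A [block_spec()]; its `k_filter` is ignored in favour of the
#'   grid.
#' @return Data frame with columns `k` and `accuracy`.
#' @export
block_accuracy_curve <- function(basis, x, labels, k_grid, folds,
                                 spec = block_spec()) {
  n <- nrow(basis$vectors)
  k_grid <- as.integer(k_grid)
  if (is.unsorted(k_grid, strictly = TRUE)) stopf("k_grid must be increasing")
  if (utils::tail(k_grid, 1) != n) stopf("k_grid must end at n = %d", n)
  labels <- as.integer(labels)
  acc <- vapply(k_grid, function(k) {
    xf <- lowpass_filter(basis, x, k)
    fold_acc <- vapply(seq_len(folds$n_folds), function(f) {
      test_idx <- which(folds$assignments == f)
      train_idx <- setdiff(seq_len(n), test_idx)
      fspec <- spec
      fspec$seed <- spec$seed + f
      block <- train_block(xf, labels, train_idx, fspec)
      mean(predict(block, xf[test_idx, , drop = FALSE], type = "class") ==
             labels[test_idx])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  data.frame(k = k_grid, accuracy = acc)
}
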