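# Softmax-gated multi-model ensemble.
#
# Stage one trains one learning block per selected low-frequency graph;
# stage two fuses their 64-dimensional representations p_i through
# learnable gate weights alpha = softmax(w) and a sigmoid head:
#
#   H = sum_i alpha_i p_i          (weighted_sum mode, width 64)
#   H = [alpha_1 p_1 | ... ]       (weighted_concat mode, width 64 m)
#   yhat = sigmoid(H V + b)
#
# trained with binary cross-entropy over the labeled training subjects.
# The default trains all block parameters and the gate jointly
# ("end_to_end"); a two-stage mode pretrains each block and then fits
# only the gate and head with the blocks frozen.

#' Softmax gate over block scores
#'
#' `alpha_i = exp(w_i) / sum_j exp(w_j)`, computed with max subtraction so
#' it is stable for scores up to about 1e3 in magnitude.  Positive,
#' sums to one, invariant to adding a constant to all scores.
#'
#' @param w Numeric scoring vector, length `>= 1`.
#' @return Gate weights of the same length.
#' @export
softmax_gate <- function(w) {
  if (!length(w)) stopf("w must be non-empty")
  e <- exp(w - max(w))
  e / sum(e)
}

#' Specification of the ensemble
#'
#' @param mode `"weighted_sum"` fuses blocks as `H = sum_i alpha_i p_i`
#'   (width 64, the literal fusion equation); `"weighted_concat"`
#'   concatenates the gated representations (width `64 m`, the stacked
#'   reading).
#' @param training `"end_to_end"` optimizes blocks, gate and head jointly
#'   per fold; `"two_stage"` pretrains blocks, freezes them, then fits
#'   gate and head.
#' @param hidden_sizes,dropout_rate,learning_rate,epochs,seed As in
#'   [block_spec()].
#' @param gate_init_sd Standard deviation of the seeded normal
#'   initialization of the scoring vector `w`; default 0.01.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(mode = c("weighted_sum", "weighted_concat"),
                          training = c("end_to_end", "two_stage"),
                          hidden_sizes = c(512L, 64L), dropout_rate = 0.3,
                          learning_rate = 0.01, epochs = 200L,
                          gate_init_sd = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  training <- match.arg(training)
  structure(
    list(mode = mode, training = training,
         hidden_sizes = as.integer(hidden_sizes),
         dropout_rate = dropout_rate, learning_rate = learning_rate,
         epochs = as.integer(epochs), gate_init_sd = gate_init_sd,
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' Construct an ensemble head for [ensemble_forward()]
#'
#' @param w Scoring vector (length m).
#' @param head_w Fusion weight vector (length 64 in `weighted_sum` mode,
#'   `64 m` in `weighted_concat` mode).
#' @param head_b Scalar bias.
#' @param mode Fusion mode.
#' @return An object of class `ensemble_model`.
#' @export
ensemble_model <- function(w, head_w, head_b = 0,
                           mode = c("weighted_sum", "weighted_concat")) {
  structure(list(w = as.numeric(w), head_w = as.numeric(head_w),
                 head_b = as.numeric(head_b), mode = match.arg(mode)),
            class = "ensemble_model")
}

#' Fuse block representations
#' @noRd
fuse_blocks <- function(block_reps, alpha, mode) {
  if (mode == "weighted_sum") {
    h <- block_reps[[1]] * alpha[1]
    for (i in seq_along(block_reps)[-1]) h <- h + block_reps[[i]] * alpha[i]
    h
  } else {
    do.call(cbind, Map(function(p, a) p * a, block_reps, alpha))
  }
}

#' Forward pass of the ensemble head
#'
#' Gates the block representations with `softmax(w)`, fuses them according
#' to the mode, and applies the sigmoid head.  With a single block the
#' gate is 1 and this reduces to a sigmoid head on that block's
#' representation.
#'
#' @param model An [ensemble_model()].
#' @param block_reps List of m matrices, each `n x 64` (same n).
#' @return Length-n vector of probabilities in (0, 1).
#' @export
ensemble_forward <- function(model, block_reps) {
  stopifnot(inherits(model, "ensemble_model"))
  m <- length(block_reps)
  if (m != length(model$w)) stopf("expected %d block representations", length(model$w))
  ns <- vapply(block_reps, nrow, integer(1))
  if (length(unique(ns)) != 1) stopf("block representations disagree on n")
  alpha <- softmax_gate(model$w)
  h <- fuse_blocks(block_reps, alpha, model$mode)
  if (ncol(h) != length(model$head_w)) {
    stopf("fused width %d does not match head width %d", ncol(h), length(model$head_w))
  }
  drop(sigmoid(h %*% model$head_w + model$head_b))
}

#' Binary cross-entropy of the ensemble (summed over samples)
#'
#' `L = -sum_i [ y_i log yhat_i + (1 - y_i) log(1 - yhat_i) ]`, the
#' two-class cross-entropy over the labeled samples.  Probabilities are
#' clipped to `[eps, 1 - eps]` because the loss is undefined at exactly
#' 0 or 1.
#'
#' @param y_hat Predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param eps Clipping constant, default `1e-12`.
#' @return Non-negative scalar.
#' @export
ensemble_loss <- function(y_hat, y, eps = 1e-12) {
  if (length(y_hat) != length(y)) stopf("y_hat and y must have equal length")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Select low-frequency graphs from their accuracy curves
#'
#' Categorizes every curve with [categorize_frequency_regime()], keeps the
#' configs judged low-frequency, and ranks them by their peak accuracy in
#' the low-k band.  A curve that never beats chance (peak accuracy at or
#' below `0.5 + margin`) is trivially flat and is never selected, whatever
#' its regime.  Raises a diagnostic error when no graph qualifies.
#'
#' @param curves Named list of data frames (columns `k`, `accuracy`), one
#'   per graph configuration.
#' @param n Number of subjects (defaults to the largest `k` seen).
#' @param low_k_fraction,margin Passed to
#'   [categorize_frequency_regime()].
#' @param top_m Optional cap on the number of selected graphs (the
#'   standard ensemble keeps the best eight).
#' @return Object of class `graph_selection`: list with `selected`
#'   (ordered names), `table` (per-config regime and peak accuracies).
#' @export
select_low_frequency_graphs <- function(curves, n = NULL,
                                        low_k_fraction = 0.2, margin = 0.01,
                                        top_m = NULL) {
  if (!length(curves)) stopf("curves must be a non-empty named list")
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    stopf("curves must be named by graph config")
  }
  n <- n %||% max(vapply(curves, function(cu) max(cu$k), numeric(1)))
  k_low <- ceiling(low_k_fraction * n)
  tab <- do.call(rbind, lapply(names(curves), function(nm) {
    cu <- curves[[nm]]
    data.frame(
      name = nm,
      regime = categorize_frequency_regime(cu, n = n,
                                           low_k_fraction = low_k_fraction,
                                           margin = margin),
      peak_low_accuracy = max(cu$accuracy[cu$k <= k_low]),
      peak_accuracy = max(cu$accuracy),
      stringsAsFactors = FALSE
    )
  }))
  keep <- tab[tab$regime == "low_frequency" &
                tab$peak_accuracy > 0.5 + margin, , drop = FALSE]
  if (!nrow(keep)) {
    stopf(paste0(
      "no graph was categorized low-frequency; peak accuracies were: ",
      paste(sprintf("%s=%.3f(low %.3f)", tab$name, tab$peak_accuracy,
                    tab$peak_low_accuracy), collapse = ", ")
    ))
  }
  keep <- keep[order(-keep$peak_low_accuracy, keep$name), , drop = FALSE]
  selected <- keep$name
  if (!is.null(top_m)) selected <- utils::head(selected, top_m)
  structure(list(selected = selected, table = tab, k_low = k_low),
            class = "graph_selection")
}

#' @export
print.graph_selection <- function(x, ...) {
  cat(sprintf("<graph_selection> %d low-frequency graphs: %s\n",
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Initialize ensemble parameters (caller seeds the RNG)
#' @noRd
ensemble_init <- function(d, m, spec) {
  trunks <- lapply(seq_len(m), function(i) nn_init(c(d, spec$hidden_sizes)))
  rep_width <- utils::tail(spec$hidden_sizes, 1)
  fused_width <- if (spec$mode == "weighted_sum") rep_width else rep_width * m
  list(trunks = trunks,
       w = stats::rnorm(m, sd = spec$gate_init_sd),
       head_w = stats::rnorm(fused_width, sd = 0.01),
       head_b = 0)
}

#' Joint forward/backward/update loop on one training fold
#' @noRd
ensemble_fit_fold <- function(x_list, y, train_idx, spec, pretrained = NULL) {
  m <- length(x_list)
  d <- ncol(x_list[[1]])
  n_tr <- length(train_idx)
  rep_width <- utils::tail(spec$hidden_sizes, 1)
  xtr <- lapply(x_list, function(x) x[train_idx, , drop = FALSE])
  ytr <- y[train_idx]

  pars <- ensemble_init(d, m, spec)
  frozen <- !is.null(pretrained)
  if (frozen) {
    pars$trunks <- lapply(pretrained, function(bl) {
      list(W = bl$params$W[-length(bl$params$W)],
           b = bl$params$b[-length(bl$params$b)])
    })
    p_fixed <- lapply(seq_len(m), function(i) {
      nn_forward(pars$trunks[[i]], xtr[[i]], training = FALSE,
                 top_linear = FALSE)$out
    })
  }

  opt_pars <- if (frozen) {
    list(w = pars$w, head_w = pars$head_w, head_b = pars$head_b)
  } else {
    pars
  }
  st <- adam_init(opt_pars)
  loss_history <- numeric(spec$epochs)

  for (epoch in seq_len(spec$epochs)) {
    if (frozen) {
      p <- p_fixed
      fwd <- NULL
    } else {
      fwd <- lapply(seq_len(m), function(i) {
        nn_forward(opt_pars$trunks[[i]], xtr[[i]],
                   dropout = spec$dropout_rate, training = TRUE,
                   top_linear = FALSE)
      })
      p <- lapply(fwd, `[[`, "out")
    }
    alpha <- softmax_gate(opt_pars$w)
    h <- fuse_blocks(p, alpha, spec$mode)
    yhat <- drop(sigmoid(h %*% opt_pars$head_w + opt_pars$head_b))
    loss_history[epoch] <- ensemble_loss(yhat, ytr)

    dz <- (yhat - ytr) / n_tr
    grads <- list(w = numeric(m),
                  head_w = drop(crossprod(h, dz)),
                  head_b = sum(dz))
    dh <- outer(dz, opt_pars$head_w)
    dalpha <- numeric(m)
    dp <- vector("list", m)
    for (i in seq_len(m)) {
      dh_i <- if (spec$mode == "weighted_sum") {
        dh
      } else {
        dh[, ((i - 1) * rep_width + 1):(i * rep_width), drop = FALSE]
      }
      dalpha[i] <- sum(dh_i * p[[i]])
      dp[[i]] <- dh_i * alpha[i]
    }
    grads$w <- alpha * (dalpha - sum(alpha * dalpha))
    if (!frozen) {
      grads$trunks <- lapply(seq_len(m), function(i) {
        nn_backward(opt_pars$trunks[[i]], fwd[[i]], dp[[i]], top_linear = FALSE)
      })
      grads <- grads[c("trunks", "w", "head_w", "head_b")]
      opt_pars <- opt_pars[c("trunks", "w", "head_w", "head_b")]
    }
    upd <- adam_step(opt_pars, grads, st, spec$learning_rate)
    opt_pars <- upd$pars
    st <- upd$state
  }

  if (frozen) {
    pars$w <- opt_pars$w
    pars$head_w <- opt_pars$head_w
    pars$head_b <- opt_pars$head_b
    opt_pars <- pars
  }
  list(pars = opt_pars, alpha = softmax_gate(opt_pars$w),
       loss_history = loss_history)
}

#' Ensemble probabilities from fitted fold parameters (dropout off)
#' @noRd
ensemble_predict_pars <- function(pars, x_list, idx, spec) {
  p <- lapply(seq_along(x_list), function(i) {
    nn_forward(pars$trunks[[i]], x_list[[i]][idx, , drop = FALSE],
               training = FALSE, top_linear = FALSE)$out
  })
  model <- ensemble_model(pars$w, pars$head_w, pars$head_b, spec$mode)
  ensemble_forward(model, p)
}

#' Train the gated ensemble with cross-validation
#'
#' For every fold, trains the ensemble on the fold's training subjects and
#' predicts the held-out subjects, so that each subject receives exactly
#' one out-of-fold probability.  In `"end_to_end"` mode all block
#' parameters, the scoring vector and the head are optimized jointly from
#' scratch per fold; in `"two_stage"` mode each block is first trained
#' stand-alone on the fold's training subjects and then frozen.
#'
#' @param x_list Named list of m filtered `n x d` feature matrices, one
#'   per selected graph (see [filter_features()]).
#' @param labels Length-n 0/1 labels.
#' @param folds A `fold_plan` from [stratified_kfold()].
#' @param spec An [ensemble_spec()].
#' @param subject_ids Optional subject identifiers for the prediction
#'   table.
#' @return Object of class `ensemble_fit`: list with `predictions`
#'   (data frame `subject_id`, `fold`, `probability`, `predicted_label`,
#'   `true_label`), `gates` (data frame `fold`, `block`, `alpha`),
#'   `loss_history` (per fold), `models` (per-fold `ensemble_model`
#'   heads), `spec`, `block_names`.
#' @export
train_ensemble <- function(x_list, labels, folds, spec = ensemble_spec(),
                           subject_ids = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(folds, "fold_plan"))
  if (!length(x_list)) stopf("x_list must contain at least one block input")
  m <- length(x_list)
  x_list <- lapply(x_list, as.matrix)
  n <- nrow(x_list[[1]])
  if (any(vapply(x_list, nrow, integer(1)) != n)) {
    stopf("all block feature matrices must share n")
  }
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("labels must have length n = %d", n)
  block_names <- names(x_list) %||% sprintf("block_%d", seq_len(m))
  subject_ids <- subject_ids %||% sprintf("sub-%04d", seq_len(n))

  prob <- rep(NA_real_, n)
  fold_of <- folds$assignments
  gates <- vector("list", folds$n_folds)
  histories <- vector("list", folds$n_folds)
  models <- vector("list", folds$n_folds)

  for (f in seq_len(folds$n_folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(labels[train_idx])) < 2) {
      stopf("fold %d: training subjects contain a single class", f)
    }
    pretrained <- NULL
    if (spec$training == "two_stage") {
      bspec <- block_spec(hidden_sizes = spec$hidden_sizes,
                          dropout_rate = spec$dropout_rate,
                          learning_rate = spec$learning_rate,
                          epochs = spec$epochs, seed = spec$seed + f)
      pretrained <- lapply(x_list, function(x) {
        train_block(x, labels, train_idx, bspec)
      })
    }
    fit <- with_seed(spec$seed + f, {
      ensemble_fit_fold(x_list, labels, train_idx, spec, pretrained)
    })
    prob[test_idx] <- ensemble_predict_pars(fit$pars, x_list, test_idx, spec)
    gates[[f]] <- data.frame(fold = f, block = block_names, alpha = fit$alpha)
    histories[[f]] <- fit$loss_history
    models[[f]] <- ensemble_model(fit$pars$w, fit$pars$head_w,
                                  fit$pars$head_b, spec$mode)
  }

  structure(
    list(
      predictions = data.frame(
        subject_id = subject_ids, fold = fold_of, probability = prob,
        predicted_label = as.integer(prob >= 0.5), true_label = labels,
        stringsAsFactors = FALSE
      ),
      gates = do.call(rbind, gates),
      loss_history = histories,
      models = models,
      spec = spec,
      block_names = block_names
    ),
    class = "ensemble_fit"
  )
}

#' @export
print.ensemble_fit <- function(x, ...) {
  acc <- mean(x$predictions$predicted_label == x$predictions$true_label)
  cat(sprintf("<ensemble_fit> %d blocks, %d folds, out-of-fold accuracy %.3f\n",
              length(x$block_names), max(x$predictions$fold), acc))
  invisible(x)
}

#' Write ensemble predictions and gate weights as CSV
#'
#' @param fit An `ensemble_fit`.
#' @param predictions_path,gates_path Output CSV paths (either may be
#'   `NULL` to skip).
#' @return `fit`, invisibly.
#' @export
write_ensemble_outputs <- function(fit, predictions_path = NULL,
                                   gates_path = NULL) {
  stopifnot(inherits(fit, "ensemble_fit"))
  if (!is.null(predictions_path)) {
    utils::write.csv(fit$predictions, predictions_path, row.names = FALSE)
  }
  if (!is.null(gates_path)) {
    utils::write.csv(fit$gates, gates_path, row.names = FALSE)
  }
  invisible(fit)
}
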