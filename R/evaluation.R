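# Stratified cross-validation, classification metrics, baselines, and the
# sensitivity sweep over the filtering threshold.

#' Stratified k-fold plan
#'
#' Shuffles subjects within each class (seeded) and deals them round-robin
#' into folds, so per-fold class counts differ by at most one from
#' proportional allocation and folds partition the cohort.
#'
#' @param labels Length-n 0/1 labels.
#' @param n_folds Number of folds, at least 2 (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `assignments`
#'   (length-n fold index), `n_folds`, `seed`.
#' @export
stratified_kfold <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (!is_count(n_folds) || n_folds < 2) {
    stopf("n_folds must be an integer >= 2")
  }
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stopf("every class needs at least n_folds = %d members (have %s)",
          n_folds, paste(counts, collapse = "/"))
  }
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#' @noRd
rank_auc <- function(probabilities, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probabilities)  # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from probabilities
#'
#' Thresholds the probabilities, forms the confusion matrix with class 1
#' (patient) as positive, and reports accuracy, rank-based AUC,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and the F-score
#' (harmonic mean of precision and sensitivity for the patient class).
#' With single-class labels the AUC is undefined and reported as `NA`.
#'
#' @param probabilities Predicted probabilities of class 1.
#' @param labels 0/1 labels, aligned with `probabilities`.
#' @param threshold Decision threshold, default 0.5.
#' @return Object of class `metrics_report`: list with `accuracy`, `auc`,
#'   `sensitivity`, `specificity`, `f_score`, `confusion`
#'   (named TP/FP/TN/FN), `n`.
#' @export
compute_metrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels)) {
    stopf("probabilities and labels must be aligned")
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  structure(
    list(accuracy = (tp + tn) / length(labels),
         auc = rank_auc(probabilities, labels),
         sensitivity = sens, specificity = spec, f_score = f1,
         confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
         n = length(labels)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  acc=%.4f  auc=%s  sens=%.4f  spec=%.4f  F=%.4f\n",
    x$n, x$accuracy, ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
    x$sensitivity, x$specificity, x$f_score
  ))
  invisible(x)
}

#' Per-fold metric aggregation (mean and sd across folds)
#'
#' @param predictions Data frame with columns `probability`, `true_label`,
#'   `fold` (as produced by [train_ensemble()]).
#' @param threshold Decision threshold.
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`.
#' @export
metrics_by_fold <- function(predictions, threshold = 0.5) {
  per_fold <- lapply(split(predictions, predictions$fold), function(df) {
    m <- compute_metrics(df$probability, df$true_label, threshold)
    c(accuracy = m$accuracy, auc = m$auc, sensitivity = m$sensitivity,
      specificity = m$specificity, f_score = m$f_score)
  })
  mat <- do.call(rbind, per_fold)
  data.frame(metric = colnames(mat),
             mean = colMeans(mat, na.rm = TRUE),
             sd = apply(mat, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' Single-model cross-validation on a fixed feature matrix
#' @noRd
single_model_cv <- function(x, labels, folds, spec) {
  n <- nrow(x)
  prob <- rep(NA_real_, n)
  for (f in seq_len(folds$n_folds)) {
    test_idx <- which(folds$assignments == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    bspec <- spec
    bspec$seed <- spec$seed + f
    block <- train_block(x, labels, train_idx, bspec)
    prob[test_idx] <- predict(block, x[test_idx, , drop = FALSE], type = "prob")
  }
  data.frame(subject = seq_len(n), fold = folds$assignments,
             probability = prob, true_label = as.integer(labels))
}

#' Run a reference baseline model
#'
#' `no_graph` trains the feed-forward classifier on the raw, unfiltered
#' features (equivalent to any graph with `k = n`); `random_graph` and
#' `fc_graph` run the single-model pipeline on the corresponding baseline
#' graph with low-pass filtering at `k`.
#'
#' @param kind `"no_graph"`, `"random_graph"`, or `"fc_graph"`.
#' @param cohort A `cohort`.
#' @param spec A [block_spec()] (its `k_filter` is the filtering
#'   threshold for graph baselines).
#' @param folds A `fold_plan`.
#' @param features Optional precomputed feature matrix from
#'   [vectorize_rsfc()].
#' @param density Edge density of the random baseline.
#' @return List with `metrics` (a `metrics_report`), `by_fold` (mean/sd
#'   table), `predictions`.
#' @export
run_baseline <- function(kind = c("no_graph", "random_graph", "fc_graph"),
                         cohort, spec = block_spec(), folds,
                         features = NULL, density = 0.1) {
  kind <- match.arg(kind)
  x <- features %||% vectorize_rsfc(cohort)
  n <- nrow(x)
  xf <- if (kind == "no_graph") {
    x
  } else {
    g <- build_baseline_graph(if (kind == "fc_graph") "fc" else "random",
                              n, density = density, seed = spec$seed,
                              subject_ids = cohort$subject_ids)
    basis <- eigendecompose(combinatorial_laplacian(g), g$config)
    filter_features(basis, x, spec$k_filter)
  }
  preds <- single_model_cv(xf, cohort$labels, folds, spec)
  list(metrics = compute_metrics(preds$probability, preds$true_label),
       by_fold = metrics_by_fold(preds),
       predictions = preds)
}

#' Sensitivity of the ensemble to the filtering threshold k
#'
#' Re-runs the full gated ensemble once per threshold with shared folds
#' and seeds, re-filtering every selected graph's features at that
#' threshold.  The `k = n` row corresponds to no spectral filtering.
#'
#' @param bases Named list of `spectral_basis` objects, one per selected
#'   graph (order defines the blocks).
#' @param x Unfiltered `n x d` feature matrix.
#' @param labels 0/1 labels.
#' @param k_values Integer thresholds within `[1, n]`.
#' @param folds A `fold_plan`.
#' @param spec An [ensemble_spec()].
#' @return Data frame with columns `k`, `accuracy_mean`, `accuracy_sd`,
#'   `auc_mean`, `auc_sd`.
#' @export
sweep_k <- function(bases, x, labels, k_values, folds,
                    spec = ensemble_spec()) {
  n <- nrow(x)
  k_values <- as.integer(k_values)
  if (any(k_values < 1 | k_values > n)) stopf("k_values must lie in [1, %d]", n)
  rows <- lapply(k_values, function(k) {
    x_list <- lapply(bases, function(b) filter_features(b, x, k))
    fit <- train_ensemble(x_list, labels, folds, spec)
    bf <- metrics_by_fold(fit$predictions)
    data.frame(k = k,
               accuracy_mean = bf$mean[bf$metric == "accuracy"],
               accuracy_sd = bf$sd[bf$metric == "accuracy"],
               auc_mean = bf$mean[bf$metric == "auc"],
               auc_sd = bf$sd[bf$metric == "auc"])
  })
  do.call(rbind, rows)
}
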