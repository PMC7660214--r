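# Shared fixtures and independent oracles, built in code at test time.

# A small, strongly separable cohort with few sites and broad age bins,
# so every RSFC-bearing graph is smooth with respect to the labels.
smooth_cohort <- function(n_per_class = 40, r = 16, seed = 1,
                          effect_size = 0.8, noise_sd = 0.15,
                          n_sites = 2, site_effect = 0.05) {
  generate_cohort(simulation_params(
    n_patients = n_per_class, n_controls = n_per_class, r = r,
    effect_size = effect_size, signal_fraction = 0.1,
    n_sites = n_sites, site_effect = site_effect,
    sex_imbalance = 0.6, age_range = c(6, 58), noise_sd = noise_sd,
    seed = seed
  ))
}

# Symmetric non-negative random weight matrix (Erdos-Renyi with weights).
random_weights <- function(n, p = 0.3, weighted = TRUE, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  edge <- stats::runif(sum(up)) < p
  val <- if (weighted) stats::runif(sum(up)) else 1
  w[up] <- edge * val
  w + t(w)
}

# Brute-force low-pass oracle: per column, sum_{i<=k} (u_i' x) u_i.
lowpass_oracle <- function(basis, x, k) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    for (i in seq_len(k)) {
      u <- basis$vectors[, i]
      out[, j] <- out[, j] + sum(u * x[, j]) * u
    }
  }
  out
}

# Independent Pearson correlation (explicit formula, no stats::cor).
pearson_oracle <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Nearest-class-mean linear classifier, used as the independent check
# that the planted class signal is linearly recoverable.
centroid_cv_accuracy <- function(x, labels, n_folds = 2, seed = 1) {
  folds <- stratified_kfold(labels, n_folds, seed)
  correct <- logical(length(labels))
  for (f in seq_len(n_folds)) {
    te <- which(folds$assignments == f)
    tr <- setdiff(seq_along(labels), te)
    mu1 <- colMeans(x[tr[labels[tr] == 1], , drop = FALSE])
    mu0 <- colMeans(x[tr[labels[tr] == 0], , drop = FALSE])
    d1 <- rowSums(sweep(x[te, , drop = FALSE], 2, mu1)^2)
    d0 <- rowSums(sweep(x[te, , drop = FALSE], 2, mu0)^2)
    correct[te] <- (d1 < d0) == (labels[te] == 1)
  }
  mean(correct)
}

# Hand confusion-matrix metrics oracle.
confusion_oracle <- function(prob, labels, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}
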