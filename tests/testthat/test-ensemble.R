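# Softmax gate, fusion head, ensemble loss, selection, CV training.

test_that("the softmax gate matches its closed form and is stable", {
  expect_equal(softmax_gate(rep(0, 8)), rep(1 / 8, 8))
  a <- softmax_gate(c(10, rep(0, 7)))
  expect_gt(a[1], 0.999)
  expect_equal(a, exp(c(10, rep(0, 7))) / sum(exp(c(10, rep(0, 7)))),
               tolerance = 1e-12)
  w <- c(0.3, -1.2, 2.5)
  expect_equal(softmax_gate(w), softmax_gate(w + 57.3), tolerance = 1e-12)
  big <- softmax_gate(c(1e3, 999, 998))
  expect_true(all(is.finite(big)) && abs(sum(big) - 1) < 1e-10)
  expect_error(softmax_gate(numeric(0)), "non-empty")
})

test_that("the fusion head computes the gated sigmoid by hand", {
  # zero head: every probability is 1/2
  m0 <- ensemble_model(w = c(0, 0), head_w = rep(0, 3), head_b = 0)
  reps <- list(matrix(1:6, 2, 3), matrix(7:12, 2, 3))
  expect_equal(ensemble_forward(m0, reps), c(0.5, 0.5))

  # hand-evaluated 2-subject, 2-block, 2-dim case
  p1 <- matrix(c(1, 0, 0.5, 2), 2, 2)
  p2 <- matrix(c(0, 1, 1, 0), 2, 2)
  w <- c(log(3), 0)          # alpha = (0.75, 0.25)
  v <- c(1, -2)
  b <- 0.5
  h <- 0.75 * p1 + 0.25 * p2
  expected <- 1 / (1 + exp(-(h %*% v + b)))
  mo <- ensemble_model(w, v, b)
  expect_equal(ensemble_forward(mo, list(p1, p2)), drop(expected),
               tolerance = 1e-12)

  # m = 1 reduces to a plain sigmoid head on that block
  m1 <- ensemble_model(w = 0.7, head_w = v, head_b = b)
  expect_equal(ensemble_forward(m1, list(p1)),
               drop(1 / (1 + exp(-(p1 %*% v + b)))), tolerance = 1e-12)

  expect_error(ensemble_forward(m0, list(p1)), "expected 2")
  expect_error(ensemble_forward(m0, list(p1, p2[1, , drop = FALSE])),
               "disagree")
})

test_that("the ensemble loss matches hand-computed cross-entropy", {
  expect_equal(ensemble_loss(rep(0.5, 7), rep(c(0, 1), length.out = 7)),
               7 * log(2), tolerance = 1e-12)
  expect_lt(ensemble_loss(c(1, 0), c(1, 0)), 1e-9)  # clipped, near zero
  expect_equal(ensemble_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)),
               tolerance = 1e-12)
  expect_gte(ensemble_loss(runif(5), rbinom(5, 1, 0.5)), 0)
  expect_error(ensemble_loss(0.5, c(1, 0)), "equal length")
})

test_that("low-frequency selection keeps smooth graphs, ranked, deterministically", {
  n <- 100
  mk <- function(acc) data.frame(k = c(20, 50, 100), accuracy = acc)
  curves <- list(
    good_a = mk(c(0.82, 0.82, 0.82)),   # low frequency, strong
    good_b = mk(c(0.74, 0.74, 0.75)),   # low frequency (within margin)
    rising = mk(c(0.55, 0.65, 0.85)),   # high frequency
    flat_chance = mk(c(0.5, 0.5, 0.5))  # never beats chance
  )
  sel <- select_low_frequency_graphs(curves, n = n)
  expect_equal(sel$selected, c("good_a", "good_b"))
  expect_identical(sel$selected, select_low_frequency_graphs(curves, n)$selected)
  sel1 <- select_low_frequency_graphs(curves, n = n, top_m = 1)
  expect_equal(sel1$selected, "good_a")

  all_chance <- list(a = mk(rep(0.5, 3)), b = mk(rep(0.49, 3)))
  expect_error(select_low_frequency_graphs(all_chance, n = n),
               "no graph was categorized low-frequency")
})

make_block_inputs <- function(n = 80, d = 30, gap = 3, m = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  lapply(seq_len(m), function(i) {
    x <- matrix(rnorm(n * d), n, d)
    x[, 1:3] <- x[, 1:3] + gap * y
    x
  }) -> xs
  names(xs) <- sprintf("g%d", seq_len(m))
  list(x_list = xs, y = y)
}

test_that("ensemble training covers every subject with one out-of-fold prediction", {
  dat <- make_block_inputs(seed = 2)
  folds <- stratified_kfold(dat$y, 4, seed = 3)
  fit <- train_ensemble(dat$x_list, dat$y, folds,
                        ensemble_spec(hidden_sizes = c(32, 16), epochs = 40,
                                      seed = 5))
  expect_false(any(is.na(fit$predictions$probability)))
  expect_equal(nrow(fit$predictions), 80)
  expect_equal(sort(unique(fit$predictions$fold)), 1:4)
  # gate normalization holds per fold after training
  for (f in 1:4) {
    a <- fit$gates$alpha[fit$gates$fold == f]
    expect_true(all(a > 0))
    expect_equal(sum(a), 1, tolerance = 1e-10)
  }
  # easy data: high out-of-fold accuracy
  expect_gt(mean(fit$predictions$predicted_label == fit$predictions$true_label),
            0.9)
})

test_that("ensemble training is reproducible under a fixed seed", {
  dat <- make_block_inputs(seed = 11)
  folds <- stratified_kfold(dat$y, 3, seed = 1)
  spec <- ensemble_spec(hidden_sizes = c(16, 8), epochs = 25, seed = 9)
  a <- train_ensemble(dat$x_list, dat$y, folds, spec)
  b <- train_ensemble(dat$x_list, dat$y, folds, spec)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$gates, b$gates)
})

test_that("full-batch training loss is non-increasing in the stable regime", {
  dat <- make_block_inputs(seed = 21)
  folds <- stratified_kfold(dat$y, 2, seed = 4)
  fit <- train_ensemble(dat$x_list, dat$y, folds,
                        ensemble_spec(hidden_sizes = c(32, 16), epochs = 60,
                                      learning_rate = 0.002,
                                      dropout_rate = 0, seed = 7))
  for (hist in fit$loss_history) {
    expect_true(all(diff(hist) <= 1e-3))
    expect_lt(tail(hist, 1), hist[1])
  }
})

test_that("duplicating a block leaves accuracy within a point of the single block", {
  # wide class separation so both runs sit at the same ceiling and the
  # one-point redundancy tolerance is meaningful at this n
  dat <- make_block_inputs(m = 1, d = 15, gap = 6, seed = 31)
  folds <- stratified_kfold(dat$y, 4, seed = 6)
  spec <- ensemble_spec(hidden_sizes = c(32, 16), epochs = 80, seed = 13)
  single <- train_ensemble(dat$x_list, dat$y, folds, spec)
  dup <- train_ensemble(rep(dat$x_list, 4), dat$y, folds, spec)
  acc <- function(fit) mean(fit$predictions$predicted_label ==
                              fit$predictions$true_label)
  expect_lte(abs(acc(single) - acc(dup)), 0.01 + 1e-9)
})

test_that("two-stage training freezes blocks and still classifies", {
  dat <- make_block_inputs(seed = 41)
  folds <- stratified_kfold(dat$y, 3, seed = 2)
  fit <- train_ensemble(dat$x_list, dat$y, folds,
                        ensemble_spec(training = "two_stage",
                                      hidden_sizes = c(32, 16), epochs = 40,
                                      seed = 3))
  expect_gt(mean(fit$predictions$predicted_label == fit$predictions$true_label),
            0.85)
})

test_that("weighted_concat mode fuses at width 64 m", {
  dat <- make_block_inputs(m = 3, seed = 51)
  folds <- stratified_kfold(dat$y, 2, seed = 8)
  fit <- train_ensemble(dat$x_list, dat$y, folds,
                        ensemble_spec(mode = "weighted_concat", epochs = 15,
                                      seed = 4))
  expect_length(fit$models[[1]]$head_w, 64 * 3)
  expect_false(any(is.na(fit$predictions$probability)))
})

test_that("prediction and gate CSV outputs are written", {
  dat <- make_block_inputs(seed = 61)
  folds <- stratified_kfold(dat$y, 2, seed = 1)
  fit <- train_ensemble(dat$x_list, dat$y, folds,
                        ensemble_spec(hidden_sizes = c(8, 4), epochs = 10,
                                      seed = 1))
  dir <- withr::local_tempdir()
  write_ensemble_outputs(fit, file.path(dir, "p.csv"), file.path(dir, "g.csv"))
  p <- read.csv(file.path(dir, "p.csv"))
  expect_equal(names(p), c("subject_id", "fold", "probability",
                           "predicted_label", "true_label"))
  g <- read.csv(file.path(dir, "g.csv"))
  expect_equal(names(g), c("fold", "block", "alpha"))
})
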