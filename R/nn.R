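# Minimal full-batch neural-network machinery (internal).
#
# The learning blocks and the ensemble head are small feed-forward
# networks trained full-batch with Adam.  Everything here operates on
# nested lists of numeric arrays so the same optimizer drives a single
# block and the jointly-trained ensemble.  All randomness (initialization,
# dropout) flows through R's RNG, so callers seed once and get
# reproducible parameters.

#' He-normal initialization for a feed-forward stack
#' Caller must have seeded the RNG.
#' @noRd
nn_init <- function(sizes) {
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

#' Forward pass.  Hidden layers are ReLU with optional inverted dropout;
#' the top layer is linear when `top_linear`, else also ReLU (trunk mode,
#' used for the 64-unit block representations).
#' @noRd
nn_forward <- function(pars, x, dropout = 0, training = FALSE,
                       top_linear = TRUE) {
  n_layers <- length(pars$W)
  a <- vector("list", n_layers + 1L)
  masks <- vector("list", n_layers)
  a[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% pars$W[[l]]
    z <- z + rep(pars$b[[l]], each = nrow(z))
    hidden <- l < n_layers || !top_linear
    h <- if (hidden) relu(z) else z
    if (hidden && training && dropout > 0) {
      m <- matrix(stats::rbinom(length(h), 1L, 1 - dropout),
                  nrow = nrow(h)) / (1 - dropout)
      h <- h * m
      masks[[l]] <- m
    }
    a[[l + 1]] <- h
  }
  list(a = a, masks = masks, out = a[[n_layers + 1L]])
}

#' Backward pass; `dtop` is the gradient at the network output.
#' @noRd
nn_backward <- function(pars, fwd, dtop, top_linear = TRUE) {
  n_layers <- length(pars$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- dtop
  if (!top_linear) {
    delta <- delta * (fwd$a[[n_layers + 1L]] > 0)
    if (!is.null(fwd$masks[[n_layers]])) delta <- delta * fwd$masks[[n_layers]]
  }
  for (l in n_layers:1) {
    gW[[l]] <- crossprod(fwd$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, pars$W[[l]])
      delta <- delta * (fwd$a[[l]] > 0)
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
    }
  }
  list(W = gW, b = gb)
}

#' Apply `f` elementwise across parallel nested lists of arrays
#' @noRd
par_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- vector("list", length(args[[1]]))
    names(out) <- names(args[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(par_map, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

#' @noRd
adam_init <- function(pars) {
  zeros <- par_map(function(x) x * 0, pars)
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam step; returns list(pars, state)
#' @noRd
adam_step <- function(pars, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- par_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  pars <- par_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                  pars, state$m, state$v)
  list(pars = pars, state = state)
}

#' Two-class softmax cross-entropy: mean loss and logit gradient
#' @noRd
softmax_ce <- function(logits, y) {
  shift <- logits - apply(logits, 1L, max)
  expz <- exp(shift)
  p <- expz / rowSums(expz)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(p))
  onehot[idx] <- 1
  list(loss = loss, p = p, dlogits = (p - onehot) / n)
}
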