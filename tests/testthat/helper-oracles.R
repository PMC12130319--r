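# Independent oracles used across the suite. These deliberately re-derive
# results with naive loops / closed forms, not via the package's code paths.

# Brute-force double sum of the split-layer transfer rule.
brute_split_forward <- function(x, W, b, gamma, g = identity) {
  N <- nrow(W)
  D <- N %/% gamma
  b <- rep_len(b, N)
  a <- numeric(D)
  for (n in 0:(D - 1)) {
    acc <- 0
    for (gm in 0:(gamma - 1)) {
      row <- n + gm * D + 1
      for (i in seq_along(x)) acc <- acc + W[row, i] * x[i]
      acc <- acc + b[row]
    }
    a[n + 1] <- acc
  }
  rep(g(a), times = gamma)
}

# Central finite differences of a scalar function of a flat vector.
fd_grad <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# Standalone plain-SGD trainer for a ReLU MLP with softmax cross-entropy.
# Mirrors the protocol (fan-in uniform init, zero biases, per-epoch
# reshuffle under one seed) but is written independently of the package's
# forward/backward.
ref_plain_sgd <- function(splits, layer_sizes, epochs, lr, batch_size, seed) {
  set.seed(seed)
  L <- length(layer_sizes) - 1
  W <- list(); b <- list()
  for (l in 1:L) {
    I <- layer_sizes[l]; N <- layer_sizes[l + 1]
    W[[l]] <- matrix(runif(N * I, -1 / sqrt(I), 1 / sqrt(I)), nrow = N)
    b[[l]] <- numeric(N)
  }
  Xtr <- as.matrix(splits$train$X); ytr <- as.integer(splits$train$y)
  Xte <- as.matrix(splits$test$X); yte <- as.integer(splits$test$y)
  n <- nrow(Xtr)
  test_acc <- numeric(epochs)
  set.seed(seed)  # the run seed governs shuffling, independent of the init draws
  fwd_all <- function(X) {
    H <- list(X)
    for (l in 1:L) {
      Z <- H[[l]] %*% t(W[[l]])
      Z <- sweep(Z, 2, b[[l]], "+")
      H[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
    }
    H
  }
  for (ep in 1:epochs) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      H <- fwd_all(Xtr[idx, , drop = FALSE])
      B <- length(idx)
      Z <- H[[L + 1]]
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z) / rowSums(exp(Z))
      delta <- P
      delta[cbind(1:B, ytr[idx])] <- delta[cbind(1:B, ytr[idx])] - 1
      delta <- delta / B
      for (l in L:1) {
        dW <- crossprod(delta, H[[l]])
        db <- colSums(delta)
        if (l > 1) delta <- (delta %*% W[[l]]) * (H[[l]] > 0)
        W[[l]] <- W[[l]] - lr * dW
        b[[l]] <- b[[l]] - lr * db
      }
    }
    logits <- fwd_all(Xte)[[L + 1]]
    test_acc[ep] <- mean(max.col(logits, ties.method = "first") == yte)
  }
  list(W = W, b = b, test_acc = test_acc)
}

# Evaluate an expression right after seeding the RNG (mirrors the order in
# which seeded package functions draw their first values).
with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# A scale field with every multiplier set to a constant.
half_field <- function(value, shape) {
  f <- sample_gradient_scales(shape, tau = 0, seed = 1)
  f$values[] <- value
  f
}

# Small seeded classification splits for trainer tests.
toy_splits <- function(seed, n_samples = 300, n_classes = 3,
                       n_features = 8, separation = 4) {
  task <- make_classification_task(
    n_classes = n_classes, n_features = n_features,
    n_samples = n_samples, separation = separation, seed = seed
  )
  prepare_splits(task$X, task$y, mode = "two_to_one", seed = seed)
}
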