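#' Initialize a dense feed-forward network
#'
#' Builds a stack of fully connected layers with ReLU (default) hidden
#' activations and a linear output layer (softmax is applied inside the
#' cross-entropy loss). Weights are drawn from the fan-in-scaled uniform
#' distribution `U(-1/sqrt(I), 1/sqrt(I))`; biases are initialized to exactly
#' zero. The init distribution is recorded per layer so weight rejuvenation
#' can redraw from it.
#'
#' With `gamma > 1` every hidden layer becomes a split (multi-synaptic)
#' layer; hidden sizes must then be divisible by `gamma`. The output layer is
#' never split. With `tau` non-`NULL`, a fixed gradient scale field is
#' attached to every trainable parameter array (fuzzy learning rates).
#'
#' @param layer_sizes integer vector of layer widths, input first,
#'   e.g. `c(784, 1000, 10)`.
#' @param activation hidden nonlinearity: `"relu"` (default) or `"tanh"`.
#' @param gamma synapses per neuron pair for hidden layers (weight
#'   splitting); 1 disables splitting.
#' @param tau gradient scaling rate for fuzzy learning rates; `NULL`
#'   disables them.
#' @param fl_distribution sampling family for the scale fields.
#' @param seed integer seed; same seed gives bit-identical parameters.
#' @return an object of class `network_state`.
#' @export
init_network <- function(layer_sizes, activation = "relu", gamma = 1,
                         tau = NULL, fl_distribution = "uniform",
                         seed = NULL) {
  if (length(layer_sizes) < 2) {
    stopf("configuration error: need at least an input and an output size")
  }
  gamma <- as.integer(gamma)
  L <- length(layer_sizes) - 1
  with_seed(seed, {
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      I <- layer_sizes[l]
      N <- layer_sizes[l + 1]
      is_output <- (l == L)
      g_l <- if (is_output) 1L else gamma
      if (N %% g_l != 0L) {
        stopf("configuration error: hidden size %d not divisible by gamma %d", N, g_l)
      }
      limit <- 1 / sqrt(I)
      W <- matrix(stats::runif(N * I, -limit, limit), nrow = N, ncol = I)
      init_spec <- list(dist = "uniform", limit = limit)
      attr(W, "init_spec") <- init_spec
      b <- numeric(N)
      field_W <- if (!is.null(tau)) {
        sample_gradient_scales(c(N, I), tau = tau,
                               distribution = fl_distribution)
      }
      field_b <- if (!is.null(tau)) {
        sample_gradient_scales(N, tau = tau, distribution = fl_distribution)
      }
      layers[[l]] <- list(
        W = W, b = b,
        spec = split_spec(g_l, N),
        activation = if (is_output) "identity" else activation,
        init_spec = init_spec,
        field_W = field_W, field_b = field_b,
        is_output = is_output
      )
    }
    structure(
      list(layers = layers, layer_sizes = as.integer(layer_sizes),
           activation = activation, gamma = gamma, tau = tau, seed = seed),
      class = "network_state"
    )
  })
}

#' Number of trainable parameters
#' @param net a `network_state`.
#' @return integer count of weights plus biases.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# column indices duplicating D distinct outputs gamma times (n + gamma*D layout)
dup_index <- function(D, gamma) rep(seq_len(D), times = gamma)

#' Forward pass of the network on a batch
#'
#' Split layers aggregate weight rows per the block-offset rule and duplicate
#' distinct outputs; plain layers are the standard affine map plus
#' nonlinearity. The returned cache holds every per-layer input and distinct
#' pre-activation, sufficient for exact backpropagation.
#'
#' @param net a `network_state`.
#' @param X batch matrix, samples in rows (`B x I`).
#' @return list with `output` (`B x n_out` logits or predictions) and `cache`.
#' @export
forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$layer_sizes[1]) {
    stopf("dimension error: batch has %d features, network expects %d",
          ncol(X), net$layer_sizes[1])
  }
  H <- X
  cache <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    D <- ly$spec$block_offset
    gam <- ly$spec$gamma
    Z <- H %*% t(ly$W)
    Z <- sweep(Z, 2, ly$b, "+")
    if (gam > 1L) {
      A <- Z[, seq_len(D), drop = FALSE]
      for (g in seq_len(gam - 1L)) {
        A <- A + Z[, g * D + seq_len(D), drop = FALSE]
      }
    } else {
      A <- Z
    }
    Hd <- activation_fn(ly$activation)(A)
    cache[[l]] <- list(input = H, pre = A)
    H <- if (gam > 1L) Hd[, dup_index(D, gam), drop = FALSE] else Hd
  }
  list(output = H, cache = cache)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Mean softmax cross-entropy loss
#' @param logits `B x C` logit matrix.
#' @param y integer class labels in `1..C`.
#' @return scalar mean cross-entropy.
#' @export
cross_entropy <- function(logits, y) {
  P <- softmax_rows(as.matrix(logits))
  -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
}

#' Backward pass: exact gradients for every trainable parameter
#'
#' Computes gradients of the mean loss over the batch -- softmax
#' cross-entropy for classification (`y` a label vector) or mean squared
#' error for regression (`y` a target matrix). Split layers route the
#' duplicated-output gradients back through the block-offset aggregation.
#'
#' @param net a `network_state`.
#' @param fwd the list returned by [forward()] for the same batch.
#' @param y integer labels (`1..C`) or a numeric target matrix.
#' @param loss `"cross_entropy"` or `"mse"`.
#' @return list with `grads` (per layer: `dW`, `db`) and the scalar `loss`.
#' @export
backward <- function(net, fwd, y, loss = c("cross_entropy", "mse")) {
  loss <- match.arg(loss)
  out <- fwd$output
  B <- nrow(out)
  if (loss == "cross_entropy") {
    y <- as.integer(y)
    if (length(y) != B) stopf("usage error: label count != batch size (stale cache?)")
    P <- softmax_rows(out)
    loss_val <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-300)))
    delta <- P
    delta[cbind(seq_len(B), y)] <- delta[cbind(seq_len(B), y)] - 1
    delta <- delta / B
  } else {
    Y <- as.matrix(y)
    if (nrow(Y) != B) stopf("usage error: target rows != batch size (stale cache?)")
    loss_val <- mean((out - Y)^2)
    delta <- 2 * (out - Y) / length(Y)
  }
  grads <- vector("list", length(net$layers))
  dH <- delta  # gradient w.r.t. the layer's (duplicated) output
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    D <- ly$spec$block_offset
    gam <- ly$spec$gamma
    if (gam > 1L) {
      dHd <- dH[, seq_len(D), drop = FALSE]
      for (g in seq_len(gam - 1L)) {
        dHd <- dHd + dH[, g * D + seq_len(D), drop = FALSE]
      }
    } else {
      dHd <- dH
    }
    dA <- dHd * activation_grad(ly$activation, cache_pre(fwd, l))
    dZ <- if (gam > 1L) dA[, dup_index(D, gam), drop = FALSE] else dA
    grads[[l]] <- list(dW = crossprod(dZ, fwd$cache[[l]]$input),
                       db = colSums(dZ))
    if (l > 1) dH <- dZ %*% ly$W
  }
  list(grads = grads, loss = loss_val)
}

cache_pre <- function(fwd, l) fwd$cache[[l]]$pre

#' Predict class labels
#' @param object a `network_state`.
#' @param X feature matrix, samples in rows.
#' @param ... unused.
#' @return integer vector of predicted labels (`1..C`).
#' @export
predict.network_state <- function(object, X, ...) {
  max.col(forward(object, X)$output, ties.method = "first")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state> %s, %d parameters, gamma = %d, fl tau = %s\n",
    paste(x$layer_sizes, collapse = "-"), n_parameters(x), x$gamma,
    if (is.null(x$tau)) "off" else format(x$tau)
  ))
  invisible(x)
}
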