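#' Multi-synaptic split specification for a layer
#'
#' Weight splitting models multi-synaptic connectivity: each pair of neurons
#' is connected by `gamma` synapses instead of one. A split layer with `N`
#' output rows forms only `N / gamma` distinct outputs; output `n` aggregates
#' the weight rows `n, n + D, n + 2D, ...` with block offset
#' `D = floor(N / gamma)`, and the distinct outputs are then duplicated
#' `gamma` times so the layer remains a drop-in replacement with an unchanged
#' trainable parameter count.
#'
#' @param gamma number of synapses per neuron pair (positive integer);
#'   `gamma = 1` reduces to a standard layer.
#' @param n_outputs total number of output units `N`; must be divisible by
#'   `gamma`.
#' @return an object of class `split_spec` with `gamma`, `n_outputs`, and the
#'   derived `block_offset`.
#' @export
split_spec <- function(gamma, n_outputs) {
  if (!is_count(gamma)) stopf("parameter error: gamma must be a positive integer")
  if (!is_count(n_outputs)) stopf("parameter error: n_outputs must be a positive integer")
  gamma <- as.integer(gamma)
  n_outputs <- as.integer(n_outputs)
  if (n_outputs %% gamma != 0L) {
    stopf("configuration error: n_outputs (%d) must be divisible by gamma (%d)",
          n_outputs, gamma)
  }
  structure(
    list(gamma = gamma, n_outputs = n_outputs,
         block_offset = n_outputs %/% gamma),
    class = "split_spec"
  )
}

activation_fn <- function(g) {
  if (is.function(g)) return(g)
  switch(g,
    identity = function(z) z,
    relu     = function(z) pmax(z, 0),
    tanh     = tanh,
    stopf("parameter error: unknown nonlinearity '%s'", g)
  )
}

activation_grad <- function(g, pre) {
  if (is.function(g)) stopf("parameter error: gradients need a named nonlinearity")
  switch(g,
    identity = array(1, dim = dim(as.matrix(pre))),
    relu     = (pre > 0) * 1,
    tanh     = 1 - tanh(pre)^2,
    stopf("parameter error: unknown nonlinearity '%s'", g)
  )
}

#' Forward pass through a split (multi-synaptic) dense layer
#'
#' Computes, for each distinct output `n` in `0 .. N/gamma - 1`, the
#' aggregated pre-activation
#' \deqn{a_n = \sum_{\gamma=0}^{\Gamma-1} \sum_i W[n + \gamma D, i]\, x_i
#'       + \sum_{\gamma=0}^{\Gamma-1} b[n + \gamma D],}
#' with block offset `D = floor(N / gamma)` (synapse transfer is the
#' identity and aggregation is the sum), applies the nonlinearity `g`, and
#' duplicates the `N/gamma` distinct outputs `gamma` times to return a
#' length-`N` output. With `gamma = 1` this is the standard dense forward
#' pass.
#'
#' @param x input vector of length `I`.
#' @param W weight matrix, `N x I`.
#' @param b bias vector of length `N` (or a scalar, recycled).
#' @param spec a [split_spec()] with `n_outputs == nrow(W)`.
#' @param g nonlinearity: `"identity"`, `"relu"`, `"tanh"`, or a function.
#' @return output vector of length `N` containing `N/gamma` distinct values,
#'   each repeated `gamma` times.
#' @export
split_forward <- function(x, W, b = 0, spec = split_spec(1, nrow(W)),
                          g = "identity") {
  W <- as.matrix(W)
  N <- nrow(W)
  if (spec$n_outputs != N) {
    stopf("dimension error: spec$n_outputs (%d) != nrow(W) (%d)", spec$n_outputs, N)
  }
  if (length(x) != ncol(W)) {
    stopf("dimension error: length(x) (%d) != ncol(W) (%d)", length(x), ncol(W))
  }
  b <- rep_len(b, N)
  D <- spec$block_offset
  z <- as.vector(W %*% x) + b
  a <- rowSums(matrix(z, nrow = D, ncol = spec$gamma))  # z[n + gamma*D] blocks
  out <- activation_fn(g)(a)
  rep(out, times = spec$gamma)
}

#' Backward pass through a split dense layer
#'
#' Exact chain rule for the composition in [split_forward()]: the upstream
#' gradients of the `gamma` duplicated copies of each distinct output are
#' summed into that output's pre-activation gradient, every weight row
#' `n + gamma * D` receives the gradient of group `n`, and the input gradient
#' aggregates over all rows.
#'
#' @param upstream gradient of the loss w.r.t. the length-`N` duplicated
#'   output vector.
#' @param x,W,b,spec,g as in [split_forward()].
#' @return list with `dW` (`N x I`), `db` (length `N`), `dx` (length `I`).
#' @export
split_gradients <- function(upstream, x, W, b = 0,
                            spec = split_spec(1, nrow(W)), g = "identity") {
  W <- as.matrix(W)
  N <- nrow(W)
  if (length(upstream) != N) {
    stopf("dimension error: length(upstream) (%d) != N (%d)", length(upstream), N)
  }
  if (length(x) != ncol(W)) {
    stopf("dimension error: length(x) (%d) != ncol(W) (%d)", length(x), ncol(W))
  }
  b <- rep_len(b, N)
  D <- spec$block_offset
  z <- as.vector(W %*% x) + b
  a <- rowSums(matrix(z, nrow = D, ncol = spec$gamma))
  # duplicated copies of group n all feed the same distinct output
  du <- rowSums(matrix(upstream, nrow = D, ncol = spec$gamma))
  da <- du * as.vector(activation_grad(g, a))
  dz <- rep(da, times = spec$gamma)  # row n + gamma*D gets group n's gradient
  list(
    dW = outer(dz, x),
    db = dz,
    dx = as.vector(crossprod(W, dz))
  )
}
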