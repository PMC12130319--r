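# Matrix-free Hessian extreme-eigenvalue estimation and 2-D loss-surface
# instrumentation (filter-normalized random directions, MinMax-ratio maps).

# Hessian-vector product by central finite differences of the gradient.
hvp <- function(grad_fn, w, v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v)
  eps <- sqrt(.Machine$double.eps) * (1 + sqrt(sum(w^2))) / nv
  (grad_fn(w + eps * v) - grad_fn(w - eps * v)) / (2 * eps)
}

power_iteration <- function(apply_op, n, tol, max_iter, v0) {
  v <- v0 / sqrt(sum(v0^2))
  lambda <- 0
  resid <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Hv <- apply_op(v)
    lambda <- sum(v * Hv)                       # Rayleigh quotient
    resid <- sqrt(sum((Hv - lambda * v)^2)) / max(abs(lambda), 1e-30)
    if (resid < tol) break
    nHv <- sqrt(sum(Hv^2))
    if (nHv == 0) break                          # operator annihilates v
    v <- Hv / nHv
  }
  list(lambda = lambda, v = v, resid = resid, iters = iters)
}

#' Extreme Hessian eigenvalues by matrix-free power iteration
#'
#' Estimates the largest and smallest (most negative) eigenvalues of the
#' loss Hessian at a parameter point without forming the Hessian:
#' Hessian-vector products come from central finite differences of the
#' supplied gradient oracle. The dominant-magnitude eigenvalue is found by
#' power iteration; the opposite extreme by power iteration on the spectrally
#' shifted operator `H - lambda1 I`, un-shifted afterwards. The MinMax ratio
#' `|lambda_min| / |lambda_max|` quantifies local non-convexity: lower
#' ratios indicate a more convex surface.
#'
#' @param grad_fn gradient oracle: takes a flat parameter vector, returns
#'   the loss gradient.
#' @param point flat parameter vector at which to evaluate.
#' @param tol relative residual tolerance for convergence.
#' @param max_iter maximum power-iteration steps per extreme.
#' @param seed integer seed for the random start vectors.
#' @return an object of class `spectrum_report` with `lambda_max`,
#'   `lambda_min`, `ratio`, `iterations`, `residuals`, `converged`
#'   (non-convergence is flagged, not an error).
#' @export
extreme_eigenvalues <- function(grad_fn, point, tol = 1e-6, max_iter = 500,
                                seed = 1) {
  if (!is.function(grad_fn)) stopf("usage error: grad_fn must be a function")
  g0 <- grad_fn(point)
  if (length(g0) != length(point) || !all(is.finite(g0))) {
    stopf("usage error: gradient oracle returned an invalid gradient")
  }
  n <- length(point)
  with_seed(seed, {
    v1 <- stats::rnorm(n)
    v2 <- stats::rnorm(n)
    p1 <- power_iteration(function(v) hvp(grad_fn, point, v),
                          n, tol, max_iter, v1)
    shifted <- function(v) hvp(grad_fn, point, v) - p1$lambda * v
    p2 <- power_iteration(shifted, n, tol, max_iter, v2)
    other <- p2$lambda + p1$lambda
    lambda_max <- max(p1$lambda, other)
    lambda_min <- min(p1$lambda, other)
    structure(
      list(
        lambda_max = lambda_max, lambda_min = lambda_min,
        ratio = abs(lambda_min) / max(abs(lambda_max), 1e-30),
        iterations = c(p1$iters, p2$iters),
        residuals = c(p1$resid, p2$resid),
        converged = (p1$resid < tol) && (p2$resid < tol)
      ),
      class = "spectrum_report"
    )
  })
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf(
    "<spectrum_report> lambda_max %.6g, lambda_min %.6g, ratio %.4f%s\n",
    x$lambda_max, x$lambda_min, x$ratio,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

# Flatten / restore all trainable parameters of a network_state.
flatten_params <- function(net) {
  unlist(lapply(net$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

unflatten_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$layers)) {
    nw <- length(net$layers[[l]]$W)
    nb <- length(net$layers[[l]]$b)
    W <- matrix(theta[pos + seq_len(nw)], nrow = nrow(net$layers[[l]]$W))
    attr(W, "init_spec") <- net$layers[[l]]$init_spec
    net$layers[[l]]$W <- W
    net$layers[[l]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  net
}

#' Loss and gradient oracles of a network on a fixed batch
#'
#' Closures over flat parameter vectors, for use with
#' [extreme_eigenvalues()] and [loss_surface()].
#'
#' @param net a `network_state` providing the architecture.
#' @param X,y the evaluation batch.
#' @param loss `"cross_entropy"` or `"mse"`.
#' @return list with functions `loss(theta)` and `grad(theta)` and the
#'   reference point `theta0 = flatten_params(net)`.
#' @export
net_loss_oracles <- function(net, X, y, loss = "cross_entropy") {
  X <- as.matrix(X)
  list(
    loss = function(theta) {
      m <- unflatten_params(net, theta)
      fwd <- forward(m, X)
      if (loss == "cross_entropy") cross_entropy(fwd$output, y)
      else mean((fwd$output - as.matrix(y))^2)
    },
    grad = function(theta) {
      m <- unflatten_params(net, theta)
      fwd <- forward(m, X)
      flatten_grads(backward(m, fwd, y, loss = loss)$grads)
    },
    theta0 = flatten_params(net)
  )
}

# Draw one filter-normalized random direction: per weight row (filter) and
# per bias vector, the direction's norm is rescaled to match the parameter's.
filter_normalized_direction <- function(net) {
  dirs <- lapply(net$layers, function(l) {
    Dw <- matrix(stats::rnorm(length(l$W)), nrow = nrow(l$W))
    for (r in seq_len(nrow(Dw))) {
      dn <- sqrt(sum(Dw[r, ]^2))
      wn <- sqrt(sum(l$W[r, ]^2))
      Dw[r, ] <- if (dn == 0) 0 else Dw[r, ] / dn * wn   # zero-norm filter zeroed
    }
    db <- stats::rnorm(length(l$b))
    dn <- sqrt(sum(db^2))
    bn <- sqrt(sum(l$b^2))
    db <- if (dn == 0 || bn == 0) rep(0, length(l$b)) else db / dn * bn
    c(as.vector(Dw), db)
  })
  unlist(dirs, use.names = FALSE)
}

#' Loss surface on a 2-D filter-normalized random plane
#'
#' Draws two seeded random directions, rescales each per filter so its norm
#' matches the corresponding parameter norms (filter normalization), and
#' evaluates the loss on a regular `(alpha, beta)` grid centered at the
#' network's current parameters. Optionally attaches a Hessian MinMax
#' spectrum report per grid point, supporting ratio maps, histograms, and
#' median summaries.
#'
#' @param net a `network_state` at the reference point (e.g. trained).
#' @param X,y evaluation batch defining the loss.
#' @param n_grid grid points per axis (`>= 3`).
#' @param extent half-width of the grid in direction units.
#' @param seed integer seed for the directions.
#' @param with_spectrum also compute a `spectrum_report` per grid point.
#' @param loss `"cross_entropy"` or `"mse"`.
#' @param spectrum_tol,spectrum_max_iter controls for the per-point power
#'   iteration.
#' @return an object of class `landscape_grid`: `alpha`, `beta` (axis
#'   coordinates), `loss` (`n_grid x n_grid` matrix, `[i, j]` at
#'   `(alpha[i], beta[j])`), `ratio` (matrix or `NULL`), `spectra`,
#'   `directions`, `center_loss`.
#' @export
loss_surface <- function(net, X, y, n_grid = 11, extent = 1, seed = 1,
                         with_spectrum = FALSE, loss = "cross_entropy",
                         spectrum_tol = 1e-4, spectrum_max_iter = 200) {
  if (n_grid < 3) stopf("parameter error: n_grid must be >= 3")
  oracles <- net_loss_oracles(net, X, y, loss = loss)
  dirs <- with_seed(seed, list(
    d1 = filter_normalized_direction(net),
    d2 = filter_normalized_direction(net)
  ))
  alpha <- seq(-extent, extent, length.out = n_grid)
  beta <- alpha
  loss_mat <- matrix(NA_real_, n_grid, n_grid)
  ratio_mat <- if (with_spectrum) matrix(NA_real_, n_grid, n_grid)
  spectra <- if (with_spectrum) vector("list", n_grid * n_grid)
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      theta <- oracles$theta0 + alpha[i] * dirs$d1 + beta[j] * dirs$d2
      loss_mat[i, j] <- oracles$loss(theta)
      if (with_spectrum) {
        sp <- extreme_eigenvalues(oracles$grad, theta, tol = spectrum_tol,
                                  max_iter = spectrum_max_iter, seed = seed)
        ratio_mat[i, j] <- sp$ratio
        spectra[[(i - 1) * n_grid + j]] <- sp
      }
    }
  }
  structure(
    list(
      alpha = alpha, beta = beta, loss = loss_mat, ratio = ratio_mat,
      spectra = spectra, directions = dirs,
      center_loss = loss_mat[(n_grid + 1) %/% 2, (n_grid + 1) %/% 2]
    ),
    class = "landscape_grid"
  )
}

#' Summarize the MinMax-ratio map of a landscape grid
#'
#' @param grid a [loss_surface()] result computed with
#'   `with_spectrum = TRUE`.
#' @param breaks histogram breaks for the ratios.
#' @return list with `median_ratio`, `ratios` (vector), and `histogram`
#'   (counts per bin).
#' @export
ratio_summary <- function(grid, breaks = seq(0, 1, by = 0.1)) {
  if (is.null(grid$ratio)) {
    stopf("usage error: grid was computed without spectra")
  }
  r <- as.vector(grid$ratio)
  list(
    median_ratio = stats::median(r),
    ratios = r,
    histogram = table(cut(pmin(r, max(breaks)), breaks, include.lowest = TRUE))
  )
}

#' Export a landscape grid as a long-format data frame
#' @param grid a [loss_surface()] result.
#' @return data frame with columns `alpha`, `beta`, `loss`, and `ratio`.
#' @export
landscape_as_df <- function(grid) {
  n <- length(grid$alpha)
  data.frame(
    alpha = rep(grid$alpha, each = n),
    beta = rep(grid$beta, times = n),
    loss = as.vector(t(grid$loss)),
    ratio = if (is.null(grid$ratio)) NA_real_ else as.vector(t(grid$ratio))
  )
}
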