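#' Normalized reconstruction error (percent)
#'
#' Error of a reconstructed batch relative to its target, anchored so that
#' 100\% denotes a difference of the same size as the target itself:
#' \deqn{\mathrm{error} = 100 \cdot
#'   \frac{\mathrm{mean}((recon - target)^2)}{\mathrm{mean}(target^2)}.}
#' A perfect reconstruction scores 0\%; an all-zero reconstruction scores
#' exactly 100\%.
#'
#' @param recon reconstructed array.
#' @param target ground-truth array, same shape, not all zero.
#' @return scalar error in percent, `>= 0`.
#' @export
reconstruction_error <- function(recon, target) {
  check_same_shape(recon, target, "recon", "target")
  denom <- mean(target^2)
  if (denom == 0) {
    stopf("undefined-metric error: all-zero target in reconstruction_error")
  }
  100 * (mean((recon - target)^2) / denom)
}

#' Attack configuration for gradient inversion
#'
#' @param n_steps maximum optimization steps per restart.
#' @param step_size initial step size of the adaptive gradient descent.
#' @param objective gradient-matching objective: squared L2 distance
#'   (default) or negative cosine similarity.
#' @param init dummy-batch initialization family.
#' @param restarts independent restarts; the best (lowest final objective)
#'   is reported.
#' @param seed integer seed; the whole attack is deterministic given it.
#' @return an object of class `attack_config`.
#' @export
attack_config <- function(n_steps = 300, step_size = 0.1,
                          objective = c("squared_l2", "cosine"),
                          init = c("gaussian", "uniform"),
                          restarts = 2, seed = 1) {
  objective <- match.arg(objective)
  init <- match.arg(init)
  if (!is_count(n_steps)) stopf("parameter error: n_steps must be >= 1")
  if (!is_count(restarts)) stopf("parameter error: restarts must be >= 1")
  structure(
    list(n_steps = as.integer(n_steps), step_size = step_size,
         objective = objective, init = init,
         restarts = as.integer(restarts), seed = as.integer(seed)),
    class = "attack_config"
  )
}

flatten_grads <- function(grads) {
  unlist(lapply(grads, function(g) c(as.vector(g$dW), g$db)), use.names = FALSE)
}

#' Gradients of a network on a batch (attacker's observable)
#'
#' One forward/backward pass; what a federated-learning participant would
#' share.
#'
#' @param net a `network_state`.
#' @param X batch matrix, samples in rows.
#' @param y integer labels.
#' @return per-layer gradient list as from [backward()].
#' @export
observe_gradients <- function(net, X, y) {
  fwd <- forward(net, X)
  backward(net, fwd, y)$grads
}

matching_objective <- function(net, x_flat, batch_dim, y, g_obs_flat,
                               objective) {
  X <- matrix(x_flat, ncol = batch_dim)
  g <- flatten_grads(observe_gradients(net, X, y))
  if (objective == "squared_l2") {
    sum((g - g_obs_flat)^2)
  } else {
    ng <- sqrt(sum(g^2))
    no <- sqrt(sum(g_obs_flat^2))
    if (ng == 0 || no == 0) return(1)
    1 - sum(g * g_obs_flat) / (ng * no)
  }
}

#' Optimization-based gradient-inversion attack
#'
#' Reconstructs a private training batch from its shared gradients by
#' gradient matching: a dummy batch is optimized so its gradients match the
#' observed ones (squared-L2 by default), using adaptive-step gradient
#' descent with central-finite-difference gradients of the matching
#' objective, known labels, and multiple restarts. Accepted steps never
#' increase the objective. Batch size 1 is the default experimental setting
#' (the hardest case for the defense).
#'
#' @param net the attacked `network_state` (trained or untrained).
#' @param observed gradients from [observe_gradients()] on the secret batch.
#' @param y labels of the secret batch (assumed known).
#' @param config an [attack_config()].
#' @param batch_size number of rows in the secret batch.
#' @param target optional secret batch; when given, the report carries its
#'   normalized reconstruction error.
#' @return an object of class `reconstruction_report`: `recon` (best dummy
#'   batch), `objective` (its final matching loss), `per_restart`
#'   (final objective per restart), `error_percent` (or `NA`), `config`.
#' @export
invert_gradients <- function(net, observed, y, config = attack_config(),
                             batch_size = length(y), target = NULL) {
  g_obs <- flatten_grads(observed)
  d <- net$layer_sizes[1]
  n_var <- batch_size * d
  with_seed(config$seed, {
    best <- NULL
    per_restart <- numeric(config$restarts)
    for (r in seq_len(config$restarts)) {
      x <- switch(config$init,
        gaussian = stats::rnorm(n_var, sd = 0.5),
        uniform  = stats::runif(n_var, -1, 1)
      )
      obj <- function(v) matching_objective(net, v, d, y, g_obs, config$objective)
      f <- obj(x)
      if (!is.finite(f)) {
        per_restart[r] <- Inf
        next
      }
      step <- config$step_size
      for (it in seq_len(config$n_steps)) {
        grad <- fd_gradient(obj, x, f)
        gn <- sqrt(sum(grad^2))
        if (gn < 1e-14) break
        accepted <- FALSE
        while (step > 1e-12) {
          x_new <- x - step * grad
          f_new <- obj(x_new)
          if (is.finite(f_new) && f_new <= f) {
            x <- x_new
            f <- f_new
            step <- step * 1.5
            accepted <- TRUE
            break
          }
          step <- step / 2
        }
        if (!accepted || f < 1e-18) break
      }
      per_restart[r] <- f
      if (is.null(best) || f < best$f) best <- list(x = x, f = f)
    }
    if (is.null(best)) {
      stopf("attack error: all restarts produced non-finite objectives")
    }
    recon <- matrix(best$x, nrow = batch_size)
    structure(
      list(
        recon = recon, objective = best$f, per_restart = per_restart,
        error_percent = if (is.null(target)) NA_real_ else
          reconstruction_error(recon, as.matrix(target)),
        config = config
      ),
      class = "reconstruction_report"
    )
  })
}

# central finite differences of a scalar objective
fd_gradient <- function(f, x, f0, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x
    xm <- x
    xp[i] <- x[i] + hi
    xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

#' Closed-form single-layer inversion oracle
#'
#' For a single dense layer with cross-entropy loss and a batch of one, the
#' weight gradient is the outer product of the logit error and the input
#' (`dW = delta x^T`, `db = delta`), so the input is recovered exactly as
#' any row `dW[i, ] / db[i]` with a nonzero `db[i]`. Serves as the analytic
#' check on the optimization-based attack.
#'
#' @param observed gradient list for the single layer.
#' @return the recovered input vector.
#' @export
single_layer_inversion <- function(observed) {
  dW <- observed[[1]]$dW
  db <- observed[[1]]$db
  i <- which.max(abs(db))
  if (abs(db[i]) == 0) stopf("attack error: all bias gradients are zero")
  as.vector(dW[i, ]) / db[i]
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_report> objective %.3g, error %s%%, %d restart(s)\n",
    x$objective,
    ifelse(is.na(x$error_percent), "NA", sprintf("%.2f", x$error_percent)),
    length(x$per_restart)
  ))
  invisible(x)
}
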