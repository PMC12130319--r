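#' Sample a gradient scale field (fuzzy learning rates)
#'
#' Draws a fixed field of per-parameter gradient multipliers, one per entry of
#' the target parameter array. Each multiplier acts as a constant random
#' factor on that parameter's gradient during training, so every synapse
#' effectively trains with its own learning rate -- a lightweight model of the
#' diversity of synaptic plasticity observed in biological networks.
#'
#' The default family is uniform on `[1 - tau/2, 1 + tau/2]`, where `tau` is
#' the gradient scaling rate. The alternative families (normal, lognormal,
#' geometric, beta) are standardized to the same mean 1 and standard deviation
#' `tau/sqrt(12)` as the uniform family, so `tau` controls the spread
#' identically across families.
#'
#' Fields are sampled once, at network initialization, and never modified
#' afterwards; reproducibility is guaranteed by `seed`.
#'
#' @param shape integer vector, the shape of the target parameter array
#'   (a single length for vectors, `c(nrow, ncol)` for matrices).
#' @param tau gradient scaling rate, in `[0, 2)` for the uniform family so
#'   that all multipliers stay strictly positive. `tau = 0` gives the
#'   constant field of ones (plain SGD).
#' @param distribution one of `"uniform"`, `"normal"`, `"lognormal"`,
#'   `"geometric"`, `"beta"`.
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return an object of class `gradient_scale_field` with elements `values`
#'   (array of multipliers with shape `shape`), `tau`, `distribution`, `seed`.
#' @examples
#' f <- sample_gradient_scales(c(4, 3), tau = 0.09, seed = 1)
#' range(f$values)  # within [0.955, 1.045]
#' @export
sample_gradient_scales <- function(shape, tau = 0.09,
                                   distribution = c("uniform", "normal",
                                                    "lognormal", "geometric",
                                                    "beta"),
                                   seed = NULL) {
  distribution <- match.arg(distribution)
  shape <- as.integer(shape)
  if (length(shape) == 0 || any(shape < 1)) {
    stopf("parameter error: shape must be a non-empty vector of positive sizes")
  }
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau < 0) {
    stopf("parameter error: tau must be a finite non-negative number")
  }
  if (distribution == "uniform" && tau >= 2) {
    stopf("parameter error: uniform fields need tau in [0, 2) for positive multipliers (got %g)", tau)
  }
  n <- prod(shape)
  target_sd <- tau / sqrt(12)
  values <- with_seed(seed, {
    if (distribution == "uniform") {
      stats::runif(n, min = 1 - tau / 2, max = 1 + tau / 2)
    } else {
      # standardize each family to mean 1, sd tau/sqrt(12)
      raw <- switch(distribution,
        normal    = stats::rnorm(n),
        lognormal = stats::rlnorm(n, meanlog = 0, sdlog = 0.5),
        geometric = stats::rgeom(n, prob = 0.5),
        beta      = stats::rbeta(n, 2, 2)
      )
      mu <- switch(distribution,
        normal    = 0,
        lognormal = exp(0.5^2 / 2),
        geometric = 1,           # (1-p)/p at p = 0.5
        beta      = 0.5
      )
      sd0 <- switch(distribution,
        normal    = 1,
        lognormal = sqrt((exp(0.25) - 1) * exp(0.25)),
        geometric = sqrt(2),     # sqrt((1-p))/p at p = 0.5
        beta      = sqrt(0.05)   # ab/((a+b)^2 (a+b+1))
      )
      1 + (raw - mu) / sd0 * target_sd
    }
  })
  values <- array(values, dim = shape)
  if (length(shape) == 1) values <- as.vector(values)
  structure(
    list(values = values, tau = tau, distribution = distribution, seed = seed),
    class = "gradient_scale_field"
  )
}

#' One SGD step with fuzzy per-parameter learning rates
#'
#' Applies `param - eta * (grad * field$values)` elementwise: the update of a
#' plain SGD step, with each gradient component rescaled by its fixed
#' multiplier. With a field of ones this is exactly plain SGD.
#'
#' @param param parameter array.
#' @param grad gradient array, same shape as `param`.
#' @param eta global learning rate.
#' @param field a [sample_gradient_scales()] field whose `values` match
#'   `param` in shape, or `NULL` for a plain step.
#' @return the updated parameter array; inputs are not modified.
#' @export
fuzzy_sgd_step <- function(param, grad, eta, field = NULL) {
  check_same_shape(param, grad, "param", "grad")
  if (!all(is.finite(grad))) {
    stopf("numeric error: gradient contains non-finite values")
  }
  if (is.null(field)) {
    return(param - eta * grad)
  }
  if (!inherits(field, "gradient_scale_field")) {
    stopf("parameter error: field must be a gradient_scale_field or NULL")
  }
  check_same_shape(param, field$values, "param", "field$values")
  param - eta * (grad * field$values)
}

#' @export
print.gradient_scale_field <- function(x, ...) {
  d <- if (is.null(dim(x$values))) length(x$values) else dim(x$values)
  cat(sprintf(
    "<gradient_scale_field> %s, tau = %g, shape = (%s), range [%.4f, %.4f]\n",
    x$distribution, x$tau, paste(d, collapse = ","),
    min(x$values), max(x$values)
  ))
  invisible(x)
}
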