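#' Per-weight rejuvenation probability
#'
#' Probability that a weight is spontaneously reinitialized, modeled on the
#' size-dependent survival of dendritic spines: small weights are likely to be
#' reset, large weights survive. The probability is the Gaussian survival
#' function of the weight magnitude on a scale set by the layer's largest
#' weight,
#' \deqn{P(\mathrm{rejuvenate}) = 1 - \Phi(|w| / \sigma_{re}), \qquad
#'       \sigma_{re} = |w_{max} / d_{re}|,}
#' with \eqn{\Phi} the standard normal CDF and \eqn{d_{re}} the rejuvenation
#' distance factor. At `d_re = 1` the layer's maximal weight is reset with
#' probability `1 - pnorm(1)` (about 16\%); at the default `d_re = 14` the
#' maximal weight is essentially never reset while a weight of 0.02 (with
#' `w_max = 1`) is reset with probability about 39\%.
#'
#' A degenerate all-zero layer (`w_max = 0`) returns 0.5 for every weight,
#' the continuity limit of the survival function at 0.
#'
#' @param w weight value(s); only the magnitude matters (vectorized).
#' @param w_max the layer's maximum absolute weight, `>= 0`.
#' @param d_re rejuvenation distance factor, `> 0`.
#' @return probability (vector) in `[0, 1]`, non-increasing in `|w|`.
#' @examples
#' rejuvenation_probability(1, 1, 1)        # ~0.159
#' rejuvenation_probability(0.02, 1, 14)    # ~0.390
#' rejuvenation_probability(1, 1, 14)       # ~0
#' @export
rejuvenation_probability <- function(w, w_max, d_re) {
  if (!is.numeric(d_re) || length(d_re) != 1 || !is.finite(d_re) || d_re <= 0) {
    stopf("parameter error: d_re must be a positive number")
  }
  if (!is.numeric(w_max) || length(w_max) != 1 || w_max < 0) {
    stopf("parameter error: w_max must be a non-negative number")
  }
  if (w_max == 0) {
    return(rep(0.5, length(w)))
  }
  sigma_re <- abs(w_max / d_re)
  stats::pnorm(abs(w) / sigma_re, lower.tail = FALSE)
}

#' Construct a rejuvenation policy
#'
#' Bundles the rejuvenation distance factor with the rules of application:
#' which parameter roles are eligible (weight matrices by default; biases are
#' zero-initialized and excluded) and which distribution fresh weights are
#' drawn from (defaults to the owning layer's recorded initialization
#' distribution). The location parameter of the survival function is fixed at
#' zero.
#'
#' @param d_re rejuvenation distance factor, positive; default 14.
#' @param reinit_spec optional init spec (see [init_network()]) overriding the
#'   layer's own; `NULL` keeps the layer's recorded spec.
#' @param applies_to parameter roles eligible for rejuvenation.
#' @return an object of class `rejuvenation_policy`.
#' @export
rejuvenation_policy <- function(d_re = 14, reinit_spec = NULL,
                                applies_to = "weight") {
  if (!is.numeric(d_re) || length(d_re) != 1 || !is.finite(d_re) || d_re <= 0) {
    stopf("parameter error: d_re must be a positive number")
  }
  structure(
    list(d_re = d_re, reinit_spec = reinit_spec,
         applies_to = applies_to, mu = 0),
    class = "rejuvenation_policy"
  )
}

# Draw n values from a recorded init spec (list(dist=, ...)).
draw_from_init_spec <- function(spec, n) {
  if (is.null(spec) || is.null(spec$dist)) {
    stopf("configuration error: layer has no recorded init spec for rejuvenation redraws")
  }
  switch(spec$dist,
    uniform = stats::runif(n, min = -spec$limit, max = spec$limit),
    normal  = stats::rnorm(n, mean = 0, sd = spec$sd),
    stopf("configuration error: unknown init distribution '%s'", spec$dist)
  )
}

#' Apply weight rejuvenation to a set of layers
#'
#' For each layer, recomputes the maximum absolute weight, evaluates each
#' weight's rejuvenation probability, and independently replaces selected
#' weights with fresh draws from the layer's initialization distribution.
#' Non-replaced entries are returned bit-identical; boolean masks mark exactly
#' the replaced entries. Intended to run once per optimizer step, after the
#' parameter update.
#'
#' @param params list of weight arrays (one per layer), each carrying an init
#'   spec either in `init_specs` or as an attribute `"init_spec"`.
#' @param policy a [rejuvenation_policy()].
#' @param init_specs optional list of init specs parallel to `params`; used
#'   when the arrays carry none, overridden by `policy$reinit_spec`.
#' @param seed integer seed; `NULL` uses the current RNG stream (the trainer
#'   seeds the stream once per run).
#' @return list with `params` (updated arrays) and `masks` (logical arrays of
#'   the replaced entries, same shapes).
#' @export
apply_rejuvenation <- function(params, policy, init_specs = NULL, seed = NULL) {
  if (!inherits(policy, "rejuvenation_policy")) {
    stopf("parameter error: policy must be a rejuvenation_policy")
  }
  if (!is.list(params)) params <- list(params)
  with_seed(seed, {
    masks <- vector("list", length(params))
    for (k in seq_along(params)) {
      W <- params[[k]]
      spec <- policy$reinit_spec
      if (is.null(spec)) spec <- attr(W, "init_spec")
      if (is.null(spec) && !is.null(init_specs)) spec <- init_specs[[k]]
      if (is.null(spec)) {
        stopf("configuration error: layer %d has no init spec for rejuvenation redraws", k)
      }
      w_max <- max(abs(W))
      p <- rejuvenation_probability(as.vector(W), w_max, policy$d_re)
      hit <- stats::runif(length(p)) < p
      if (any(hit)) {
        W[hit] <- draw_from_init_spec(spec, sum(hit))
      }
      mask <- array(hit, dim = if (is.null(dim(W))) length(W) else dim(W))
      if (is.null(dim(params[[k]]))) mask <- as.vector(mask)
      params[[k]] <- W
      masks[[k]] <- mask
    }
    list(params = params, masks = masks)
  })
}
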