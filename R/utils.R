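# Internal helpers shared across modules.

#' Run an expression with a locally seeded RNG
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the surrounding random stream. With `seed = NULL` the expression
#' runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_same_shape <- function(a, b, what_a, what_b) {
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stopf(
      "dimension error: %s has shape (%s) but %s has shape (%s)",
      what_a, paste(da, collapse = ","), what_b, paste(db, collapse = ",")
    )
  }
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 1
}
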