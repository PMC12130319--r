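#' Generate a separable-but-noisy Gaussian classification task
#'
#' Class means sit at the vertices of a regular simplex with pairwise
#' distance `separation` (in units of the unit noise sigma), randomly rotated
#' into the feature space; samples are the means plus standard normal noise.
#' Labels are balanced to within one sample. With `separation = 0` the
#' classes are indistinguishable (Bayes accuracy `1/n_classes`); for two
#' classes the Bayes accuracy is `pnorm(separation / 2)`.
#'
#' @param n_classes number of classes `K` (requires
#'   `n_features >= n_classes - 1` for the simplex embedding).
#' @param n_features feature dimension.
#' @param n_samples total sample count, `>= n_classes`.
#' @param separation pairwise distance between class means, in noise-sigma
#'   units.
#' @param label_noise fraction of labels reassigned uniformly at random.
#' @param seed integer seed; identical seeds give identical arrays.
#' @return list with `X` (`n_samples x n_features`), `y` (integer labels
#'   `1..K`), and `means` (`K x n_features` true class means).
#' @export
make_classification_task <- function(n_classes = 3, n_features = 16,
                                     n_samples = 900, separation = 4,
                                     label_noise = 0, seed = NULL) {
  if (!is_count(n_classes) || !is_count(n_features) || !is_count(n_samples)) {
    stopf("parameter error: sizes must be positive integers")
  }
  if (n_samples < n_classes) {
    stopf("parameter error: n_samples (%d) < n_classes (%d)", n_samples, n_classes)
  }
  if (n_features < n_classes - 1) {
    stopf("parameter error: need n_features >= n_classes - 1 for the simplex")
  }
  with_seed(seed, {
    # regular simplex with unit pairwise distance in (K-1) dims
    K <- n_classes
    M <- diag(K) - 1 / K                      # K points, pairwise distance sqrt(2)
    sv <- svd(M)
    simplex <- sv$u[, seq_len(K - 1), drop = FALSE] %*%
      diag(sv$d[seq_len(K - 1)], K - 1)
    simplex <- simplex / sqrt(2) * separation # exact pairwise distance
    # random rotation into feature space
    Q <- qr.Q(qr(matrix(stats::rnorm(n_features * (K - 1)), n_features)))
    means <- simplex %*% t(Q[, seq_len(K - 1), drop = FALSE])
    y <- rep(seq_len(K), length.out = n_samples)
    y <- sample(y)                            # balanced within 1 sample
    X <- means[y, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_features), n_samples)
    if (label_noise > 0) {
      flip <- stats::runif(n_samples) < label_noise
      y[flip] <- sample.int(K, sum(flip), replace = TRUE)
    }
    list(X = X, y = y, means = means)
  })
}

#' Procedural small-image classification task
#'
#' Desk-scale stand-in for natural image datasets: each class is a smooth
#' 2-D Gaussian bump at a class-specific position on a `side x side` grid,
#' plus pixel noise, clipped to `[0, 1]`. Used mainly by the
#' gradient-inversion experiments, which need image-shaped inputs.
#'
#' @param n_samples number of images.
#' @param side image side length (images are `side^2`-dimensional rows).
#' @param n_classes number of bump positions / classes.
#' @param noise_sd pixel noise standard deviation.
#' @param seed integer seed.
#' @return list with `X` (`n_samples x side^2`, values in `[0,1]`), `y`,
#'   and `side`.
#' @export
make_image_task <- function(n_samples = 64, side = 8, n_classes = 4,
                            noise_sd = 0.1, seed = NULL) {
  with_seed(seed, {
    centers <- cbind(
      stats::runif(n_classes, 0.25, 0.75) * side,
      stats::runif(n_classes, 0.25, 0.75) * side
    )
    gx <- matrix(rep(seq_len(side), side), side)
    gy <- t(gx)
    y <- rep(seq_len(n_classes), length.out = n_samples)
    y <- sample(y)
    X <- t(vapply(y, function(k) {
      img <- exp(-((gx - centers[k, 1])^2 + (gy - centers[k, 2])^2) /
                   (2 * (side / 4)^2))
      pmin(pmax(as.vector(img) + stats::rnorm(side^2, sd = noise_sd), 0), 1)
    }, numeric(side^2)))
    list(X = X, y = y, side = side)
  })
}

#' Sliding-window forecasting task from a multivariate series
#'
#' Frames next-step prediction: each sample's features are `window`
#' consecutive states flattened, and its target is the following state.
#'
#' @param series `T x d` trajectory matrix.
#' @param window input window length (number of past states).
#' @return list with `X` (`(T - window) x (window * d)`) and `Y`
#'   (`(T - window) x d`).
#' @export
make_forecast_task <- function(series, window = 8) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (Tn <= window) stopf("parameter error: series shorter than window + 1")
  n <- Tn - window
  d <- ncol(series)
  X <- matrix(0, n, window * d)
  for (w in seq_len(window)) {
    X[, (w - 1) * d + seq_len(d)] <- series[w:(w + n - 1), , drop = FALSE]
  }
  list(X = X, Y = series[(window + 1):Tn, , drop = FALSE])
}

#' Split and normalize a dataset
#'
#' Implements the evaluation split conventions: `"two_to_one"` holds out the
#' last third (sizes `ceiling(2n/3)` train, `floor(n/3)` test after a seeded
#' shuffle), and `"three_fold"` concatenation-style cross-validation splits
#' the data into three equal parts, testing one part at a time. Per-feature
#' normalization (mean and standard deviation) is always computed on the
#' training portion only and applied to both portions; a zero-variance
#' feature has its sigma clamped to 1 with a warning.
#'
#' @param X feature matrix (or series windows), samples in rows.
#' @param y labels or target matrix, matching rows.
#' @param mode `"two_to_one"` or `"three_fold"`.
#' @param seed integer seed for the shuffle.
#' @param normalize_y also normalize the targets with train statistics
#'   (regression only).
#' @return for `"two_to_one"`, a list with `train`, `test` (each
#'   `list(X, y)`) and `normalization` (`mean`, `sd` per feature); for
#'   `"three_fold"`, a list of three such split lists.
#' @export
prepare_splits <- function(X, y, mode = c("two_to_one", "three_fold"),
                           seed = NULL, normalize_y = FALSE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  y_is_matrix <- is.matrix(y) || is.data.frame(y)
  if (y_is_matrix) y <- as.matrix(y)
  take_y <- function(idx) if (y_is_matrix) y[idx, , drop = FALSE] else y[idx]
  if (mode == "three_fold" && n < 9) {
    stopf("parameter error: three_fold needs at least 3 samples per fold")
  }
  with_seed(seed, {
    perm <- sample.int(n)
    one_split <- function(test_idx) {
      train_idx <- setdiff(perm, test_idx)
      mu <- colMeans(X[train_idx, , drop = FALSE])
      sg <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
      if (any(sg == 0)) {
        warning("zero-variance feature(s): sigma clamped to 1", call. = FALSE)
        sg[sg == 0] <- 1
      }
      norm <- function(M) sweep(sweep(M, 2, mu, "-"), 2, sg, "/")
      ytr <- take_y(train_idx)
      yte <- take_y(test_idx)
      ynorm <- NULL
      if (normalize_y && y_is_matrix) {
        ymu <- colMeans(ytr)
        ysg <- apply(ytr, 2, stats::sd)
        ysg[ysg == 0] <- 1
        ytr <- sweep(sweep(ytr, 2, ymu, "-"), 2, ysg, "/")
        yte <- sweep(sweep(yte, 2, ymu, "-"), 2, ysg, "/")
        ynorm <- list(mean = ymu, sd = ysg)
      }
      list(
        train = list(X = norm(X[train_idx, , drop = FALSE]), y = ytr),
        test = list(X = norm(X[test_idx, , drop = FALSE]), y = yte),
        normalization = list(mean = mu, sd = sg, y = ynorm),
        test_index = sort(test_idx)
      )
    }
    if (mode == "two_to_one") {
      n_test <- n %/% 3                       # train gets ceiling(2n/3)
      one_split(perm[seq_len(n_test) + (n - n_test)])
    } else {
      fold <- rep(seq_len(3), length.out = n) # equal thirds (within 1)
      lapply(seq_len(3), function(k) one_split(perm[fold == k]))
    }
  })
}

#' Read an IDX-format array file
#'
#' Minimal reader for the IDX format used by classic handwritten-digit
#' distributions: a magic number declaring element type and rank, big-endian
#' dimension sizes, then the raw array. Lets user-supplied image files feed
#' the trainer without code changes.
#'
#' @param path path to an uncompressed IDX file.
#' @return an array with the declared dimensions (images as
#'   `n x rows x cols`).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0) {
    stopf("parameter error: not an IDX file (bad magic number)")
  }
  type <- magic[3]
  rank <- magic[4]
  dims <- readBin(con, "integer", n = rank, size = 4, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(type),
    "8"  = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "9"  = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "11" = readBin(con, "integer", n = n, size = 2, endian = "big"),
    "12" = readBin(con, "integer", n = n, size = 4, endian = "big"),
    "13" = readBin(con, "numeric", n = n, size = 4, endian = "big"),
    "14" = readBin(con, "numeric", n = n, size = 8, endian = "big"),
    stopf("parameter error: unsupported IDX element type 0x%02x", type)
  )
  if (rank == 1) return(data)
  # IDX is row-major; fill the reversed dims then transpose back
  aperm(array(data, dim = rev(dims)), rev(seq_len(rank)))
}
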