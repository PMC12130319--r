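test_that("classification tasks are balanced, deterministic, and seed-sensitive", {
  a <- make_classification_task(n_classes = 4, n_features = 10,
                                n_samples = 202, separation = 3, seed = 9)
  b <- make_classification_task(n_classes = 4, n_features = 10,
                                n_samples = 202, separation = 3, seed = 9)
  c_ <- make_classification_task(n_classes = 4, n_features = 10,
                                 n_samples = 202, separation = 3, seed = 10)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_false(identical(a$X, c_$X))
  expect_lte(diff(range(table(a$y))), 1)
  # class means sit at the requested pairwise separation
  d <- as.matrix(dist(a$means))
  expect_equal(d[upper.tri(d)], rep(3, 6), tolerance = 1e-10)
  expect_error(make_classification_task(n_samples = 2, n_classes = 3), "n_samples")
})

test_that("Bayes accuracy follows the separation: chance at 0, near-perfect at 6 sigma", {
  # Monte-Carlo Bayes oracle: classify a large fresh sample by nearest mean
  bayes_acc <- function(task, n = 20000) {
    K <- nrow(task$means)
    y <- sample.int(K, n, replace = TRUE)
    X <- task$means[y, , drop = FALSE] + matrix(rnorm(n * ncol(task$means)), n)
    d2 <- sapply(seq_len(K), function(k) {
      rowSums(sweep(X, 2, task$means[k, ], "-")^2)
    })
    mean(max.col(-d2) == y)
  }
  set.seed(77)
  flat <- make_classification_task(n_classes = 3, n_samples = 30,
                                   separation = 0, seed = 1)
  expect_lt(abs(bayes_acc(flat) - 1 / 3), 0.02)
  sep2 <- make_classification_task(n_classes = 2, n_samples = 30,
                                   separation = 6, seed = 2)
  expect_gt(bayes_acc(sep2), 0.99)
  # two-Gaussian closed form: accuracy = pnorm(separation / 2)
  sep3 <- make_classification_task(n_classes = 2, n_samples = 30,
                                   separation = 3, seed = 3)
  expect_lt(abs(bayes_acc(sep3) - pnorm(1.5)), 0.02)
})

test_that("procedural images are bounded, labeled, and reproducible", {
  img <- make_image_task(n_samples = 20, side = 6, n_classes = 3, seed = 4)
  expect_identical(dim(img$X), c(20L, 36L))
  expect_true(all(img$X >= 0 & img$X <= 1))
  expect_setequal(unique(img$y), 1:3)
  expect_identical(img$X, make_image_task(20, 6, 3, seed = 4)$X)
})

test_that("two_to_one splitting gives the ceiling/floor sizes and train-only normalization", {
  for (n in c(90, 91, 92)) {
    X <- matrix(rnorm(n * 5), n)
    y <- rep(1:3, length.out = n)
    sp <- prepare_splits(X, y, mode = "two_to_one", seed = 1)
    expect_identical(nrow(sp$train$X), as.integer(ceiling(2 * n / 3)))
    expect_identical(nrow(sp$test$X), as.integer(floor(n / 3)))
    expect_equal(colMeans(sp$train$X), rep(0, 5), tolerance = 1e-10)
    expect_equal(apply(sp$train$X, 2, sd), rep(1, 5), tolerance = 1e-10)
    # test portion normalized with *train* statistics, not its own
    expect_gt(max(abs(colMeans(sp$test$X))), 1e-8)
  }
})

test_that("three_fold test portions partition the sample index set exactly", {
  X <- matrix(rnorm(60 * 3), 60)
  y <- rep(1:3, 20)
  folds <- prepare_splits(X, y, mode = "three_fold", seed = 2)
  expect_length(folds, 3)
  test_idx <- lapply(folds, `[[`, "test_index")
  expect_identical(sort(unlist(test_idx)), 1:60)
  expect_identical(sum(vapply(test_idx, length, integer(1))), 60L)
  for (f in folds) {
    expect_equal(colMeans(f$train$X), rep(0, 3), tolerance = 1e-10)
  }
})

test_that("zero-variance features are clamped with a warning", {
  X <- cbind(rnorm(30), rep(2, 30))
  expect_warning(sp <- prepare_splits(X, rep(1:2, 15), seed = 1),
                 "zero-variance")
  expect_true(all(is.finite(sp$train$X)))
})

test_that("forecast windows align inputs with next-step targets", {
  series <- matrix(seq_len(20), ncol = 2)  # columns 1:10 and 11:20
  task <- make_forecast_task(series, window = 3)
  expect_identical(dim(task$X), c(7L, 6L))
  expect_identical(task$Y, series[4:10, ])
  expect_identical(task$X[1, ], c(1, 11, 2, 12, 3, 13))
})

test_that("IDX round-trip recovers images and labels", {
  tmp <- tempfile(fileext = ".idx")
  con <- file(tmp, "wb")
  writeBin(as.raw(c(0, 0, 8, 3)), con)                    # ubyte, rank 3
  writeBin(c(2L, 3L, 4L), con, size = 4, endian = "big")  # 2 images 3x4
  vals <- as.raw(seq_len(24))
  writeBin(vals, con)
  close(con)
  arr <- read_idx(tmp)
  expect_identical(dim(arr), c(2L, 3L, 4L))
  # row-major layout: first image rows are consecutive runs
  expect_identical(as.integer(arr[1, 1, ]), 1:4)
  expect_identical(as.integer(arr[1, 2, ]), 5:8)
  expect_identical(as.integer(arr[2, 1, ]), 13:16)
  unlink(tmp)
})
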