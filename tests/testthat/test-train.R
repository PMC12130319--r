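test_that("with all mechanisms off, training is bit-identical to a plain-SGD reference", {
  for (seed in 1:3) {
    splits <- toy_splits(seed)
    sizes <- c(8, 16, 3)
    cfg <- train_config(epochs = 5, batch_size = 32, seed = seed)
    res <- run_experiment(splits, hidden = 16, config = cfg)
    ref <- ref_plain_sgd(splits, sizes, epochs = 5, lr = cfg$learning_rate,
                         batch_size = 32, seed = seed)
    for (l in 1:2) {
      expect_identical(as.vector(res$net$layers[[l]]$W), as.vector(ref$W[[l]]))
      expect_identical(res$net$layers[[l]]$b, ref$b[[l]])
    }
    expect_identical(res$test_curve, ref$test_acc)
  }
})

test_that("training is reproducible and every mechanism combination runs", {
  splits <- toy_splits(2, n_samples = 120)
  combos <- mechanism_combinations()
  for (i in seq_len(nrow(combos))) {
    cfg <- train_config(epochs = 2, batch_size = 32, seed = 5,
                        fl = combos$fl[i], wr = combos$wr[i], ws = combos$ws[i])
    a <- run_experiment(splits, hidden = 8, config = cfg)
    b <- run_experiment(splits, hidden = 8, config = cfg)
    expect_identical(a$test_curve, b$test_curve)
    expect_identical(a$net$layers[[1]]$W, b$net$layers[[1]]$W)
    expect_identical(a$rejuvenation_counts, b$rejuvenation_counts)
    if (!combos$wr[i]) expect_identical(sum(a$rejuvenation_counts), 0L)
  }
})

test_that("a short baseline run learns the default blob task beyond 0.9 accuracy", {
  task <- make_classification_task(seed = 1)
  splits <- prepare_splits(task$X, task$y, seed = 1)
  res <- run_experiment(splits, config = train_config(epochs = 50, seed = 1))
  expect_gt(max(res$test_curve), 0.9)
  expect_length(res$test_curve, 50)
  expect_true(all(res$test_curve >= 0 & res$test_curve <= 1))
})

test_that("rejuvenation churn stabilizes after the initial phase", {
  task <- make_classification_task(seed = 3)
  splits <- prepare_splits(task$X, task$y, seed = 3)
  cfg <- train_config(epochs = 40, wr = TRUE, seed = 3)
  res <- run_experiment(splits, config = cfg)
  counts <- res$rejuvenation_counts
  q <- length(counts) %/% 4
  expect_lt(var(counts[(length(counts) - q + 1):length(counts)]),
            var(counts[1:q]))
})

test_that("the retrospective patience rule picks the documented epochs", {
  r <- epochs_to_peak(c(0.5, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 5)
  expect_identical(r$epoch, 2L)
  expect_identical(r$value, 0.9)
  inc <- seq(0.1, 0.9, by = 0.1)
  r2 <- epochs_to_peak(inc, patience = 5)
  expect_identical(r2$epoch, length(inc))
  r3 <- epochs_to_peak(c(0.5, 0.8, 0.7, 0.85, 0.85, 0.85, 0.85, 0.85, 0.85),
                       patience = 5)
  expect_identical(r3$epoch, 4L)
  expect_identical(r3$value, 0.85)
  expect_error(epochs_to_peak(numeric(0)), "empty")
})

test_that("patience rule agrees with an exhaustive scan on random curves", {
  set.seed(44)
  scan_oracle <- function(curve, patience) {
    n <- length(curve)
    for (e in seq_len(n)) {
      later <- curve[seq_len(min(n, e + patience))[-seq_len(e)]]
      if (length(later) == 0 || max(later) <= curve[e]) return(e)
    }
    which.max(curve)
  }
  for (i in 1:50) {
    curve <- round(runif(sample(3:20, 1)), 2)
    p <- sample(1:6, 1)
    expect_identical(epochs_to_peak(curve, patience = p)$epoch,
                     scan_oracle(curve, p))
  }
})

test_that("metric identities hold", {
  expect_identical(accuracy_auc(rep(0.8, 7)), 0.8)
  expect_equal(error_rate(0.95), 0.05, tolerance = 1e-15)
  set.seed(5)
  y <- matrix(rnorm(40), 20)
  expect_identical(nrmse(y, y), 0)
  mean_pred <- matrix(mean(y), 20, 2)
  expect_equal(nrmse(mean_pred, y), 1, tolerance = 1e-12)
  expect_error(nrmse(y, matrix(1, 20, 2)), "zero-variance")
})

test_that("the tuned preset overrides tau, d_re, and disables splitting", {
  cfg <- train_config(preset = "tuned", ws = TRUE)
  expect_identical(cfg$tau, 0.5)
  expect_identical(cfg$d_re, 6)
  expect_false(cfg$ws)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(patience = 0), "patience")
})

test_that("regression training on a forecasting task reduces NRMSE below the mean predictor", {
  series <- simulate_thomas(n_samples = 400, dt = 0.05, substeps = 4, seed = 8)
  task <- make_forecast_task(series, window = 4)
  splits <- prepare_splits(task$X, task$Y, mode = "two_to_one", seed = 8,
                           normalize_y = TRUE)
  cfg <- train_config(epochs = 15, loss = "mse", learning_rate = 0.01, seed = 8)
  res <- run_experiment(splits, hidden = 32, config = cfg)
  expect_lt(min(res$test_curve), 1)  # beats predicting the mean
})
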