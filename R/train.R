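#' Training configuration
#'
#' Defaults reproduce the default-hyperparameter protocol: SGD with learning
#' rate 0.01, cross-entropy loss, 100 epochs, retrospective patience-5 early
#' stopping, and the mechanism defaults `tau = 0.09`, `d_re = 14`,
#' `gamma = 2`. The tuned preset uses `tau = 0.5`, `d_re = 6` with weight
#' splitting off.
#'
#' @param learning_rate SGD learning rate.
#' @param epochs number of epochs actually trained (early stopping is
#'   retrospective and never interrupts training).
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs, `>= 1`.
#' @param fl,wr,ws mechanism toggles (fuzzy learning rates, weight
#'   rejuvenation, weight splitting).
#' @param tau gradient scaling rate used when `fl` is on.
#' @param d_re rejuvenation distance factor used when `wr` is on.
#' @param gamma synapses per neuron pair used when `ws` is on.
#' @param seed run seed governing initialization, shuffling and rejuvenation.
#' @param loss `"cross_entropy"` (classification) or `"mse"` (regression;
#'   curves are then NRMSE instead of accuracy).
#' @param preset `"default"` or `"tuned"`; the tuned preset overrides
#'   `tau = 0.5`, `d_re = 6`, `ws = FALSE`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100, batch_size = 32,
                         patience = 5, fl = FALSE, wr = FALSE, ws = FALSE,
                         tau = 0.09, d_re = 14, gamma = 2, seed = 1,
                         loss = c("cross_entropy", "mse"),
                         preset = c("default", "tuned")) {
  loss <- match.arg(loss)
  preset <- match.arg(preset)
  if (preset == "tuned") {
    tau <- 0.5
    d_re <- 6
    ws <- FALSE
  }
  if (!is_count(epochs)) stopf("parameter error: epochs must be >= 1")
  if (!is_count(patience)) stopf("parameter error: patience must be >= 1")
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         fl = isTRUE(fl), wr = isTRUE(wr), ws = isTRUE(ws),
         tau = tau, d_re = d_re, gamma = as.integer(gamma),
         seed = as.integer(seed), loss = loss, preset = preset),
    class = "train_config"
  )
}

accuracy_of <- function(net, X, y) mean(predict(net, X) == as.integer(y))

nrmse_of <- function(net, X, Y) {
  nrmse(forward(net, X)$output, Y)
}

#' Train a network with SGD and the synaptic-diversity mechanisms
#'
#' Runs minibatch SGD for `config$epochs` epochs. Per step: forward,
#' backward, a fuzzy SGD step when fuzzy learning rates are enabled (plain
#' step otherwise), then weight rejuvenation of the weight matrices when
#' enabled. Per epoch: records train/test accuracy (or NRMSE for `"mse"`
#' loss) and the number of rejuvenated weights. The run is fully reproducible
#' from `config$seed`.
#'
#' Mechanism toggles are read from `config`; the network itself carries the
#' weight-splitting structure and the scale fields, so `net` should be built
#' consistently (see [run_experiment()] for the one-call path).
#'
#' @param net a `network_state` from [init_network()].
#' @param splits list with `train` and `test`, each `list(X, y)`, normalized
#'   (see [prepare_splits()]).
#' @param config a [train_config()].
#' @return an object of class `train_result`: per-epoch curves
#'   (`train_curve`, `test_curve`), `epochs_to_peak`, `peak_accuracy`,
#'   `accuracy_auc`, `rejuvenation_counts`, the final `net`, and the `config`.
#' @export
train_network <- function(net, splits, config = train_config()) {
  Xtr <- as.matrix(splits$train$X)
  ytr <- splits$train$y
  Xte <- as.matrix(splits$test$X)
  yte <- splits$test$y
  n <- nrow(Xtr)
  classify <- config$loss == "cross_entropy"
  policy <- rejuvenation_policy(d_re = config$d_re)
  with_seed(config$seed, {
    train_curve <- numeric(config$epochs)
    test_curve <- numeric(config$epochs)
    rejuv_counts <- integer(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      n_rejuv <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        fwd <- forward(net, Xtr[idx, , drop = FALSE])
        bk <- backward(net, fwd,
                       if (classify) ytr[idx] else ytr[idx, , drop = FALSE],
                       loss = config$loss)
        if (!is.finite(bk$loss)) {
          stopf("run aborted: non-finite loss at epoch %d (divergence)", epoch)
        }
        for (l in seq_along(net$layers)) {
          ly <- net$layers[[l]]
          fW <- if (config$fl) ly$field_W else NULL
          fb <- if (config$fl) ly$field_b else NULL
          net$layers[[l]]$W <- fuzzy_sgd_step(ly$W, bk$grads[[l]]$dW,
                                              config$learning_rate, fW)
          net$layers[[l]]$b <- fuzzy_sgd_step(ly$b, bk$grads[[l]]$db,
                                              config$learning_rate, fb)
        }
        if (config$wr) {
          Ws <- lapply(net$layers, `[[`, "W")
          rej <- apply_rejuvenation(Ws, policy,
                                    init_specs = lapply(net$layers, `[[`, "init_spec"))
          for (l in seq_along(net$layers)) net$layers[[l]]$W <- rej$params[[l]]
          n_rejuv <- n_rejuv + sum(vapply(rej$masks, sum, numeric(1)))
        }
      }
      rejuv_counts[epoch] <- n_rejuv
      if (classify) {
        train_curve[epoch] <- accuracy_of(net, Xtr, ytr)
        test_curve[epoch] <- accuracy_of(net, Xte, yte)
      } else {
        train_curve[epoch] <- nrmse_of(net, Xtr, ytr)
        test_curve[epoch] <- nrmse_of(net, Xte, yte)
      }
    }
    peak <- epochs_to_peak(test_curve, patience = config$patience,
                           maximize = classify)
    structure(
      list(
        train_curve = train_curve, test_curve = test_curve,
        epochs_to_peak = peak$epoch, peak_accuracy = peak$value,
        accuracy_auc = if (classify) accuracy_auc(test_curve) else NA_real_,
        rejuvenation_counts = rejuv_counts,
        net = net, config = config
      ),
      class = "train_result"
    )
  })
}

#' Build and train a network for one mechanism configuration
#'
#' Convenience wrapper: constructs the network consistently with the
#' mechanism toggles in `config` (split hidden layers when `ws`, scale fields
#' when `fl`) and trains it. The desk-scale default architecture is a single
#' hidden layer of 128 units.
#'
#' @param splits data splits as for [train_network()].
#' @param hidden integer vector of hidden-layer widths.
#' @param config a [train_config()].
#' @param n_outputs output width; inferred from the labels / targets when
#'   `NULL`.
#' @return a `train_result`.
#' @export
run_experiment <- function(splits, hidden = 128, config = train_config(),
                           n_outputs = NULL) {
  n_in <- ncol(as.matrix(splits$train$X))
  if (is.null(n_outputs)) {
    n_outputs <- if (config$loss == "cross_entropy") {
      max(as.integer(splits$train$y), as.integer(splits$test$y))
    } else {
      ncol(as.matrix(splits$train$y))
    }
  }
  net <- init_network(
    c(n_in, hidden, n_outputs),
    gamma = if (config$ws) config$gamma else 1L,
    tau = if (config$fl) config$tau else NULL,
    seed = config$seed
  )
  train_network(net, splits, config)
}

#' Retrospective early-stopping epoch (learning-speed measure)
#'
#' Returns the first epoch whose metric is not improved upon during the
#' following `patience` epochs; training is never interrupted, the rule is
#' applied retrospectively to the recorded curve. If no epoch qualifies
#' before the end of the curve, the argmax (argmin for `maximize = FALSE`)
#' is returned.
#'
#' @param curve numeric per-epoch metric curve.
#' @param patience number of consecutive non-improving epochs required.
#' @param maximize `TRUE` for accuracy-like curves, `FALSE` for error-like.
#' @return list with `epoch` (1-based index) and `value` (curve at it).
#' @export
epochs_to_peak <- function(curve, patience = 5, maximize = TRUE) {
  if (length(curve) == 0) stopf("usage error: empty curve")
  if (!maximize) {
    res <- epochs_to_peak(-curve, patience = patience, maximize = TRUE)
    return(list(epoch = res$epoch, value = -res$value))
  }
  n <- length(curve)
  for (e in seq_len(n)) {
    upto <- min(n, e + patience)
    if (e == n || max(curve[(e + 1):upto]) <= curve[e]) {
      return(list(epoch = e, value = curve[e]))
    }
  }
  e <- which.max(curve)
  list(epoch = e, value = curve[e])
}

#' Normalized area under the accuracy curve
#'
#' The mean of the per-epoch test accuracy: a length-normalized area under
#' the curve, comparable across runs of different lengths. A constant curve
#' at `a` has AUC `a`.
#'
#' @param curve per-epoch accuracy values in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
accuracy_auc <- function(curve) {
  if (length(curve) == 0) stopf("usage error: empty curve")
  mean(curve)
}

#' Classification error rate
#' @param accuracy accuracy (scalar or vector).
#' @return `1 - accuracy`.
#' @export
error_rate <- function(accuracy) 1 - accuracy

#' Normalized root-mean-square error
#'
#' RMSE divided by the standard deviation of the ground-truth series over
#' the evaluation horizon. Predicting the target's mean everywhere gives
#' NRMSE 1; perfect prediction gives 0.
#'
#' @param pred predicted values.
#' @param truth ground-truth values, same shape.
#' @return scalar NRMSE.
#' @export
nrmse <- function(pred, truth) {
  check_same_shape(pred, truth, "pred", "truth")
  tv <- as.vector(truth)
  s <- sqrt(mean((tv - mean(tv))^2))  # population sd: mean-predictor gives exactly 1
  if (!is.finite(s) || s == 0) {
    stopf("undefined-metric error: zero-variance target in nrmse")
  }
  sqrt(mean((pred - truth)^2)) / s
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> %d epochs, peak %.4f at epoch %d, auc %s, %s rejuvenations\n",
    length(x$test_curve), x$peak_accuracy, x$epochs_to_peak,
    ifelse(is.na(x$accuracy_auc), "NA", sprintf("%.4f", x$accuracy_auc)),
    sum(x$rejuvenation_counts)
  ))
  invisible(x)
}
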