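#' Default mechanism on/off combinations
#'
#' All eight combinations of fuzzy learning rates, weight rejuvenation, and
#' weight splitting, baseline first.
#'
#' @return data frame with logical columns `fl`, `wr`, `ws` and a `label`.
#' @export
mechanism_combinations <- function() {
  g <- expand.grid(fl = c(FALSE, TRUE), wr = c(FALSE, TRUE),
                   ws = c(FALSE, TRUE))
  g$label <- apply(g, 1, function(r) {
    on <- c("fl", "wr", "ws")[as.logical(r[1:3])]
    if (length(on) == 0) "baseline" else paste(on, collapse = "+")
  })
  g
}

#' Default experiment configuration for mechanism comparisons
#'
#' One strict-JSON-serializable list describing a full comparison: the
#' synthetic task, the base training configuration, the mechanism
#' combinations, and the seeds. Unknown keys in a supplied config file are
#' rejected.
#'
#' @param seeds integer vector of run seeds.
#' @param epochs,hidden,learning_rate,batch_size trainer settings.
#' @param tau,d_re,gamma mechanism hyperparameters.
#' @param task list of [make_classification_task()] arguments.
#' @param combos optional character vector of combination labels (subset of
#'   [mechanism_combinations()]'s labels); `NULL` runs all eight.
#' @return a named list (class `experiment_config`).
#' @export
experiment_config <- function(seeds = 1:3, epochs = 40, hidden = 128,
                              learning_rate = 0.01, batch_size = 32,
                              tau = 0.09, d_re = 14, gamma = 2,
                              task = list(n_classes = 3, n_features = 16,
                                          n_samples = 900, separation = 4,
                                          label_noise = 0),
                              combos = NULL) {
  structure(
    list(seeds = as.integer(seeds), epochs = as.integer(epochs),
         hidden = as.integer(hidden), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), tau = tau, d_re = d_re,
         gamma = as.integer(gamma), task = task, combos = combos),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a strict JSON file
#'
#' Unknown keys are rejected; present keys override the defaults of
#' [experiment_config()].
#'
#' @param path JSON file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, function(x) is.null(x) ||
                       (is.list(x) && length(x) == 0), logical(1))]
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stopf("config error: unknown key(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, raw)
}

#' Run the mechanism comparison experiment
#'
#' Trains every requested mechanism combination with every seed on the
#' synthetic task and aggregates learning-speed and accuracy statistics,
#' mirroring the headline comparison at desk scale: per combination, the
#' mean and standard deviation over seeds of the error rate at the early
#' stopping epoch, the epochs-to-peak, and the accuracy AUC.
#'
#' @param config an [experiment_config()].
#' @return list (class `comparison_bundle`) with `runs` (list of
#'   `train_result`, named `label/seed`), `aggregate` (one row per
#'   combination), and `config`.
#' @export
run_comparison <- function(config = experiment_config()) {
  combos <- mechanism_combinations()
  if (!is.null(config$combos)) {
    keep <- combos$label %in% config$combos
    if (!any(keep) || !all(config$combos %in% combos$label)) {
      stopf("config error: unknown combination label(s): %s",
            paste(setdiff(config$combos, combos$label), collapse = ", "))
    }
    combos <- combos[keep, , drop = FALSE]
  }
  runs <- list()
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    err <- e2p <- auc <- numeric(length(config$seeds))
    for (si in seq_along(config$seeds)) {
      seed <- config$seeds[si]
      task <- do.call(make_classification_task,
                      c(config$task, list(seed = seed)))
      splits <- prepare_splits(task$X, task$y, mode = "two_to_one",
                               seed = seed)
      tc <- train_config(
        learning_rate = config$learning_rate, epochs = config$epochs,
        batch_size = config$batch_size,
        fl = combos$fl[ci], wr = combos$wr[ci], ws = combos$ws[ci],
        tau = config$tau, d_re = config$d_re, gamma = config$gamma,
        seed = seed
      )
      res <- run_experiment(splits, hidden = config$hidden, config = tc)
      runs[[paste0(combos$label[ci], "/", seed)]] <- res
      err[si] <- error_rate(res$peak_accuracy)
      e2p[si] <- res$epochs_to_peak
      auc[si] <- res$accuracy_auc
    }
    rows[[ci]] <- data.frame(
      label = combos$label[ci],
      fl = combos$fl[ci], wr = combos$wr[ci], ws = combos$ws[ci],
      n_runs = length(config$seeds),
      error_rate_mean = mean(err), error_rate_sd = stats::sd(err),
      epochs_to_peak_mean = mean(e2p), epochs_to_peak_sd = stats::sd(e2p),
      accuracy_auc_mean = mean(auc), accuracy_auc_sd = stats::sd(auc)
    )
  }
  structure(
    list(runs = runs, aggregate = do.call(rbind, rows), config = config),
    class = "comparison_bundle"
  )
}

#' Write a comparison bundle to disk
#'
#' Emits a JSON summary (aggregate table plus the full configuration and
#' seeds for provenance), a CSV of the aggregate table, and a long-format
#' CSV of every per-epoch curve (one row per run and epoch).
#'
#' @param bundle a [run_comparison()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary.json"),
    aggregate = file.path(dir, "aggregate.csv"),
    curves = file.path(dir, "curves.csv")
  )
  jsonlite::write_json(
    list(config = unclass(bundle$config), aggregate = bundle$aggregate),
    paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(bundle$aggregate, paths["aggregate"], row.names = FALSE)
  curves <- do.call(rbind, lapply(names(bundle$runs), function(nm) {
    r <- bundle$runs[[nm]]
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    data.frame(
      label = parts[1], seed = as.integer(parts[2]),
      epoch = seq_along(r$test_curve),
      train_accuracy = r$train_curve, test_accuracy = r$test_curve,
      rejuvenations = r$rejuvenation_counts
    )
  }))
  utils::write.csv(curves, paths["curves"], row.names = FALSE)
  invisible(paths)
}
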