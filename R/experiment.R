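# End-to-end experiments: extract -> select -> train -> evaluate.
#
# Experiment 1: normal vs ictal (binary).
# Experiment 2: {normal + interictal} vs ictal (binary, imbalanced 2:1).
# Experiment 3: normal / interictal / ictal (three-class).

#' Stratified train/test split of a feature table
#'
#' @param table feature table (numeric columns + `label`).
#' @param fraction training fraction per class.
#' @param seed split seed.
#' @return list with `train` and `test` data frames (disjoint, per-class
#'   sizes within one of `fraction * n_c`).
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- as.character(table$label)
  if (min(table(labels)) < 2L) stop_arg("every class needs >= 2 samples to split")
  idx_train <- with_seed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(fraction * length(idx)))
    }))
  })
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       test = table[-idx_train, , drop = FALSE])
}

experiment_table <- function(table, exp_id) {
  labels <- as.character(table$label)
  if (exp_id == 1L) {
    need <- c("normal", "ictal")
    if (!all(need %in% labels)) stop_arg("experiment 1 needs classes: normal, ictal")
    table[labels %in% need, , drop = FALSE]
  } else if (exp_id == 2L) {
    need <- c("normal", "interictal", "ictal")
    if (!all(need %in% labels)) {
      stop_arg("experiment 2 needs classes: normal, interictal, ictal")
    }
    out <- table
    out$label <- ifelse(labels == "ictal", "ictal", "nonictal")
    out
  } else if (exp_id == 3L) {
    need <- c("normal", "interictal", "ictal")
    if (!all(need %in% labels)) {
      stop_arg("experiment 3 needs classes: normal, interictal, ictal")
    }
    table
  } else {
    stop_arg("exp_id must be 1, 2 or 3")
  }
}

#' Run a full seizure-detection experiment
#'
#' Orchestrates the pipeline on an EEG dataset (or a pre-extracted feature
#' table): feature extraction, a stratified 80/20 split, dragonfly feature
#' selection on the training split, MLP training on the selected features,
#' and evaluation on the held-out split. The positive class for the binary
#' experiments is `"ictal"`.
#'
#' @param dataset an [eeg_dataset], or a feature table already produced by
#'   [extract_table()].
#' @param exp_id experiment 1, 2 or 3 (see Details).
#' @param config a [pipeline_config()]; `config$seed` drives the split, the
#'   optimizer and the network initialization.
#' @return object of class `seizure_experiment`: list with `exp_id`, `seed`,
#'   `selection` (a `bdfa_result`), `model` (an `mlp_net`), `metrics` (a
#'   `metrics_report` on the held-out split), `fisher` (a `fisher_report` on
#'   the full table restricted to the selected features), `ratio`, `history`,
#'   and the train/test tables.
#' @export
run_experiment <- function(dataset, exp_id = 3L, config = pipeline_config()) {
  table <- if (inherits(dataset, "eeg_dataset")) {
    extract_table(dataset, config)
  } else if (is.data.frame(dataset)) {
    dataset
  } else {
    stop_arg("'dataset' must be an eeg_dataset or a feature table")
  }
  table <- experiment_table(table, as.integer(exp_id))
  parts <- split_train_test(table, config$split_fraction, seed = config$seed)

  bd <- config$bdfa
  bd$seed <- config$seed
  sel <- select_features(parts$train, bd)

  net <- train_classifier(parts$train, sel$mask,
                          classifier_spec(hidden = config$hidden,
                                          max_epochs = config$max_epochs,
                                          seed = config$seed))
  pred <- predict(net, parts$test)
  pos <- if (exp_id %in% c(1L, 2L)) "ictal" else NULL
  met <- compute_metrics(parts$test$label, pred, positive_class = pos)
  fis <- fisher_report(table, sel$mask)
  structure(list(exp_id = as.integer(exp_id), seed = config$seed,
                 selection = sel, model = net, metrics = met, fisher = fis,
                 ratio = sel$ratio, history = sel$history,
                 train = parts$train, test = parts$test, config = config),
            class = "seizure_experiment")
}

#' @export
print.seizure_experiment <- function(x, ...) {
  cat(sprintf("<seizure_experiment %d> seed %d\n", x$exp_id, x$seed))
  cat(sprintf("  selected %d/%d features (ratio %.4f), Fisher F_tot %.4f\n",
              sum(x$selection$mask), length(x$selection$mask), x$ratio,
              x$fisher$f_tot))
  cat(sprintf("  held-out accuracy %.4f, macro F1 %.4f\n",
              x$metrics$accuracy, x$metrics$f1))
  invisible(x)
}

#' @export
summary.seizure_experiment <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (rows = truth):\n")
  print(object$metrics$confusion)
  cat("\nSelected features:\n")
  print(object$selection$selected)
  invisible(object)
}

#' @export
predict.seizure_experiment <- function(object, newdata, ...) {
  table <- if (inherits(newdata, "eeg_dataset")) {
    extract_table(newdata, object$config)
  } else {
    newdata
  }
  predict(object$model, table, ...)
}

#' @export
plot.seizure_experiment <- function(x, ...) {
  plot(x$selection, ...)
  invisible(x)
}
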