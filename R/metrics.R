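# Evaluation metrics: confusion matrix, accuracy, sensitivity, specificity,
# precision, F1 (binary and one-vs-rest macro), and the Fisher separability
# score of a feature subset.

#' Classification metrics from true and predicted labels
#'
#' For a binary problem the rates are computed from the confusion counts of
#' `positive_class` (TP, TN, FP, FN): accuracy `(TP+TN)/(TP+FN+FP+TN)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, and `F1 = 2*precision*recall/(precision+recall)`. With more
#' than two classes each class is scored one-vs-rest and the macro average is
#' reported alongside the per-class table; accuracy is the confusion-matrix
#' trace over the total.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class the positive class for binary problems (default: the
#'   last level, so `"ictal"` ranks as positive against `"normal"` and
#'   `"interictal"` under the default ordering).
#' @param class_levels optional explicit label ordering.
#' @return object of class `metrics_report`: list with `confusion` (counts,
#'   rows = truth), `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, and for multi-class problems `per_class` (data frame of
#'   one-vs-rest rates).
#' @export
compute_metrics <- function(y_true, y_pred, positive_class = NULL,
                            class_levels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_arg("y_true and y_pred lengths differ (%d vs %d)",
             length(y_true), length(y_pred))
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  levels <- class_levels %||% sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, levels), factor(y_pred, levels))
  total <- sum(cm)
  accuracy <- sum(diag(cm)) / total

  ovr <- function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      0
    }
    c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
  }

  if (length(levels) == 2L) {
    pos <- positive_class %||% levels[length(levels)]
    if (!pos %in% levels) stop_arg("positive_class '%s' not among labels", pos)
    r <- ovr(pos)
    rep <- list(confusion = cm, accuracy = accuracy,
                sensitivity = unname(r["sensitivity"]),
                specificity = unname(r["specificity"]),
                precision = unname(r["precision"]),
                f1 = unname(r["f1"]),
                positive_class = pos)
  } else {
    per <- t(vapply(levels, ovr, numeric(4)))
    per_df <- as.data.frame(per)
    rep <- list(confusion = cm, accuracy = accuracy,
                sensitivity = mean(per_df$sensitivity, na.rm = TRUE),
                specificity = mean(per_df$specificity, na.rm = TRUE),
                precision = mean(per_df$precision, na.rm = TRUE),
                f1 = mean(per_df$f1, na.rm = TRUE),
                per_class = per_df)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy %.*f | sensitivity %.*f | specificity %.*f | precision %.*f | F1 %.*f\n",
              digits, x$accuracy, digits, x$sensitivity, digits, x$specificity,
              digits, x$precision, digits, x$f1))
  if (!is.null(x$per_class)) {
    cat("per-class (one-vs-rest):\n")
    print(round(x$per_class, digits))
  }
  invisible(x)
}

#' Fisher separability score of a feature subset
#'
#' For feature `i`, `F_i = sum_c n_c (mu_ci - mu_i)^2 / sum_c n_c var_ci`
#' (between-class dispersion of class means about the grand mean over pooled
#' within-class variance; population variances). The report carries the
#' per-feature scores and their average `F_tot` over the `S` selected
#' features. A feature with zero pooled within-class variance scores 0.
#'
#' @param table feature table (numeric columns + `label`).
#' @param mask optional 0/1 vector selecting the subset (default: all).
#' @return object of class `fisher_report`: list with `scores` (named), `f_tot`,
#'   and `n_selected`.
#' @export
fisher_report <- function(table, mask = NULL) {
  feat <- setdiff(names(table), "label")
  labels <- as.character(table$label)
  if (length(unique(labels)) < 2L) stop_arg("need >= 2 classes")
  if (is.null(mask)) mask <- rep(1, length(feat))
  if (length(mask) != length(feat)) {
    stop_arg("mask length %d != feature count %d", length(mask), length(feat))
  }
  sel <- feat[mask != 0]
  if (length(sel) == 0L) stop_arg("mask selects no features")
  x <- as.matrix(table[sel])
  cls <- unique(labels)
  n_c <- vapply(cls, function(cl) sum(labels == cl), numeric(1))
  grand <- colMeans(x)
  between <- numeric(ncol(x)); within <- numeric(ncol(x))
  for (ci in seq_along(cls)) {
    xc <- x[labels == cls[ci], , drop = FALSE]
    mu_c <- colMeans(xc)
    between <- between + n_c[ci] * (mu_c - grand)^2
    within <- within + n_c[ci] * colMeans(sweep(xc, 2L, mu_c)^2)
  }
  scores <- ifelse(within > 0, between / within, 0)
  names(scores) <- sel
  structure(list(scores = scores, f_tot = mean(scores),
                 n_selected = length(sel)),
            class = "fisher_report")
}

#' @export
print.fisher_report <- function(x, ...) {
  cat(sprintf("<fisher_report> F_tot = %.4f over %d features\n",
              x$f_tot, x$n_selected))
  invisible(x)
}
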