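# Classification metrics from confusion counts: per-class accuracy,
# recall, precision and F1, and support-weighted report-level averages
# expressed in percent. Report-level accuracy is the overall fraction
# correct, which for a full-coverage multiclass evaluation equals
# support-weighted recall.

safe_ratio <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den <= 0)) {
    warning(sprintf("zero denominator in %s set to 0 by convention", what),
            call. = FALSE)
  }
  out
}

#' Metrics from binary confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and `F1 = 2PR/(P+R)`, expressed in percent; zero
#' denominators yield 0 with a warning.
#'
#' @param tp,tn,fp,fn Confusion counts (vectorized).
#' @return Data frame with columns `accuracy`, `recall`, `precision`,
#'   `f1`, in percent.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  acc <- safe_ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  rec <- safe_ratio(tp, tp + fn, "recall")
  prec <- safe_ratio(tp, tp + fp, "precision")
  f1 <- safe_ratio(2 * prec * rec, prec + rec, "F1")
  data.frame(accuracy = 100 * acc, recall = 100 * rec,
             precision = 100 * prec, f1 = 100 * f1)
}

# Support-weighted F1 on the 0-1 scale, used internally by every
# cross-validation loop. Zero-denominator classes score 0 silently.
weighted_f1 <- function(predictions, labels, classes = NULL) {
  classes <- classes %||% sort(unique(as.character(labels)))
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Evaluate predictions against reference labels
#'
#' Builds the confusion matrix and per-class TP/TN/FP/FN counts, computes
#' per-class metrics via [metrics_from_counts()], and support-weighted
#' report-level recall, precision and F1 in percent. Report-level
#' `accuracy` is the overall fraction correct (identical to weighted
#' recall for a full-coverage multiclass evaluation).
#'
#' @param predictions,labels Vectors of equal length; every prediction
#'   must belong to the label class set (or `classes` when given).
#' @param classes Optional fixed class order; defaults to the sorted
#'   label set.
#' @return A `"classification_report"`: `classes`, `support`,
#'   `confusion` (reference rows x prediction columns), `per_class`
#'   (counts + metrics), and weighted `accuracy`, `recall`, `precision`,
#'   `f1` in percent.
#' @export
evaluate <- function(predictions, labels, classes = NULL) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop_foldear("predictions and labels differ in length",
                 "foldear_bad_eval")
  }
  classes <- classes %||% sort(unique(labels))
  unknown <- setdiff(unique(c(predictions, labels)), classes)
  if (length(unknown)) {
    stop_foldear(paste0("unknown label(s): ", paste(unknown, collapse = ", ")),
                 "foldear_bad_eval")
  }
  n <- length(labels)
  confusion <- table(factor(labels, classes), factor(predictions, classes),
                     dnn = c("reference", "prediction"))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  per_class <- cbind(data.frame(class = classes, support = rowSums(confusion),
                                tp = as.numeric(tp), tn = as.numeric(tn),
                                fp = as.numeric(fp), fn = as.numeric(fn),
                                row.names = NULL),
                     suppressWarnings(metrics_from_counts(tp, tn, fp, fn)))
  support <- per_class$support
  wmean <- function(v) sum(v * support) / sum(support)
  structure(list(classes = classes, support = support,
                 confusion = unclass(confusion), per_class = per_class,
                 accuracy = 100 * sum(tp) / n,
                 recall = wmean(per_class$recall),
                 precision = wmean(per_class$precision),
                 f1 = wmean(per_class$f1)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "Classification report (n = %d)\n  accuracy %.2f%%  recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
    sum(x$support), x$accuracy, x$recall, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}
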