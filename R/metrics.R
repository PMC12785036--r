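#' Confusion matrix from label vectors
#'
#' @param true,predicted Character vectors of true and predicted class names.
#' @param class_names Character vector fixing row/column order.
#' @return C x C integer matrix; rows are true classes, columns predictions.
#' @export
confusion_matrix <- function(true, predicted, class_names) {
  stopifnot(length(true) == length(predicted))
  bad <- setdiff(unique(c(true, predicted)), class_names)
  if (length(bad) > 0) stop("labels outside class_names: ",
                            paste(bad, collapse = ", "))
  f <- function(x) factor(x, levels = class_names)
  cm <- table(true = f(true), predicted = f(predicted))
  matrix(as.integer(cm), nrow = length(class_names),
         dimnames = list(true = class_names, predicted = class_names))
}

#' Per-class precision, recall and F1
#'
#' Precision is TP/(TP+FP), recall TP/(TP+FN), and F1 their harmonic mean
#' 2PR/(P+R). Degenerate 0/0 ratios are set to 0 (with a warning), which
#' only affects classes never predicted or never observed.
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @param class_index Integer or class name selecting one class.
#' @return Named numeric vector (precision, recall, f1).
#' @export
precision_recall_f1 <- function(cm, class_index) {
  if (is.character(class_index)) class_index <- match(class_index, rownames(cm))
  tp <- cm[class_index, class_index]
  fp <- sum(cm[, class_index]) - tp
  fn <- sum(cm[class_index, ]) - tp
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("0/0 in ", what, " set to 0")
      return(0)
    }
    num / den
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Macro (unweighted) average of per-class metric values
#'
#' @param per_class_values Numeric vector, one value per class.
#' @return Their unweighted mean.
#' @export
macro_average <- function(per_class_values) {
  stopifnot(length(per_class_values) >= 1L)
  mean(per_class_values)
}

#' Support-weighted average F1
#'
#' Computes the per-class F1 from precision and recall, then weights each
#' class by its share of the total support:
#' `sum_c (2 P_c R_c / (P_c + R_c)) * n_c / n_total`.
#'
#' @param per_class_precision,per_class_recall Numeric vectors per class.
#' @param supports Positive class sizes, aligned with the metric vectors.
#' @return The weighted-average F1.
#' @export
weighted_average_f1 <- function(per_class_precision, per_class_recall,
                                supports) {
  if (length(per_class_precision) != length(per_class_recall) ||
      length(supports) != length(per_class_precision)) {
    stop("precision, recall and supports must have equal length")
  }
  if (any(supports <= 0)) stop("supports must be positive")
  s <- per_class_precision + per_class_recall
  f1 <- ifelse(s == 0, 0, 2 * per_class_precision * per_class_recall / s)
  sum(f1 * supports / sum(supports))
}

#' Global accuracy
#'
#' @param cm Confusion matrix.
#' @return trace(cm) / sum(cm).
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Full evaluation report
#'
#' Per-class precision/recall/F1 with supports, plus global accuracy and
#' the macro and support-weighted averages of each metric.
#'
#' @param cm Confusion matrix with class dimnames.
#' @return Object of class `metrics_report`: list with `per_class`
#'   (data.frame class/precision/recall/f1/support), `accuracy`, `macro`
#'   and `weighted` (named vectors over precision/recall/f1), `n_total`.
#' @export
metrics_report <- function(cm) {
  classes <- rownames(cm)
  prf <- t(vapply(seq_along(classes),
                  function(i) suppressWarnings(precision_recall_f1(cm, i)),
                  numeric(3)))
  support <- rowSums(cm)
  per_class <- data.frame(class = classes,
                          precision = prf[, "precision"],
                          recall = prf[, "recall"],
                          f1 = prf[, "f1"],
                          support = as.integer(support),
                          stringsAsFactors = FALSE, row.names = NULL)
  w <- support / sum(support)
  structure(list(
    per_class = per_class,
    accuracy = accuracy(cm),
    macro = c(precision = macro_average(per_class$precision),
              recall = macro_average(per_class$recall),
              f1 = macro_average(per_class$f1)),
    weighted = c(precision = sum(per_class$precision * w),
                 recall = sum(per_class$recall * w),
                 f1 = sum(per_class$f1 * w)),
    n_total = sum(cm)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  tab <- x$per_class
  tab$precision <- sprintf("%.2f", tab$precision)
  tab$recall <- sprintf("%.2f", tab$recall)
  tab$f1 <- sprintf("%.2f", tab$f1)
  print(tab, row.names = FALSE)
  cat(sprintf("Accuracy      %.2f  (n = %d)\n", x$accuracy, x$n_total))
  cat(sprintf("Macro avg     P %.2f  R %.2f  F1 %.2f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("Weighted avg  P %.2f  R %.2f  F1 %.2f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

#' Serialize a metrics report / confusion matrix as TSV
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_tsv <- function(report, path) {
  tab <- report$per_class
  names(tab) <- c("Group", "Precision", "Recall", "F1-Score", "Support")
  extra <- data.frame(
    Group = c("Accuracy", "Macro avg", "Weighted avg"),
    Precision = c(NA, report$macro["precision"], report$weighted["precision"]),
    Recall = c(NA, report$macro["recall"], report$weighted["recall"]),
    `F1-Score` = c(report$accuracy, report$macro["f1"], report$weighted["f1"]),
    Support = rep(report$n_total, 3), check.names = FALSE)
  utils::write.table(rbind(tab, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @param cm Confusion matrix.
#' @export
write_confusion_tsv <- function(cm, path) {
  utils::write.table(cbind(class = rownames(cm), as.data.frame(cm)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
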