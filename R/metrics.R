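#' Confusion matrix over the five stimulation classes
#'
#' @param truth,pred Integer vectors of true and predicted classes (0-4).
#' @param n_classes Number of classes.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 5) {
  lv <- 0:(n_classes - 1)
  tb <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(tb), nrow = n_classes,
              dimnames = list(true = paste0("class", lv),
                              pred = paste0("class", lv)))
  m
}

#' Macro-averaged precision, recall and F1 from a confusion matrix
#'
#' For each class `c`, one-vs-rest counts are read off the confusion
#' matrix (`tp` the diagonal entry, `fp` the column sum minus `tp`, `fn`
#' the row sum minus `tp`) and
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2RP/(R+P)`,
#' with `0/0` defined as 0. Macro values are the unweighted mean over the
#' classes present in the true labels (classes absent from a test fold are
#' excluded from the macro mean). Overall accuracy is the trace over the
#' total; per-class accuracy is the diagonal over the row sum.
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return An `eval_metrics` list: `per_class` (data frame with
#'   `precision`, `recall`, `f1`, `accuracy`, `support`),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `accuracy`,
#'   `classes_used` (those entering the macro mean), `n`.
#' @export
macro_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  div0 <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * recall * precision, recall + precision)
  support <- rowSums(cm)
  present <- support > 0
  per_class <- data.frame(
    precision = precision, recall = recall, f1 = f1,
    accuracy = ifelse(present, tp / pmax(support, 1), NA_real_),
    support = support
  )
  rownames(per_class) <- rownames(cm)
  out <- list(per_class = per_class,
              macro_precision = mean(precision[present]),
              macro_recall = mean(recall[present]),
              macro_f1 = mean(f1[present]),
              accuracy = sum(tp) / total,
              classes_used = which(present) - 1L,
              n = total)
  class(out) <- "eval_metrics"
  out
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d records: accuracy %.3f, macro-P %.3f, macro-R %.3f, macro-F1 %.3f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(round(x$per_class, 3))
  invisible(x)
}

#' Relative improvement between two metric values
#'
#' `(with_prev - gyro_only) / gyro_only * 100`, the percentage gain from
#' adding the previous-stimulation-level feature.
#'
#' @param gyro_only Metric under the gyroscope-only feature set.
#' @param with_prev Metric with the previous stimulation level added.
#' @return Percentage improvement.
#' @export
improvement_pct <- function(gyro_only, with_prev) {
  (with_prev - gyro_only) / gyro_only * 100
}
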