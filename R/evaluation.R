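# Evaluation suite: confusion matrix, one-vs-rest sensitivity/specificity,
# accuracy, ROC/AUC by threshold sweep with trapezoidal integration, a
# 20-bin prediction-error histogram, and McNemar's exact test for paired
# classifier comparison.

#' Confusion matrix
#'
#' `counts[i, j]` = number of samples with true class `i` predicted as `j`.
#'
#' @param true_labels,predicted_labels Equal-length vectors of labels drawn
#'   from `class_labels`.
#' @param class_labels Ordered class set (default: the five classes 1..5).
#' @export
confusion <- function(true_labels, predicted_labels, class_labels = 1:5) {
  if (length(true_labels) != length(predicted_labels)) {
    abort_arg("true and predicted label vectors must have equal length")
  }
  if (!all(true_labels %in% class_labels) || !all(predicted_labels %in% class_labels)) {
    abort_arg("labels outside the declared class set")
  }
  counts <- table(factor(true_labels, levels = class_labels),
                  factor(predicted_labels, levels = class_labels))
  m <- matrix(as.integer(counts), nrow = length(class_labels),
              dimnames = list(true = as.character(class_labels),
                              predicted = as.character(class_labels)))
  structure(list(counts = m, class_labels = class_labels),
            class = "confusion_matrix")
}

#' Metrics from a confusion matrix
#'
#' One-vs-rest per class: `TP = counts[k, k]`, `FN = row_k - TP`,
#' `FP = col_k - TP`, `TN = total - TP - FN - FP`; sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`. Overall accuracy is
#' `trace/total`; macro values are unweighted means over classes.
#' A class with no true members has undefined sensitivity: it is reported as
#' `NA`, excluded from the macro mean, and a warning is issued.
#'
#' @param cm A [confusion()] matrix.
#' @return List: `accuracy`, `per_class_sensitivity`,
#'   `per_class_specificity`, `macro_sensitivity`, `macro_specificity`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0L) abort_arg("empty confusion matrix")
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  if (anyNA(sens)) {
    warning(sprintf("classes with no true members excluded from macro sensitivity: %s",
                    paste(cm$class_labels[is.na(sens)], collapse = ", ")))
  }
  list(accuracy = sum(tp) / total,
       per_class_sensitivity = stats::setNames(sens, cm$class_labels),
       per_class_specificity = stats::setNames(spec, cm$class_labels),
       macro_sensitivity = mean(sens, na.rm = TRUE),
       macro_specificity = mean(spec, na.rm = TRUE))
}

#' One-vs-rest ROC curve
#'
#' Sweeps the unique scores of the chosen class as thresholds (plus the
#' endpoints), reporting FPR/TPR pairs from (0,0) to (1,1) and the
#' trapezoidal AUC. With all scores identical the curve is the single tie
#' step and the AUC is 0.5.
#'
#' @param true_labels Label vector.
#' @param prob_matrix Score/probability matrix, one column per class.
#' @param class_index Column (class) treated as positive.
#' @return List of class `roc_curve`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_ovr <- function(true_labels, prob_matrix, class_index) {
  scores <- prob_matrix[, class_index]
  pos <- true_labels == class_index
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort_degenerate("ROC undefined: need both positive and negative examples")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc),
            class = "roc_curve")
}

#' Prediction-error histogram
#'
#' Per-sample error `e = P(true class) - 1` (0 for a perfectly confident
#' correct prediction, approaching -1 for a confidently wrong one), binned
#' into `bins` equal-width bins spanning the observed range.
#'
#' @param true_labels Label vector (1-based class indices).
#' @param prob_matrix Probability matrix, one column per class.
#' @param bins Number of bins (default 20).
#' @return List: `breaks` (length `bins + 1`), `counts`, `errors`,
#'   `zero_bin` (index of the bin containing zero error).
#' @export
error_histogram <- function(true_labels, prob_matrix, bins = 20L) {
  e <- prob_matrix[cbind(seq_along(true_labels), true_labels)] - 1
  rng <- range(e)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) / bins
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- as.integer(table(cut(e, breaks, include.lowest = TRUE)))
  # same (a, b] bin convention (lowest bin closed) as the counts
  zero_bin <- if (0 == breaks[1]) 1L else {
    hit <- which(breaks[-(bins + 1L)] < 0 & 0 <= breaks[-1])
    if (length(hit)) hit[1] else NA_integer_
  }
  list(breaks = breaks, counts = counts, errors = e, zero_bin = zero_bin)
}

#' McNemar exact test between two classifiers
#'
#' Compares paired predictions through the discordant pairs: `b` = samples
#' model A gets right and B wrong, `c` = the reverse. Exact two-sided
#' binomial p-value under the null that discordant errors are equally likely.
#' With no discordant pairs there is no evidence either way and p = 1.
#'
#' @param preds_a,preds_b Predicted label vectors of the two models.
#' @param true_labels True labels.
#' @return List: `b`, `c`, `statistic` (`b - c`), `p_value`.
#' @export
compare_models <- function(preds_a, preds_b, true_labels) {
  if (length(preds_a) != length(true_labels) ||
      length(preds_b) != length(true_labels)) {
    abort_arg("prediction vectors must match the label vector length")
  }
  ok_a <- preds_a == true_labels
  ok_b <- preds_b == true_labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  p <- if (b + cc == 0L) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
  list(b = b, c = cc, statistic = b - cc, p_value = min(p, 1))
}

#' Full evaluation report
#'
#' Confusion matrix, accuracy, per-class and macro sensitivity/specificity,
#' per-class one-vs-rest ROC curves with AUC, and the 20-bin error histogram.
#'
#' @param true_labels True class labels.
#' @param predicted_labels Predicted class labels.
#' @param prob_matrix Class-probability matrix (for ROC and histogram).
#' @param class_labels Ordered class set.
#' @return List of class `evaluation_report`.
#' @export
evaluate_model <- function(true_labels, predicted_labels, prob_matrix,
                           class_labels = 1:5) {
  cm <- confusion(true_labels, predicted_labels, class_labels)
  metrics <- metrics_from_confusion(cm)
  roc <- lapply(seq_along(class_labels), function(k) {
    if (any(true_labels == class_labels[k]) && !all(true_labels == class_labels[k])) {
      roc_ovr(true_labels, prob_matrix, k)
    } else NULL
  })
  names(roc) <- as.character(class_labels)
  structure(c(list(confusion = cm), metrics,
              list(roc = roc,
                   mean_auc = mean(vapply(Filter(Negate(is.null), roc),
                                          `[[`, numeric(1), "auc")),
                   error_histogram = error_histogram(true_labels, prob_matrix))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.4f | macro sensitivity %.4f | macro specificity %.4f | mean AUC %.4f\n",
              x$accuracy, x$macro_sensitivity, x$macro_specificity, x$mean_auc))
  print(x$confusion$counts)
  invisible(x)
}
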