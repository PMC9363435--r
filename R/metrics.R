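#' Confusion matrix
#'
#' @param truth,predicted Vectors of class labels, equal length.
#' @param labels Ordered label set; defaults to the sorted union of both
#'   vectors. Labels outside the set are an error.
#' @return Integer matrix of class `thal_confusion` with `M[i, j]` = count of
#'   samples with true label i predicted as j.
#' @export
confusion <- function(truth, predicted, labels = NULL) {
  stopf(length(truth) == length(predicted),
        "truth (%d) and predicted (%d) differ in length",
        length(truth), length(predicted))
  stopf(length(truth) > 0, "empty input")
  labels <- labels %||% sort(unique(c(truth, predicted)))
  unseen <- setdiff(unique(c(truth, predicted)), labels)
  stopf(length(unseen) == 0, "label(s) outside the label set: %s",
        paste(unseen, collapse = ", "))
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  structure(m, class = c("thal_confusion", "matrix", "array"))
}

#' Per-class one-vs-rest performance metrics
#'
#' For each class k: TP = `M[k, k]`, FN = row k minus TP, FP = column k minus
#' TP, TN = everything else; then sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN) and F1 =
#' 2 PPV sens / (PPV + sens). Undefined ratios (0/0) are reported as `NA`,
#' never coerced to 0. Overall accuracy = trace/total.
#'
#' @param cm A `thal_confusion`.
#' @return Tibble with one row per class (`class`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`); attribute `accuracy`.
#' @examples
#' cm <- confusion(c("a", "a", "b"), c("a", "a", "b"))
#' class_metrics(cm)
#' @export
class_metrics <- function(cm) {
  stopf(inherits(cm, "thal_confusion"), "cm must come from confusion()")
  total <- sum(cm)
  stopf(total > 0, "empty confusion matrix")
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f1 <- ifelse(is.na(ppv) | is.na(sens) | (ppv + sens) == 0,
               NA_real_, 2 * ppv * sens / (ppv + sens))
  out <- tibble(class = rownames(cm), sensitivity = unname(sens),
                specificity = unname(spec), ppv = unname(ppv),
                npv = unname(npv), f1 = unname(f1))
  structure(out, accuracy = sum(tp) / total)
}

#' Macro-averaged F1 over a subset of classes
#'
#' @param cm A `thal_confusion`.
#' @param classes Classes to average over (default all).
#' @return Mean per-class F1 (NA-dropping is an error: every requested class
#'   must have a defined F1).
#' @export
macro_f1 <- function(cm, classes = rownames(cm)) {
  m <- class_metrics(cm)
  m <- m[m$class %in% classes, ]
  stopf(nrow(m) == length(classes), "class(es) missing from the matrix: %s",
        paste(setdiff(classes, m$class), collapse = ", "))
  stopf(!anyNA(m$f1), "F1 undefined for class(es): %s",
        paste(m$class[is.na(m$f1)], collapse = ", "))
  mean(m$f1)
}

#' Collapse five-class labels to the stage-1 binary task
#'
#' @param labels Character vector of class labels.
#' @param normal_label The label counted as normal (default `"aa_aa"`).
#' @return Character vector of `"normal"` / `"abnormal"`.
#' @export
collapse_binary <- function(labels, normal_label = "aa_aa") {
  ifelse(labels == normal_label, "normal", "abnormal")
}

#' Evaluate predictions at both granularities
#'
#' Produces the stage-1 (normal/abnormal collapse) and ensemble (five-class)
#' confusion matrices and per-class metrics for a set of calls.
#'
#' @param truth,predicted Five-class label vectors.
#' @param labels Ensemble label set (default: the five canonical classes).
#' @return List of class `thal_evaluation`: `stage1` and `ensemble`, each
#'   with `confusion`, `metrics`, `accuracy`.
#' @export
evaluate_predictions <- function(truth, predicted,
                                 labels = c("aa_aa", "aa_SEA", "aa_3.7",
                                            "aa_4.2", "Others")) {
  cm5 <- confusion(truth, predicted, labels)
  cm2 <- confusion(collapse_binary(truth), collapse_binary(predicted),
                   c("normal", "abnormal"))
  pack <- function(cm) {
    m <- class_metrics(cm)
    list(confusion = cm, metrics = m, accuracy = attr(m, "accuracy"))
  }
  structure(list(stage1 = pack(cm2), ensemble = pack(cm5)),
            class = "thal_evaluation")
}

#' @export
print.thal_evaluation <- function(x, ...) {
  cat(sprintf("<evaluation: stage-1 accuracy %.4f, ensemble accuracy %.4f>\n",
              x$stage1$accuracy, x$ensemble$accuracy))
  print(x$ensemble$metrics)
  invisible(x)
}

#' Format a metrics tibble as percentages
#'
#' @param metrics Output of [class_metrics()].
#' @param digits Decimal places (default 2).
#' @return Tibble with metric columns as percent values.
#' @export
metrics_as_percent <- function(metrics, digits = 2) {
  mutate(metrics, across(-"class", ~ round(.x * 100, digits)))
}
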