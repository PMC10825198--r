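#' Support-weighted binary classification metrics
#'
#' Computes the evaluation suite used throughout the pipeline: accuracy and
#' the class-support-weighted versions of precision, negative predictive
#' value, specificity and F1. With the designated positive class P and
#' negative class N, the confusion counts are TP (true P predicted P),
#' FP (true N predicted P), FN (true P predicted N), TN (true N predicted
#' N). Each weighted metric is `sum_c (n_c / n) m_c`, where `m_c` is the
#' per-class metric computed treating class c as positive and `n_c` its
#' support in `y_true`. A ratio with zero denominator contributes 0 and the
#' record is flagged (this arises only in degenerate folds where a class is
#' absent).
#'
#' @param y_true,y_pred equal-length label vectors over the task's two
#'   classes.
#' @param positive_class the designated positive label (e.g. `"left"`,
#'   `"extra_temporal"`, `"posterior"`).
#' @param negative_class optional; inferred as the other observed label
#'   when omitted.
#' @return list with `metrics` (named numeric: `accuracy`, `precision_w`,
#'   `npv_w`, `specificity_w`, `f1_w`), `confusion` (named numeric TP, FP,
#'   FN, TN) and `flagged` (TRUE when any ratio was undefined).
#' @export
compute_weighted_metrics <- function(y_true, y_pred, positive_class,
                                     negative_class = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stopf("y_true and y_pred must be equal-length non-empty vectors")
  }
  observed <- unique(c(y_true, y_pred))
  if (is.null(negative_class)) {
    negs <- setdiff(observed, positive_class)
    if (length(negs) > 1) {
      stopf("labels outside the task pair: %s", paste(negs, collapse = ", "))
    }
    negative_class <- if (length(negs) == 1) negs else paste0("not_", positive_class)
  }
  classes <- c(positive_class, negative_class)
  bad <- !observed %in% classes
  if (any(bad)) stopf("unknown label(s): %s", paste(observed[bad], collapse = ", "))

  n <- length(y_true)
  TP <- sum(y_true == positive_class & y_pred == positive_class)
  FP <- sum(y_true == negative_class & y_pred == positive_class)
  FN <- sum(y_true == positive_class & y_pred == negative_class)
  TN <- sum(y_true == negative_class & y_pred == negative_class)

  flagged <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { flagged <<- TRUE; 0 } else num / den
  }
  per_class <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    tn <- sum(y_true != cls & y_pred != cls)
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    specificity <- safe_div(tn, tn + fp)
    npv <- safe_div(tn, tn + fn)
    f1 <- if (precision + recall == 0) { flagged <<- TRUE; 0 } else
      2 * precision * recall / (precision + recall)
    c(precision = precision, npv = npv, specificity = specificity, f1 = f1)
  }
  w <- vapply(classes, function(cls) sum(y_true == cls) / n, 0)
  pc <- vapply(classes, per_class, numeric(4))
  weighted <- as.numeric(pc %*% w)
  names(weighted) <- c("precision_w", "npv_w", "specificity_w", "f1_w")
  list(metrics = c(accuracy = (TP + TN) / n, weighted),
       confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
       flagged = flagged)
}
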