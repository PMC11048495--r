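# Confusion-matrix metrics for imbalanced evaluation.  The positive class is
# the minority (non-target) class throughout, so "recall" is minority-class
# sensitivity and G-means balances it against majority-class specificity.

#' Confusion counts
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The label value counted as positive (default `"positive"`).
#' @return Object of class `confusion_counts` with integer fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive = "positive") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Geometric mean of recall and specificity
#'
#' `sqrt(recall * specificity)`, the balanced headline metric for imbalanced
#' classification: it is high only when both the minority and the majority
#' class are recognized.
#'
#' @param recall,specificity Reals in `[0, 1]`.
#' @return The G-means value.
#' @export
gmeans <- function(recall, specificity) {
  if (is.na(recall) || is.na(specificity)) return(NA_real_)
  if (recall < 0 || recall > 1 || specificity < 0 || specificity > 1) {
    stop("recall and specificity must lie in [0, 1]", call. = FALSE)
  }
  sqrt(recall * specificity)
}

#' Derive an evaluation report from confusion counts
#'
#' Computes accuracy, precision, recall (sensitivity), specificity and
#' G-means.  Metrics with a zero denominator are reported as `NA` (serialized
#' as JSON `null` by [write_report()]), never as the result of `0/0`
#' arithmetic.
#'
#' @param counts A [confusion()] result.
#' @param auc Optional AUC to attach (computed separately from scores).
#' @return Object of class `evaluation_report`.
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("no evaluated points", call. = FALSE)
  recall <- safe_ratio(counts$TP, counts$TP + counts$FN)
  specificity <- safe_ratio(counts$TN, counts$TN + counts$FP)
  structure(
    list(accuracy = (counts$TP + counts$TN) / total,
         precision = safe_ratio(counts$TP, counts$TP + counts$FP),
         recall = recall,
         specificity = specificity,
         gmeans = if (is.na(recall) || is.na(specificity)) NA_real_
                  else gmeans(recall, specificity),
         auc = auc,
         counts = counts),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("acc %.3f | prec %.3f | recall %.3f | spec %.3f | G-means %.3f | AUC %.3f\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$gmeans, x$auc))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted 0.5; identical to
#' trapezoidal integration of the ROC curve.
#'
#' @param y_true Label vector.
#' @param scores Numeric scores, one per sample.
#' @param positive The positive label (default `"positive"`).
#' @param higher_is_positive If `TRUE` (default) larger scores indicate the
#'   positive class.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_score <- function(y_true, scores, positive = "positive",
                      higher_is_positive = TRUE) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  pos <- y_true == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  s <- if (higher_is_positive) scores else -scores
  # map infinities to finite extremes so midranks stay well defined
  if (any(is.infinite(s))) {
    fin <- s[is.finite(s)]
    hi <- if (length(fin)) max(fin) + 1 else 1
    lo <- if (length(fin)) min(fin) - 1 else -1
    s[s == Inf] <- hi
    s[s == -Inf] <- lo
  }
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Truncate a value to a number of decimal places
#'
#' Truncation (toward zero), not rounding: the convention under which
#' three-decimal published metric tables are compared.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places kept.
#' @return Truncated values.
#' @export
truncate_decimals <- function(x, digits = 3L) {
  trunc(x * 10^digits) / 10^digits
}
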