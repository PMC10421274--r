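# Evaluation: confusion matrix, threshold metrics and ROC AUC.

.as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("active", "inactive"))
    if (length(bad)) {
      stop("labels must be 'active'/'inactive' (got: ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    return(as.integer(y == "active"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  stop("labels must be active/inactive, logical, or 0/1", call. = FALSE)
}

#' Confusion matrix and derived classification metrics
#'
#' Thresholds the predicted probabilities (`>= threshold` predicts active),
#' counts TP/FP/TN/FN, and derives the true-positive rate (recall), the
#' false-positive rate, specificity, precision and F1, together with the
#' threshold-free ROC AUC (trapezoidal, over all thresholds). Metrics whose
#' denominator is zero are reported as `NA` and listed in the `undefined`
#' field instead of erroring.
#'
#' @param y_true True labels: `"active"`/`"inactive"`, logical, or 0/1.
#' @param y_prob Predicted probabilities of the active class, in `[0, 1]`.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `EvalReport` with fields `tp`, `fp`, `tn`,
#'   `fn`, `tpr`, `fpr`, `specificity`, `precision`, `recall`, `f1`,
#'   `roc_auc`, `n`, `threshold` and `undefined`.
#' @export
confusion_and_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y <- .as_binary_labels(y_true)
  if (length(y) != length(y_prob)) {
    stop("y_true and y_prob must have the same length", call. = FALSE)
  }
  if (any(!is.finite(y_prob)) || any(y_prob < 0 | y_prob > 1)) {
    stop("y_prob must contain probabilities in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  undefined <- character(0)
  frac <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  tpr <- frac(tp, tp + fn, "tpr")
  specificity <- frac(tn, tn + fp, "specificity")
  fpr <- if (is.na(specificity)) { undefined <- c(undefined, "fpr"); NA_real_
  } else 1 - specificity
  precision <- frac(tp, tp + fp, "precision")
  recall <- tpr
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  roc_auc <- if (length(unique(y)) < 2L) {
    undefined <- c(undefined, "roc_auc"); NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = y_prob,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = tpr, fpr = fpr, specificity = specificity,
                 precision = precision, recall = recall, f1 = f1,
                 roc_auc = roc_auc, n = length(y), threshold = threshold,
                 undefined = unique(undefined)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("<EvalReport> n =", x$n, " threshold =", x$threshold, "\n")
  cat("                    Predicted\n")
  cat("                    Active  Inactive\n")
  cat(sprintf("  Actual Active   %6d  %8d\n", x$tp, x$fn))
  cat(sprintf("         Inactive %6d  %8d\n", x$fp, x$tn))
  fmt <- function(v) ifelse(is.na(v), "  NA ", sprintf("%.4f", v))
  cat("  precision ", fmt(x$precision), "  recall ", fmt(x$recall),
      "  F1 ", fmt(x$f1), "\n  specificity ", fmt(x$specificity),
      "  ROC AUC ", fmt(x$roc_auc), "\n", sep = "")
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
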