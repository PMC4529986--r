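#' Confusion-count classification metrics
#'
#' The standard binary suite from the four confusion counts: sensitivity
#' (TPR), FPR, accuracy, precision, specificity, F-score and MCC.
#' Zero-denominator conventions: precision is 0 when TP + FP = 0; MCC is
#' 0 when any factor of its denominator is 0.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return named list of counts and metrics.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  list(TP = tp, FP = fp, FN = fn, TN = tn, n = n,
       sensitivity = safe_div(tp, tp + fn),
       FPR = safe_div(fp, tn + fp),
       accuracy = safe_div(tp + tn, n),
       precision = safe_div(tp, tp + fp),
       specificity = safe_div(tn, tn + fp),
       f_score = safe_div(2 * tp, 2 * tp + fp + fn),
       mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' Evaluate a prediction set
#'
#' Thresholded confusion metrics plus the ROC curve and AUC of the
#' continuous scores.
#'
#' @param pred a `prediction_set` (see [predict_scores()]) or a
#'   data.frame with `score`, `pred_label`, `true_label`.
#' @return an object of class `metrics_report`.
#' @export
compute_metrics <- function(pred) {
  stopifnot(all(c("score", "pred_label", "true_label") %in% names(pred)))
  truth <- as.logical(pred$true_label)
  if (any(is.na(truth))) stop("true labels required for compute_metrics")
  guess <- as.logical(pred$pred_label)
  out <- confusion_metrics(tp = sum(guess & truth),
                           fp = sum(guess & !truth),
                           fn = sum(!guess & truth),
                           tn = sum(!guess & !truth))
  if (length(unique(truth)) == 2L) {
    roc <- roc_auc(pred$score, truth)
    out$auc <- roc$auc
    out$roc_points <- roc$roc_points
  } else {
    out$auc <- NA_real_
    out$roc_points <- NULL
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics: n=%d TP=%d FP=%d FN=%d TN=%d | AUC=%.3f MCC=%.3f acc=%.3f>\n",
    x$n, x$TP, x$FP, x$FN, x$TN,
    ifelse(is.na(x$auc), NaN, x$auc), x$mcc, x$accuracy))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped at one
#' threshold), FPR/TPR at each threshold, and trapezoidal area under the
#' curve.
#'
#' @param score numeric scores (larger = more positive).
#' @param truth logical (or 0/1) true labels; both classes must be
#'   present.
#' @return list with `roc_points` (data.frame of FPR, TPR, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), !any(is.na(score)))
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L) {
    stop("roc_auc requires both classes in the truth labels")
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(c(diff(grp) != 0, TRUE))  # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}
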