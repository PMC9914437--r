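#' Binary confusion counts
#'
#' Positive class = `heard`. `TP` are heard trials predicted heard, `TN`
#' unheard predicted unheard, `FP` unheard predicted heard, `FN` heard
#' predicted unheard.
#'
#' @param y_true,y_pred vectors of `"heard"` / `"unheard"` labels (or
#'   logicals, `TRUE` = heard), equal length.
#' @return A `confusion` list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  pos <- function(y) if (is.logical(y)) y else y == "heard"
  t_ <- pos(y_true); p_ <- pos(y_pred)
  structure(list(tp = sum(t_ & p_), fp = sum(!t_ & p_),
                 fn = sum(t_ & !p_), tn = sum(!t_ & !p_)),
            class = "confusion")
}

#' Derived classification metrics
#'
#' From the confusion counts: classification error `(FP+FN)/N`, accuracy
#' `(TP+TN)/N`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)` (undefined,
#' `NA`, when no positive prediction was made), specificity `TN/(TN+FP)`,
#' F1 (harmonic mean of precision and recall; undefined when precision is
#' undefined or precision + recall is zero), and Matthews correlation
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when the denominator vanishes. Given class probabilities, also log loss
#' (mean cross-entropy, probabilities clipped to `[1e-15, 1 - 1e-15]`) and
#' trapezoidal ROC AUC.
#'
#' @param cm a [confusion_counts()] result (or list with tp/fp/fn/tn).
#' @param prob_heard optional vector of predicted P(heard), one per case,
#'   aligned with `y_true`; required for `log_loss` and `auc`.
#' @param y_true required with `prob_heard`.
#' @return A `metrics_report` list: `error`, `accuracy`, `recall`,
#'   `precision`, `specificity`, `f1`, `mcc`, and (when probabilities are
#'   given) `log_loss`, `auc`. Undefined entries are `NA`.
#' @export
classification_metrics <- function(cm, prob_heard = NULL, y_true = NULL) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion matrix")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  rep_ <- list(error = (fp + fn) / n, accuracy = (tp + tn) / n,
               recall = recall, precision = precision,
               specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
               f1 = f1, mcc = mcc,
               log_loss = NA_real_, auc = NA_real_)
  if (!is.null(prob_heard)) {
    if (is.null(y_true)) stop("y_true is required with prob_heard")
    y <- if (is.logical(y_true)) y_true else y_true == "heard"
    rep_$log_loss <- log_loss(y, prob_heard)
    rep_$auc <- roc_auc(y, prob_heard)
  }
  structure(rep_, class = "metrics_report")
}

#' @rdname classification_metrics
#' @param y logical truth (TRUE = positive).
#' @export
log_loss <- function(y, prob_heard) {
  p <- pmin(pmax(prob_heard, 1e-15), 1 - 1e-15)
  -mean(ifelse(y, log(p), log(1 - p)))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over every distinct predicted
#' probability and integrates sensitivity over the false-positive rate by
#' the trapezoidal rule.
#'
#' @param y logical truth (TRUE = positive).
#' @param prob_heard predicted positive-class probabilities.
#' @return For [roc_points()], a data frame `threshold`, `fpr`, `tpr`;
#'   for [roc_auc()], the scalar area under that curve.
#' @export
roc_points <- function(y, prob_heard) {
  stopifnot(length(y) == length(prob_heard))
  thr <- c(Inf, sort(unique(prob_heard), decreasing = TRUE))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes present")
  tpr <- vapply(thr, function(t) sum(y & prob_heard >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!y & prob_heard >= t) / n_neg, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' @rdname roc_points
#' @export
roc_auc <- function(y, prob_heard) {
  pts <- roc_points(y, prob_heard)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(round(v, digits))
  cat(sprintf(
    "accuracy %s  error %s  recall %s  precision %s  specificity %s  f1 %s  mcc %s",
    fmt(x$accuracy), fmt(x$error), fmt(x$recall), fmt(x$precision),
    fmt(x$specificity), fmt(x$f1), fmt(x$mcc)))
  if (!is.na(x$log_loss)) cat(sprintf("  logloss %s", fmt(x$log_loss)))
  if (!is.na(x$auc)) cat(sprintf("  auc %s", fmt(x$auc)))
  cat("\n")
  invisible(x)
}
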