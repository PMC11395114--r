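#' Confusion counts
#'
#' Container for the 2x2 classification table: true/false positives and
#' negatives.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(v)) || any(v < 0)) stop("confusion counts must be >= 0")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Confusion counts from continuous scores
#'
#' Thresholds scores at `threshold` (score >= threshold predicts the
#' positive class) and tabulates against binary labels.
#'
#' @param scores Numeric scores (e.g. elderly probabilities).
#' @param labels Binary labels (0/1 or logical), same length.
#' @param threshold Decision threshold, default 0.5.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty score vector")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  p <- as.integer(scores >= threshold)
  confusion_counts(tp = sum(p == 1L & y == 1L), fp = sum(p == 1L & y == 0L),
                   tn = sum(p == 0L & y == 0L), fn = sum(p == 0L & y == 1L))
}

#' Classification metrics from confusion counts
#'
#' Evaluates accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`,
#' recall (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F1
#' score `2*Precision*Recall/(Precision+Recall)`. Metrics whose
#' denominator is zero are undefined for that table; they are returned as
#' `NA` and listed in the `undefined` field rather than coerced to 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return A `metric_set` list with fields `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1` (fractions in `[0, 1]`) and
#'   `undefined`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion table is empty")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  out <- list(accuracy = (tp + tn) / total,
              precision = precision,
              recall = recall,
              specificity = sdiv(tn, tn + fp),
              f1 = f1)
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && is.na(v), logical(1))]
  structure(out, class = "metric_set")
}

#' Metrics as rounded percentages
#'
#' Converts a [compute_metrics()] result to percentages at a chosen
#' printed precision (round-half-even, R's default rounding).
#'
#' @param metrics A `metric_set`.
#' @param digits Decimal places, default 2.
#' @return Named numeric vector of percentages.
#' @export
metrics_percent <- function(metrics, digits = 2) {
  stopifnot(inherits(metrics, "metric_set"))
  v <- unlist(metrics[c("accuracy", "precision", "recall", "specificity",
                        "f1")])
  round(100 * v, digits)
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  pct <- metrics_percent(x, digits)
  for (nm in names(pct))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(pct[nm])) "undefined" else
                  sprintf(paste0("%.", digits, "f%%"), pct[nm])))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped into a single step), returning the ROC points and the
#' trapezoid-rule area under the curve. The AUC equals the tie-corrected
#' Mann-Whitney probability that a random positive outscores a random
#' negative.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels with both classes present.
#' @return List with `points` (data.frame: threshold, fpr, tpr) and
#'   `auc`; class `roc_curve`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  ss <- scores[ord]; ys <- y[ord]
  idx <- cumsum(rle(ss)$lengths)  # last index of each tie group
  tpr <- c(0, cumsum(ys)[idx] / npos)
  fpr <- c(0, cumsum(1L - ys)[idx] / nneg)
  thr <- c(Inf, ss[idx])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold steps, AUC = %.4f\n",
              nrow(x$points) - 1L, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Pearson correlation between predicted and true values
#'
#' Product-moment correlation, used to score predicted against
#' chronological age. Requires at least 3 pairs and non-degenerate
#' variances.
#'
#' @param predicted,true Numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(true) == 0)
    stop("zero variance: correlation undefined")
  cor(predicted, true)
}
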