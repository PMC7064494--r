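#' Classification metrics from a confusion matrix
#'
#' Standard definitions: sensitivity = tp / (tp + fn), specificity =
#' tn / (tn + fp), precision = tp / (tp + fp), accuracy = (tp + tn) / total,
#' F1 = harmonic mean of precision and sensitivity. The false-positive and
#' false-negative rates are the exact complements `1 - specificity` and
#' `1 - sensitivity`. A ratio with a zero denominator is recorded as 0 and
#' its name is added to the `undefined` attribute with a warning.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (total > 0).
#' @return An object of class `metric_set`: named list with `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `f1`, `fpr`, `fnr` and the
#'   counts.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts)) stop("confusion counts contain missing values ",
                          "(degenerate predictions?)")
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  acc <- (tp + tn) / total
  f1 <- if (prec + sens == 0) {
    undefined <- c(undefined, "f1")
    0
  } else 2 * prec * sens / (prec + sens)
  if (length(undefined))
    warning("undefined metric(s) recorded as 0: ",
            paste(undefined, collapse = ", "))
  structure(
    list(sensitivity = sens, specificity = spec, precision = prec,
         accuracy = acc, f1 = f1, fpr = 1 - spec, fnr = 1 - sens,
         tp = tp, fp = fp, fn = fn, tn = tn),
    class = "metric_set", undefined = undefined)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) score pairs ranked correctly, with ties counted as
#' one half. Equivalent to trapezoidal ROC integration.
#'
#' @param scores continuous classifier scores (higher = more positive).
#' @param labels binary (0/1) labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
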