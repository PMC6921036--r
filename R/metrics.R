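#' Binary classification performance metrics
#'
#' The four standard confusion-matrix summaries used for peptide activity
#' classifiers, each reported on a 0-100 scale:
#' sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' accuracy = 100 (TP+TN)/(TP+FN+TN+FP) and the Matthews correlation
#' coefficient
#' \deqn{MCC = 100\,\frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#'
#' @name classification_metrics
NULL

#' Confusion counts from truth and prediction
#'
#' @param truth Binary 0/1 vector of true labels (1 = positive class).
#' @param predicted Binary 0/1 vector of predicted labels.
#' @return One-row tibble `tp`, `fn`, `tn`, `fp` (sums to `length(truth)`).
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    abort("Labels must be binary 0/1.")
  }
  tibble(
    tp = sum(truth == 1 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1)
  )
}

#' Performance metrics from confusion counts
#'
#' Vectorized over count quadruples.  A metric whose denominator is zero is
#' returned as `NA` (undefined), not an error; all-zero counts yield all
#' `NA`.
#'
#' @param tp Either a numeric vector of true-positive counts, or a data
#'   frame / tibble with columns `tp`, `fn`, `tn`, `fp` (e.g.
#'   [confusion_counts()] output), in which case the remaining arguments are
#'   ignored.
#' @param fn,tn,fp False-negative, true-negative and false-positive counts.
#' @return Tibble with columns `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`, each on the 0-100 scale (MCC in \[-100, 100\]).
#' @examples
#' confusion_metrics(tp = 40, fn = 10, tn = 45, fp = 5)
#' @export
confusion_metrics <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp
    tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  }
  if (any(c(tp, fn, tn, fp) < 0)) abort("Counts must be non-negative.")
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  tn <- as.numeric(tn); fp <- as.numeric(fp)
  total <- tp + fn + tn + fp
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble(
    sensitivity = 100 * safe_div(tp, tp + fn),
    specificity = 100 * safe_div(tn, tn + fp),
    accuracy = 100 * safe_div(tp + tn, total),
    mcc = 100 * safe_div(tp * tn - fp * fn, mcc_den)
  )
}
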