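# Time-point classification metrics.

#' Area under the precision-recall curve (average precision)
#'
#' Interpolation-free step integration: precision is accumulated at every
#' positive, weighted by the recall increment (the average-precision
#' estimator). Ties in scores are handled by grouping.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUPRC in `[0, 1]`; `NA` if there are no positives.
#' @export
auprc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  P <- sum(labels == 1)
  if (P == 0 || length(scores) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  # evaluate at the last index of each tied score block
  idx <- cumsum(rle(s)$lengths)
  prec <- tp[idx] / (tp[idx] + fp[idx])
  rec <- tp[idx] / P
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic (tie-corrected).
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`; `NA` for single-class labels.
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
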