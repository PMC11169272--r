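#' Classification metrics
#'
#' `metric_auroc()` is the Mann-Whitney rank statistic (ties get half
#' credit); `metric_auprc()` is average precision computed as the step
#' integral of the precision-recall curve (not trapezoidal); and
#' `metric_brier()` is the mean squared difference between predicted
#' probability and binary outcome.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Logical or 0/1 labels.
#' @return A scalar metric value.
#' @export
metric_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metric_auroc
#' @export
metric_auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)  # average precision: step integral
}

#' @rdname metric_auroc
#' @export
metric_brier <- function(scores, labels) {
  mean((scores - as.numeric(as.logical(labels)))^2)
}
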