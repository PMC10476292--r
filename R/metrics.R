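# Ground-truth evaluation: confusion rates against a known outlier mask and
# the removal-fraction deviation statistic used for real-data comparisons.

#' Confusion rates of a predicted outlier mask
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A rate whose denominator is zero is
#' reported as `NA` (there is nothing to measure); F1 with a zero
#' denominator is reported as 0 and flagged via attribute
#' `"f1_degenerate"`, which keeps methods comparable.
#'
#' @param pred logical predicted mask.
#' @param truth logical ground-truth mask, same length.
#' @return named numeric vector `c(TPR, FPR, F1)`.
#' @export
#' @examples
#' confusion_rates(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
confusion_rates <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("confusion_rates: mask lengths differ")
  }
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  f1_den <- 2 * tp + fp + fn
  f1 <- if (f1_den > 0) 2 * tp / f1_den else 0
  out <- c(TPR = tpr, FPR = fpr, F1 = f1)
  if (f1_den == 0) attr(out, "f1_degenerate") <- TRUE
  out
}

#' Mean absolute deviation of removal fractions from a target
#'
#' For a well-calibrated detector run on many clean features, the fraction
#' removed per feature should sit near `1 - coverage` (0.7% at the default);
#' this statistic is the mean absolute difference from that target across
#' features.
#'
#' @param fractions per-column removal fractions.
#' @param target ideal removal fraction (default 0.007).
#' @return scalar mean absolute difference.
#' @export
#' @examples
#' removal_deviation(c(0.005, 0.009)) # 0.002
removal_deviation <- function(fractions, target = 0.007) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1)
  mean(abs(fractions - target))
}
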