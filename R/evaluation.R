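# Confusion-matrix bookkeeping and the six performance measures, with
# clash as the positive class: TP = clash-causing variants predicted not
# to fit, TN = compatible variants predicted to fit.

#' Confusion matrix with clash as the positive class
#'
#' @param predicted character vector of verdicts, `"clash"` or `"fits"`.
#' @param labels character vector of reference labels, same values and
#'   length, aligned with `predicted`.
#' @return A `confusion_matrix` list with tp, fp, tn, fn.
#' @export
confusion_matrix <- function(predicted, labels) {
  if (length(predicted) != length(labels))
    stop("predicted and labels differ in length")
  ok <- c("clash", "fits")
  if (!all(predicted %in% ok) || !all(labels %in% ok))
    stop('verdicts must be "clash" or "fits"')
  cm <- list(tp = sum(predicted == "clash" & labels == "clash"),
             fp = sum(predicted == "clash" & labels == "fits"),
             tn = sum(predicted == "fits" & labels == "fits"),
             fn = sum(predicted == "fits" & labels == "clash"))
  class(cm) <- "confusion_matrix"
  cm
}

#' Bundle raw counts into a confusion matrix
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
  cm <- list(tp = tp, fp = fp, tn = tn, fn = fn)
  class(cm) <- "confusion_matrix"
  cm
}

#' The six performance measures
#'
#' Accuracy, positive and negative predictive value, sensitivity (TPR),
#' specificity (TNR) and the Matthews correlation coefficient, each
#' reported at full precision. A score whose denominator is zero is
#' reported as NA (undefined), never as 0.
#'
#' @param cm a `confusion_matrix` with at least one counted case.
#' @return Named numeric vector: accuracy, ppv, npv, tpr, tnr, mcc.
#' @export
performance_scores <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total < 1) stop("scores are undefined for an empty confusion matrix")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  c(accuracy = div(tp + tn, total),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    tpr = div(tp, tp + fn),
    tnr = div(tn, tn + fp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

#' Round half-up to a fixed number of decimals
#'
#' Display-style rounding (0.745 -> 0.75 at 2 decimals), matching how the
#' performance tables are conventionally printed; `round()` in R rounds
#' half-to-even instead.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Score several labelled datasets and average
#'
#' @param matrices named list of `confusion_matrix` objects.
#' @param pooled average by recomputing scores on the pooled counts
#'   (TRUE) or by the unweighted mean of per-dataset scores (FALSE,
#'   default).
#' @return Matrix of scores, one row per dataset plus an `average` row.
#' @export
score_datasets <- function(matrices, pooled = FALSE) {
  rows <- t(vapply(matrices, performance_scores, numeric(6)))
  avg <- if (pooled) {
    tot <- confusion_counts(sum(vapply(matrices, `[[`, 0, "tp")),
                            sum(vapply(matrices, `[[`, 0, "fp")),
                            sum(vapply(matrices, `[[`, 0, "tn")),
                            sum(vapply(matrices, `[[`, 0, "fn")))
    performance_scores(tot)
  } else colMeans(rows, na.rm = TRUE)
  rbind(rows, average = avg)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (positive = clash): TP", x$tp, "FP", x$fp,
      "TN", x$tn, "FN", x$fn, "\n")
  invisible(x)
}
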