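## Confusion-count bookkeeping and the three evaluation statistics.

#' Accumulate decisions into confusion counts
#'
#' @param decisions list of \linkS4class{Decision}s (or a character vector of
#'   "ictal"/"interictal" predictions).
#' @param truth ground-truth labels: 1/0 integers or "ictal"/"interictal".
#' @return A \linkS4class{ConfusionCounts}; ictal is the positive class.
#' @export
accumulateCounts <- function(decisions, truth) {
  if (is.list(decisions))
    pred <- vapply(decisions, decisionLabel, character(1))
  else pred <- as.character(decisions)
  if (is.numeric(truth)) truth <- ifelse(truth == 1, "ictal", "interictal")
  truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("argument error: every decision needs a ground-truth label")
  if (anyNA(truth)) stop("argument error: unlabelled decision in the set")
  confusionCounts(
    TP = sum(pred == "ictal" & truth == "ictal"),
    FP = sum(pred == "ictal" & truth == "interictal"),
    TN = sum(pred == "interictal" & truth == "interictal"),
    FN = sum(pred == "interictal" & truth == "ictal"))
}

metricGuard <- function(den, what) {
  if (den < 1L) stop(sprintf("undefined metric: %s has empty denominator", what))
}

#' Sensitivity (true positive rate), percent
#'
#' `100 * TP / (TP + FN)`, rounded half-to-even to one decimal.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @param digits decimals to round to (default 1; NA for unrounded).
#' @return Percentage.
#' @export
#' @examples
#' sensitivity(confusionCounts(TP = 137, FN = 4, TN = 559, FP = 14))  # 97.2
sensitivity <- function(c, digits = 1L) {
  stopifnot(is(c, "ConfusionCounts"))
  metricGuard(c@TP + c@FN, "sensitivity (TP + FN)")
  pct <- 100 * c@TP / (c@TP + c@FN)
  if (is.na(digits)) pct else round(pct, digits)
}

#' Specificity (true negative rate), percent
#'
#' `100 * TN / (TN + FP)`, rounded half-to-even to one decimal.
#'
#' @inheritParams sensitivity
#' @return Percentage.
#' @export
#' @examples
#' specificity(confusionCounts(TP = 137, FN = 4, TN = 559, FP = 14))  # 97.6
specificity <- function(c, digits = 1L) {
  stopifnot(is(c, "ConfusionCounts"))
  metricGuard(c@TN + c@FP, "specificity (TN + FP)")
  pct <- 100 * c@TN / (c@TN + c@FP)
  if (is.na(digits)) pct else round(pct, digits)
}

#' Accuracy, percent
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`, rounded half-to-even to one
#' decimal.
#'
#' @inheritParams sensitivity
#' @return Percentage.
#' @export
#' @examples
#' accuracy(confusionCounts(TP = 137, FN = 4, TN = 559, FP = 14))  # 97.5
accuracy <- function(c, digits = 1L) {
  stopifnot(is(c, "ConfusionCounts"))
  total <- c@TP + c@FP + c@TN + c@FN
  metricGuard(total, "accuracy (total)")
  pct <- 100 * (c@TP + c@TN) / total
  if (is.na(digits)) pct else round(pct, digits)
}

#' Metrics report
#'
#' All three statistics plus the raw counts, as a list convertible to JSON.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return Named list with counts and the three percentages.
#' @export
metricsReport <- function(c) {
  list(counts = as.list(countsVector(c)),
       sensitivity_pct = sensitivity(c),
       specificity_pct = specificity(c),
       accuracy_pct = accuracy(c))
}
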