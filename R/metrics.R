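#' Binary confusion counts
#'
#' @param truth,pred vectors of true and predicted labels.
#' @param positive the label treated as positive; default the larger of
#'   the two sorted unique labels.
#' @return a list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, pred, positive = NULL) {
  stopifnot(length(truth) == length(pred))
  lv <- sort(unique(c(truth, pred)))
  if (is.null(positive)) positive <- lv[length(lv)]
  tP <- truth == positive
  pP <- pred == positive
  list(TP = sum(tP & pP), TN = sum(!tP & !pP),
       FP = sum(!tP & pP), FN = sum(tP & !pP))
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`,
#' `G-mean = sqrt(TP/(TP+FN) * TN/(TN+FP))` (geometric mean of
#' sensitivity and specificity). Division-by-zero cases return 0 with
#' attribute `"degenerate" = TRUE`.
#'
#' @param TP,TN,FP,FN nonnegative counts, or pass a list as `TP`.
#' @return named numeric vector `c(accuracy, f1, gmean)`.
#' @examples
#' computeMetrics(30, 30, 10, 10)  # all 0.75
#' @export
computeMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP)) { cm <- TP; TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN }
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion matrix")
  degenerate <- FALSE
  acc <- (TP + TN) / total
  f1 <- if (2 * TP + FP + FN == 0) { degenerate <- TRUE; 0 } else
    2 * TP / (2 * TP + FP + FN)
  sens <- if (TP + FN == 0) { degenerate <- TRUE; 0 } else TP / (TP + FN)
  spec <- if (TN + FP == 0) { degenerate <- TRUE; 0 } else TN / (TN + FP)
  out <- c(accuracy = acc, f1 = f1, gmean = sqrt(sens * spec))
  attr(out, "degenerate") <- degenerate
  out
}

# Macro-averaged metrics for multi-class labels: per-class one-vs-rest
# confusion counts, averaged; accuracy is the plain overall fraction.
macroMetrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  if (length(classes) <= 2L) {
    cm <- confusionCounts(truth, pred, positive = classes[length(classes)])
    return(computeMetrics(cm))
  }
  per <- sapply(classes, function(cl) {
    computeMetrics(confusionCounts(truth == cl, pred == cl,
                                   positive = TRUE))
  })
  c(accuracy = mean(truth == pred),
    f1 = mean(per["f1", ]), gmean = mean(per["gmean", ]))
}
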