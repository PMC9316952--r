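# Binary classification metrics: confusion matrix, accuracy/precision/
# recall/specificity/F1, ROC sweep and trapezoid AUC.

asPositiveLogical <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("positive", "negative")
    if (any(bad)) stop("labels must be 'positive'/'negative' or 0/1")
    return(labels == "positive")
  }
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
  labels == 1
}

#' Evaluate classifier scores against binary labels
#'
#' Confusion matrix and threshold metrics at `threshold`, an ROC curve from a
#' sweep over all distinct score values, and AUC by the trapezoid rule.
#' Requires both classes to be present (otherwise the ROC, and hence the AUC,
#' is undefined).
#'
#' @param scores numeric positive-class scores in `[0, 1]`.
#' @param labels `"positive"`/`"negative"` (factor or character) or 0/1.
#' @param threshold decision threshold for the confusion matrix.
#' @return an [EvalReport-class].
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  pos <- asPositiveLogical(labels)
  if (length(scores) != length(pos))
    stop("scores and labels must have equal length")
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("labels contain a single class; ROC/AUC are undefined")

  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c("positive", "negative"),
                                      predicted = c("positive", "negative")))

  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  # ROC sweep: thresholds descending through the distinct scores
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) sum(scores >= t & pos) / nP, 1)
  fpr <- vapply(ths, function(t) sum(scores >= t & !pos) / nN, 1)
  roc <- data.frame(threshold = c(Inf, ths), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)

  new("EvalReport", confusion = confusion,
      accuracy = (tp + tn) / length(pos), precision = precision,
      recall = recall, specificity = specificity, f1 = f1,
      roc = roc, auc = auc, threshold = threshold, n = length(pos))
}

#' Export an evaluation report
#'
#' Writes the metrics as JSON and the confusion matrix as CSV.
#'
#' @param report an [EvalReport-class].
#' @param jsonPath,csvPath output paths (either may be `NULL`).
#' @return invisibly, the list written to JSON.
#' @export
writeEvalReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  out <- list(n = report@n, threshold = report@threshold,
              accuracy = report@accuracy, precision = report@precision,
              recall = report@recall, specificity = report@specificity,
              f1 = report@f1, auc = report@auc,
              confusion = as.list(as.data.frame(report@confusion)))
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(report@confusion, csvPath)
  invisible(out)
}
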