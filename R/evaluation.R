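# Confusion-matrix metrics, ROC/AUC and cross-validated evaluation.

#' Confusion-matrix metrics
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, the standard F1 score 2TP/(2TP+FP+FN), the
#' `fScoreAsPrinted` variant 2TP/(2TP+FP+TN) that some reports use, and the
#' Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as `NA` rather than 0.
#'
#' @param counts named numeric/integer with elements TP, TN, FP, FN.
#' @return a [MetricsReport-class] (AUC slot `NA`; see [rocAUC()]).
#' @export
computeMetrics <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts)))
    stop("counts must be named TP, TN, FP, FN")
  counts <- counts[need]
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safeDiv <- function(num, den) if (den == 0) NA_real_ else num / den
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  new("MetricsReport",
      counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
      sensitivity = safeDiv(tp, tp + fn),
      specificity = safeDiv(tn, tn + fp),
      accuracy = safeDiv(tp + tn, tp + tn + fp + fn),
      fScore = safeDiv(2 * tp, 2 * tp + fp + fn),
      fScoreAsPrinted = safeDiv(2 * tp, 2 * tp + fp + tn),
      mcc = if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly drawn positive
#' outscores a randomly drawn negative, with ties counted 1/2. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels positive/negative indicators: +1/-1, 1/0, TRUE/FALSE or a
#'   factor whose second level is positive.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(scores, labels) {
  pos <- labels %in% c(1, "1", TRUE, "positive")
  if (is.factor(labels)) pos <- labels == levels(labels)[2]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes are required to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Empirical (FPR, TPR) points at every distinct score threshold, suitable
#' for plotting or TSV export.
#'
#' @inheritParams rocAUC
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(scores, labels) {
  pos <- labels %in% c(1, "1", TRUE, "positive")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    called <- scores >= t
    c(fpr = sum(called & !pos) / max(sum(!pos), 1),
      tpr = sum(called & pos) / max(sum(pos), 1))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Cross-validated evaluation of a scoring pipeline
#'
#' Splits the data into `k` seeded stratified folds, trains the pipeline on
#' each training split and scores the held-out fold. Reports the pooled-score
#' AUC, pooled confusion metrics at `cutoff`, and a per-fold breakdown.
#' The default pipeline is the package's SVR classifier at the configured
#' (cost, gamma).
#'
#' @param x features ([FeatureMatrix-class] or matrix).
#' @param labels +1/-1 labels (from `x` if a `FeatureMatrix`).
#' @param config an [SVRConfig-class] (drives the default pipeline, `k`,
#'   `seed` and `cutoff` defaults).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param trainFun,predictFun optional pipeline override: `trainFun(x,
#'   labels)` returns a model, `predictFun(model, x)` returns scores.
#' @return a [MetricsReport-class] with the `folds` slot filled.
#' @export
crossValidate <- function(x, labels = NULL, config = svrConfig(),
                          k = config@cvFolds, seed = config@seed,
                          trainFun = NULL, predictFun = NULL) {
  labels <- asLabels(x, labels)
  xm <- asFeatureData(x)
  if (is.null(trainFun))
    trainFun <- function(x, labels) trainSVR(x, labels, config)
  if (is.null(predictFun)) predictFun <- predictScores
  folds <- stratifiedFolds(labels, k, seed)
  scores <- numeric(length(labels))
  perFold <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    model <- trainFun(xm[tr, , drop = FALSE], labels[tr])
    s <- predictFun(model, xm[!tr, , drop = FALSE])
    scores[!tr] <<- s
    pred <- classifyScores(s, config@cutoff)
    truth <- labels[!tr]
    c(fold = f,
      TP = sum(pred == 1 & truth == 1), TN = sum(pred == -1 & truth == -1),
      FP = sum(pred == 1 & truth == -1), FN = sum(pred == -1 & truth == 1),
      auc = if (length(unique(truth)) == 2) rocAUC(s, truth) else NA_real_)
  })
  foldDf <- as.data.frame(do.call(rbind, perFold))
  pred <- classifyScores(scores, config@cutoff)
  counts <- c(TP = sum(pred == 1 & labels == 1),
              TN = sum(pred == -1 & labels == -1),
              FP = sum(pred == 1 & labels == -1),
              FN = sum(pred == -1 & labels == 1))
  report <- computeMetrics(counts)
  report@auc <- rocAUC(scores, labels)
  report@folds <- foldDf
  report
}
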