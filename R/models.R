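# SVR-as-classifier: epsilon-SVR with an RBF kernel trained on +1/-1 labels;
# the continuous regression score is thresholded into a cleavage call.

#' Construct an SVR training configuration
#'
#' Defaults follow libsvm conventions: epsilon 0.1, grid
#' c in 2^-5 .. 2^15 and gamma in 2^-15 .. 2^3, both in steps of x4,
#' five-fold cross-validation, classification cutoff 0 on the +1/-1
#' regression score. All values are user-configurable.
#'
#' @param cost,gamma current parameter values (used when no grid search is
#'   run).
#' @param epsilon epsilon-insensitive loss width.
#' @param costGrid,gammaGrid candidate grids for [gridSearchSVR()].
#' @param cutoff classification threshold on the regression score.
#' @param cvFolds folds for cross-validation (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @return an [SVRConfig-class].
#' @export
svrConfig <- function(cost = 1, gamma = 0.125, epsilon = 0.1,
                      costGrid = 2^seq(-5, 15, by = 2),
                      gammaGrid = 2^seq(-15, 3, by = 2),
                      cutoff = 0, cvFolds = 5L, seed = 1L) {
  new("SVRConfig", cost = cost, gamma = gamma, epsilon = epsilon,
      costGrid = costGrid, gammaGrid = gammaGrid, cutoff = cutoff,
      cvFolds = as.integer(cvFolds), seed = as.integer(seed))
}

asFeatureData <- function(x) {
  if (is(x, "FeatureMatrix")) featureData(x) else as.matrix(x)
}

asLabels <- function(x, labels) {
  if (is(x, "FeatureMatrix") && is.null(labels)) labels <- sampleLabels(x)
  if (!length(labels)) stop("labels are required")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1")
  labels
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds, preserving the class balance in
#' every fold; deterministic given `seed`.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Train an epsilon-SVR classifier
#'
#' Fits epsilon-SVR with an RBF kernel on features standardised with
#' statistics computed from the supplied (training) rows only; the stored
#' statistics are reapplied at prediction time, so no test-fold information
#' ever leaks into the scaling.
#'
#' @param x [FeatureMatrix-class] or numeric matrix with named columns.
#' @param labels +1/-1 labels (taken from `x` if a `FeatureMatrix`).
#' @param config an [SVRConfig-class].
#' @return a [TrainedSVR-class].
#' @export
trainSVR <- function(x, labels = NULL, config = svrConfig()) {
  labels <- asLabels(x, labels)
  xm <- asFeatureData(x)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (!all(is.finite(xm))) stop("feature matrix must be finite")
  center <- colMeans(xm)
  scale <- apply(xm, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(xm, center = center, scale = scale)
  fit <- e1071::svm(x = xs, y = labels, type = "eps-regression",
                    kernel = "radial", cost = config@cost,
                    gamma = config@gamma, epsilon = config@epsilon,
                    scale = FALSE)
  fp <- sprintf("n=%d p=%d sum=%.6g labsum=%d", nrow(xm), ncol(xm),
                sum(xm), sum(labels))
  new("TrainedSVR", featureNames = colnames(xm), fit = fit,
      center = setNames(as.numeric(center), colnames(xm)),
      scale = setNames(as.numeric(scale), colnames(xm)),
      config = config, fingerprint = fp)
}

#' Predict continuous SVR scores
#'
#' @param model a [TrainedSVR-class].
#' @param x matrix or [FeatureMatrix-class] containing at least the model's
#'   feature columns (any order; extra columns are ignored).
#' @return numeric scores, one per row; larger = more cleavage-like.
#' @export
predictScores <- function(model, x) {
  xm <- asFeatureData(x)
  missing <- setdiff(model@featureNames, colnames(xm))
  if (length(missing))
    stop("prediction data lacks feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  xm <- xm[, model@featureNames, drop = FALSE]
  xs <- scale(xm, center = model@center, scale = model@scale)
  as.numeric(stats::predict(model@fit, xs))
}

#' Threshold scores into cleavage calls
#'
#' @param scores numeric prediction scores.
#' @param cutoff classification threshold (default 0); scores strictly above
#'   it are called positive.
#' @return integer labels +1/-1.
#' @export
classifyScores <- function(scores, cutoff = 0) {
  ifelse(scores > cutoff, 1L, -1L)
}

# Per-fold AUCs of an SVR at fixed (cost, gamma) under a given fold
# assignment. Standardisation happens inside trainSVR on the training rows
# of each fold only.
foldAUCs <- function(xm, labels, folds, config) {
  vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    te <- !tr
    stopifnot(!any(tr & te))          # train/test disjointness per fold
    model <- trainSVR(xm[tr, , drop = FALSE], labels[tr], config)
    rocAUC(predictScores(model, xm[te, , drop = FALSE]), labels[te])
  }, numeric(1))
}

#' Grid search for SVR cost and gamma
#'
#' Evaluates every (cost, gamma) grid point by mean cross-validated AUC
#' under seeded stratified folds (the same folds for every point) and
#' returns the maximiser; exact ties resolve to the smallest cost, then the
#' smallest gamma.
#'
#' @param x features ([FeatureMatrix-class] or matrix).
#' @param labels +1/-1 labels.
#' @param config an [SVRConfig-class]; its `costGrid`, `gammaGrid`,
#'   `cvFolds` and `seed` drive the search.
#' @return the input config with `cost` and `gamma` set to the winning
#'   point, plus attributes `cvAUC` (winning mean AUC) and `grid`
#'   (data.frame of all evaluated points).
#' @export
gridSearchSVR <- function(x, labels = NULL, config = svrConfig()) {
  labels <- asLabels(x, labels)
  xm <- asFeatureData(x)
  folds <- stratifiedFolds(labels, config@cvFolds, config@seed)
  grid <- expand.grid(gamma = sort(config@gammaGrid),
                      cost = sort(config@costGrid))[, c("cost", "gamma")]
  grid <- grid[order(grid$cost, grid$gamma), ]
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg@cost <- grid$cost[i]
    cfg@gamma <- grid$gamma[i]
    mean(foldAUCs(xm, labels, folds, cfg))
  }, numeric(1))
  best <- which.max(aucs)             # first max: smallest cost, then gamma
  config@cost <- grid$cost[best]
  config@gamma <- grid$gamma[best]
  attr(config, "cvAUC") <- aucs[best]
  attr(config, "grid") <- cbind(grid, meanAUC = aucs)
  config
}
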