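# Knowledge-transfer learning: common-knowledge extraction from source
# proteases, candidate-list construction, AUC-driven forward selection on
# the target, and the merged-data baseline.

poolFeatureMatrices <- function(matrices) {
  cols <- lapply(matrices, featureNames)
  if (!all(vapply(cols, identical, logical(1), cols[[1]])))
    stop("all datasets must be encoded on the same feature columns")
  new("FeatureMatrix",
      data = do.call(rbind, lapply(matrices, featureData)),
      labels = unlist(lapply(matrices, sampleLabels), use.names = FALSE))
}

#' Extract common knowledge from the source domain
#'
#' Pools the labelled rows of all source-domain datasets (encoded on the
#' same feature universe) and ranks the top `mCommon` features by mRMR.
#' These features are the "common knowledge" transferred to the target
#' protease.
#'
#' @param sourceMatrices named list of [FeatureMatrix-class] objects, one
#'   per source protease.
#' @param mCommon number of features to transfer (default 50; 0 gives an
#'   empty knowledge set, useful for ablation).
#' @return a [CommonKnowledge-class].
#' @export
extractCommonKnowledge <- function(sourceMatrices, mCommon = 50) {
  if (!length(sourceMatrices)) stop("at least one source dataset is required")
  pooled <- poolFeatureMatrices(sourceMatrices)
  if (mCommon > ncol(featureData(pooled)))
    stop("'mCommon' exceeds the number of feature columns")
  nm <- names(sourceMatrices)
  if (is.null(nm)) nm <- paste0("source", seq_along(sourceMatrices))
  if (mCommon == 0)
    return(new("CommonKnowledge", features = character(0),
               score = numeric(0), sourceNames = nm))
  ranking <- mrmrRank(pooled, m = mCommon)
  new("CommonKnowledge", features = ranking@features,
      score = ranking@score, sourceNames = nm)
}

#' Combine common knowledge with target-ranked features
#'
#' Builds the forward-selection candidate list: the common features first,
#' in their source-domain order, followed by the target's top-`mTarget`
#' mRMR features that are not already present, in target-rank order.
#'
#' @param common a [CommonKnowledge-class] (or character vector).
#' @param targetRanking a [FeatureRanking-class] (or character vector) from
#'   the target dataset.
#' @param mTarget number of target-ranked features to consider (default
#'   100).
#' @return character vector of candidate features without duplicates, with
#'   attribute `origin` ("common" / "target_novel").
#' @export
buildCandidateList <- function(common, targetRanking, mTarget = 100) {
  cf <- if (is(common, "CommonKnowledge")) common@features else common
  tf <- if (is(targetRanking, "FeatureRanking"))
    targetRanking@features else targetRanking
  tf <- utils::head(tf, mTarget)
  novel <- setdiff(tf, cf)
  out <- c(cf, novel)
  attr(out, "origin") <- c(rep("common", length(cf)),
                           rep("target_novel", length(novel)))
  out
}

#' AUC-driven forward selection over a candidate feature list
#'
#' Walks the candidate list in order, adding one feature at a time; each
#' prefix trains an SVR and is scored by mean seeded stratified
#' cross-validated AUC (the same folds for every prefix). The selected
#' model uses the AUC-maximising prefix (exact ties resolve to the shortest
#' prefix) and is refitted on all target rows.
#'
#' By default a single grid search for (cost, gamma) is run on the full
#' candidate list and the winning point reused for every prefix;
#' `perPrefixGrid = TRUE` re-optimises at every prefix length (slower,
#' stricter).
#'
#' @param candidateList ordered feature names (see [buildCandidateList()]).
#' @param target the target-domain [FeatureMatrix-class] (labelled).
#' @param config an [SVRConfig-class].
#' @param gridSearch run [gridSearchSVR()] on the full list first.
#' @param perPrefixGrid grid-search at every prefix instead.
#' @return a [TransferResult-class].
#' @export
forwardSelect <- function(candidateList, target, config = svrConfig(),
                          gridSearch = TRUE, perPrefixGrid = FALSE) {
  if (!length(candidateList)) stop("candidate list is empty")
  labels <- sampleLabels(target)
  if (!length(labels)) stop("target dataset must be labelled")
  if (min(table(labels)) < 2L * config@cvFolds)
    stop("target dataset needs at least 2 samples per class per fold")
  xm <- featureData(target)
  missing <- setdiff(candidateList, colnames(xm))
  if (length(missing))
    stop("candidate feature(s) absent from target matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  origin <- attr(candidateList, "origin")
  if (is.null(origin)) origin <- rep("target_novel", length(candidateList))
  candidateList <- as.character(candidateList)
  xm <- xm[, candidateList, drop = FALSE]
  if (gridSearch && !perPrefixGrid)
    config <- gridSearchSVR(xm, labels, config)
  folds <- stratifiedFolds(labels, config@cvFolds, config@seed)
  trace <- t(vapply(seq_along(candidateList), function(nfeat) {
    xs <- xm[, seq_len(nfeat), drop = FALSE]
    cfg <- if (perPrefixGrid) gridSearchSVR(xs, labels, config) else config
    a <- foldAUCs(xs, labels, folds, cfg)
    c(mean = mean(a), sd = stats::sd(a))
  }, numeric(2)))
  best <- which.max(trace[, "mean"])   # ties -> shortest prefix
  bestCfg <- if (perPrefixGrid)
    gridSearchSVR(xm[, seq_len(best), drop = FALSE], labels, config) else
    config
  model <- trainSVR(xm[, seq_len(best), drop = FALSE], labels, bestCfg)
  new("TransferResult", candidateList = candidateList, origin = origin,
      aucTrace = as.numeric(trace[, "mean"]),
      aucTraceSD = as.numeric(trace[, "sd"]),
      bestPrefixLength = as.integer(best), model = model)
}

#' Leave-one-protease-out knowledge transfer
#'
#' Full transfer pipeline for one target protease: common knowledge is
#' extracted from every dataset except the target (the target never
#' contributes rows to the source pool), the target's own top-`mTarget`
#' features are ranked, the combined candidate list is forward-selected,
#' and the best-prefix model refitted on the target.
#'
#' @param datasets named list of labelled [FeatureMatrix-class] objects,
#'   one per protease, all on the same feature universe.
#' @param targetName name of the target dataset within `datasets`.
#' @param mCommon common-knowledge size (default 50).
#' @param mTarget target ranking depth (default 100).
#' @param config an [SVRConfig-class].
#' @param gridSearch,perPrefixGrid see [forwardSelect()].
#' @return a [TransferResult-class].
#' @export
transferLearn <- function(datasets, targetName, mCommon = 50, mTarget = 100,
                          config = svrConfig(), gridSearch = TRUE,
                          perPrefixGrid = FALSE) {
  if (!targetName %in% names(datasets))
    stop("'targetName' not found among datasets")
  sources <- datasets[setdiff(names(datasets), targetName)]
  target <- datasets[[targetName]]
  common <- extractCommonKnowledge(sources, mCommon)
  targetRanking <- mrmrRank(target, m = min(mTarget,
                                            ncol(featureData(target))))
  candidates <- buildCandidateList(common, targetRanking, mTarget)
  forwardSelect(candidates, target, config, gridSearch = gridSearch,
                perPrefixGrid = perPrefixGrid)
}

#' Nested cross-validated evaluation of the transfer pipeline
#'
#' Unbiased performance estimate for [transferLearn()]: the target rows are
#' split into seeded stratified outer folds, and *all* target-side
#' selection — the target mRMR ranking, the candidate list and the
#' AUC-driven forward selection — is redone inside each outer training
#' fold, so no held-out row ever influences which features are chosen.
#' Common knowledge still comes from the source datasets only (which never
#' contain target rows). The held-out scores are pooled into one
#' [MetricsReport-class].
#'
#' This is roughly `outerFolds` times the cost of [transferLearn()]; the
#' plain function's reported AUC trace, which selects target features on
#' the full target dataset first, is optimistically biased in comparison
#' (substantially so when the feature space is much larger than the number
#' of target windows).
#'
#' @inheritParams transferLearn
#' @param outerFolds number of outer evaluation folds (default
#'   `config@cvFolds`).
#' @return a [MetricsReport-class]; attribute `results` holds the per-fold
#'   [TransferResult-class] objects.
#' @export
transferLearnCV <- function(datasets, targetName, mCommon = 50,
                            mTarget = 100, config = svrConfig(),
                            gridSearch = TRUE,
                            outerFolds = config@cvFolds) {
  if (!targetName %in% names(datasets))
    stop("'targetName' not found among datasets")
  sources <- datasets[setdiff(names(datasets), targetName)]
  target <- datasets[[targetName]]
  common <- extractCommonKnowledge(sources, mCommon)
  labels <- sampleLabels(target)
  xm <- featureData(target)
  folds <- stratifiedFolds(labels, outerFolds, config@seed + 1L)
  scores <- numeric(length(labels))
  results <- vector("list", outerFolds)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    trainFM <- new("FeatureMatrix", data = xm[tr, , drop = FALSE],
                   labels = labels[tr])
    ranking <- mrmrRank(trainFM, m = min(mTarget, ncol(xm)))
    candidates <- buildCandidateList(common, ranking, mTarget)
    res <- forwardSelect(candidates, trainFM, config,
                         gridSearch = gridSearch)
    scores[!tr] <- predictScores(res@model, xm[!tr, , drop = FALSE])
    results[[f]] <- res
  }
  pred <- classifyScores(scores, config@cutoff)
  counts <- c(TP = sum(pred == 1 & labels == 1),
              TN = sum(pred == -1 & labels == -1),
              FP = sum(pred == 1 & labels == -1),
              FN = sum(pred == -1 & labels == 1))
  report <- computeMetrics(counts)
  report@auc <- rocAUC(scores, labels)
  report@folds <- data.frame(fold = sort(unique(folds)))
  attr(report, "results") <- results
  report
}

#' Merged-data baseline model
#'
#' The non-transfer reference: all datasets are merged without
#' source/target distinction, the top `m` mRMR features are selected on the
#' merged data, and an SVR on those features is evaluated on the target
#' dataset by seeded stratified cross-validation. `targetOnlySelection`
#' switches to the alternative reading in which the top-`m` features are
#' ranked on the target data alone.
#'
#' @param datasets named list of labelled [FeatureMatrix-class] objects.
#' @param targetName the protease being predicted.
#' @param m number of features (default 100).
#' @param config an [SVRConfig-class].
#' @param gridSearch optimise (cost, gamma) on the selected features.
#' @param targetOnlySelection rank features on the target only.
#' @return list with elements `model` ([TrainedSVR-class], fitted on all
#'   target rows), `metrics` ([MetricsReport-class] from target CV) and
#'   `ranking` ([FeatureRanking-class]).
#' @export
trainBaseline <- function(datasets, targetName, m = 100,
                          config = svrConfig(), gridSearch = TRUE,
                          targetOnlySelection = FALSE) {
  if (!targetName %in% names(datasets))
    stop("'targetName' not found among datasets")
  target <- datasets[[targetName]]
  corpus <- if (targetOnlySelection) target else
    poolFeatureMatrices(datasets)
  m <- min(m, ncol(featureData(corpus)))
  ranking <- mrmrRank(corpus, m = m)
  xm <- featureData(target)[, ranking@features, drop = FALSE]
  labels <- sampleLabels(target)
  if (gridSearch) config <- gridSearchSVR(xm, labels, config)
  metrics <- crossValidate(xm, labels, config)
  model <- trainSVR(xm, labels, config)
  list(model = model, metrics = metrics, ranking = ranking)
}

#' Export a transfer result
#'
#' Writes the AUC trace as TSV (`prefix_length`, `mean_auc`, `sd_auc`) and,
#' optionally, a JSON summary of the chosen features with their
#' common/target-novel origin.
#'
#' @param result a [TransferResult-class].
#' @param tracePath TSV output path.
#' @param summaryPath optional JSON output path.
#' @export
writeTransferResult <- function(result, tracePath, summaryPath = NULL) {
  utils::write.table(
    data.frame(prefix_length = seq_along(result@aucTrace),
               mean_auc = result@aucTrace, sd_auc = result@aucTraceSD),
    tracePath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summaryPath)) {
    sel <- seq_len(result@bestPrefixLength)
    jsonlite::write_json(
      list(best_prefix_length = result@bestPrefixLength,
           cv_auc = result@aucTrace[result@bestPrefixLength],
           features = data.frame(feature = result@candidateList[sel],
                                 origin = result@origin[sel])),
      summaryPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}
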