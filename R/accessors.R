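# Accessor generics, methods and show() methods for the core classes.

#' @rdname Substrate-class
#' @param object a `Substrate`.
#' @export
setGeneric("substrateSequence",
           function(object) standardGeneric("substrateSequence"))
#' @rdname Substrate-class
#' @export
setMethod("substrateSequence", "Substrate", function(object) object@sequence)

#' @rdname Substrate-class
#' @export
setGeneric("cleavageSites", function(object) standardGeneric("cleavageSites"))
#' @rdname Substrate-class
#' @export
setMethod("cleavageSites", "Substrate",
          function(object) object@cleavagePositions)

#' @rdname DomainDataset-class
#' @param object a `DomainDataset`.
#' @export
setGeneric("windows", function(object) standardGeneric("windows"))
#' @rdname DomainDataset-class
#' @export
setMethod("windows", "DomainDataset", function(object) object@windows)

#' @rdname DomainDataset-class
#' @export
setGeneric("datasetName", function(object) standardGeneric("datasetName"))
#' @rdname DomainDataset-class
#' @export
setMethod("datasetName", "DomainDataset", function(object) object@name)

#' @rdname FeatureMatrix-class
#' @param object a `FeatureMatrix`.
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureData", "FeatureMatrix", function(object) object@data)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureNames", "FeatureMatrix",
          function(object) colnames(object@data))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(object) object@labels)

#' @rdname FeatureRanking-class
#' @param object a `FeatureRanking` or `CommonKnowledge`.
#' @export
setGeneric("rankedFeatures", function(object) standardGeneric("rankedFeatures"))
#' @rdname FeatureRanking-class
#' @export
setMethod("rankedFeatures", "FeatureRanking", function(object) object@features)
#' @rdname CommonKnowledge-class
#' @export
setMethod("rankedFeatures", "CommonKnowledge", function(object) object@features)

#' @rdname TransferResult-class
#' @param object a `TransferResult`.
#' @export
setGeneric("aucTrace", function(object) standardGeneric("aucTrace"))
#' @rdname TransferResult-class
#' @export
setMethod("aucTrace", "TransferResult", function(object) object@aucTrace)

#' @rdname TransferResult-class
#' @export
setGeneric("bestPrefixLength",
           function(object) standardGeneric("bestPrefixLength"))
#' @rdname TransferResult-class
#' @export
setMethod("bestPrefixLength", "TransferResult",
          function(object) object@bestPrefixLength)

#' @rdname TransferResult-class
#' @export
setGeneric("selectedFeatures",
           function(object) standardGeneric("selectedFeatures"))
#' @rdname TransferResult-class
#' @export
setMethod("selectedFeatures", "TransferResult", function(object)
  object@candidateList[seq_len(object@bestPrefixLength)])
#' @rdname TrainedSVR-class
#' @param object a `TrainedSVR`.
#' @export
setMethod("selectedFeatures", "TrainedSVR", function(object)
  object@featureNames)

#' @rdname EntropyProfile-class
#' @param object an `EntropyProfile`.
#' @export
setGeneric("entropyBits", function(object) standardGeneric("entropyBits"))
#' @rdname EntropyProfile-class
#' @export
setMethod("entropyBits", "EntropyProfile", function(object) object@entropy)

setMethod("show", "Substrate", function(object) {
  cat("Substrate", object@id, "-", nchar(object@sequence), "aa,",
      length(object@cleavagePositions), "cleavage site(s)\n")
  cat("  profiles:",
      paste(c("accessibility", "disorder",
              "pssm")[c(length(object@accessibility) > 0,
                        length(object@disorder) > 0,
                        nrow(object@pssm) > 0)], collapse = ", "),
      "\n")
})

setMethod("show", "DomainDataset", function(object) {
  tab <- table(factor(object@windows$label, c("positive", "negative")))
  cat("DomainDataset", object@name, sprintf("(%s domain)\n", object@role))
  cat("  windows:", nrow(object@windows),
      sprintf("(%d positive, %d negative)", tab[["positive"]],
              tab[["negative"]]), "\n")
  if (object@negativeShortage)
    cat("  note: fewer negative candidates than the requested ratio\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@data), "windows x",
      ncol(object@data), "features\n")
  schemes <- unique(sub("\\..*$", "", colnames(object@data)))
  cat("  schemes:", paste(schemes, collapse = ", "), "\n")
  if (length(object@labels))
    cat("  labels:", sum(object@labels == 1), "positive /",
        sum(object@labels == -1), "negative\n")
})

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking with", length(object@features), "features; top:\n")
  top <- utils::head(data.frame(feature = object@features,
                                relevance_bits = object@relevance,
                                mrmr_score = object@score), 5)
  print(top, row.names = FALSE)
})

setMethod("show", "CommonKnowledge", function(object) {
  cat("CommonKnowledge:", length(object@features),
      "features pooled from sources:",
      paste(object@sourceNames, collapse = ", "), "\n")
})

setMethod("show", "TransferResult", function(object) {
  cat("TransferResult:", length(object@candidateList), "candidates",
      sprintf("(%d common, %d target-novel)\n",
              sum(object@origin == "common"),
              sum(object@origin == "target_novel")))
  cat("  best prefix:", object@bestPrefixLength,
      sprintf("features, CV AUC %.3f\n",
              object@aucTrace[object@bestPrefixLength]))
})

setMethod("show", "TrainedSVR", function(object) {
  cat("TrainedSVR on", length(object@featureNames), "features",
      sprintf("(cost %.4g, gamma %.4g)\n", object@config@cost,
              object@config@gamma))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              object@sensitivity, object@specificity, object@accuracy))
  cat(sprintf("  F1 %.3f  MCC %.3f  AUC %s\n", object@fScore, object@mcc,
              ifelse(is.na(object@auc), "NA", sprintf("%.3f", object@auc))))
})

setMethod("show", "EntropyProfile", function(object) {
  cat("EntropyProfile for", object@protease, "-", object@nWindows,
      "windows\n")
  cat(sprintf("  average entropy %.3f bits (max %.3f)\n", object@average,
              log2(20)))
})
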