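# Single-file model serialization: a JSON document whose header carries the
# feature names, configuration and scaler statistics in the clear, with the
# fitted SVR state as an opaque base64 payload.

#' Save a trained SVR model to one JSON file
#'
#' @param model a [TrainedSVR-class].
#' @param path output path.
#' @export
saveTrainedSVR <- function(model, path) {
  cfg <- model@config
  doc <- list(
    format = "CleaveTransfer-SVR",
    version = 1L,
    featureNames = model@featureNames,
    config = list(cost = cfg@cost, gamma = cfg@gamma, epsilon = cfg@epsilon,
                  cutoff = cfg@cutoff, cvFolds = cfg@cvFolds,
                  seed = cfg@seed, costGrid = cfg@costGrid,
                  gammaGrid = cfg@gammaGrid),
    center = as.list(model@center),
    scale = as.list(model@scale),
    fingerprint = model@fingerprint,
    payload = jsonlite::base64_enc(serialize(model@fit, NULL))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a trained SVR model saved by [saveTrainedSVR()]
#'
#' @param path path to the JSON model file.
#' @return a [TrainedSVR-class].
#' @export
loadTrainedSVR <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "CleaveTransfer-SVR"))
    stop("not a CleaveTransfer SVR model file")
  cfg <- svrConfig(cost = doc$config$cost, gamma = doc$config$gamma,
                   epsilon = doc$config$epsilon, cutoff = doc$config$cutoff,
                   costGrid = doc$config$costGrid,
                   gammaGrid = doc$config$gammaGrid,
                   cvFolds = doc$config$cvFolds, seed = doc$config$seed)
  fit <- unserialize(jsonlite::base64_dec(doc$payload))
  new("TrainedSVR", featureNames = doc$featureNames, fit = fit,
      center = unlist(doc$center), scale = unlist(doc$scale),
      config = cfg, fingerprint = doc$fingerprint)
}
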