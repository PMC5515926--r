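#' @import methods
NULL

#' Substrate: a protease substrate with cleavage annotations
#'
#' Holds one substrate protein sequence together with its experimentally
#' annotated cleavage sites and, optionally, per-residue profiles consumed by
#' the profile-based encoders: solvent accessibility classes ('b' buried /
#' 'e' exposed), disorder probabilities, and a PSI-BLAST PSSM.
#'
#' Cleavage positions are 1-based P1 indices: the scissile bond lies between
#' residue `p` and residue `p + 1`, so every position satisfies
#' `1 <= p < nchar(sequence)`.
#'
#' @slot id substrate identifier (must match FASTA / annotation ids).
#' @slot sequence amino-acid string over the 20 standard letters plus 'X'.
#' @slot cleavagePositions integer vector of 1-based P1 positions.
#' @slot accessibility per-residue 'b'/'e' classes, or `character(0)`.
#' @slot disorder per-residue disorder probabilities in `[0, 1]`, or
#'   `numeric(0)`.
#' @slot pssm residues x 20 matrix of log-odds scores (columns in
#'   alphabetical one-letter order), or a 0 x 0 matrix when absent.
#' @export
setClass("Substrate",
  representation(
    id = "character",
    sequence = "character",
    cleavagePositions = "integer",
    accessibility = "character",
    disorder = "numeric",
    pssm = "matrix"
  ),
  prototype(
    cleavagePositions = integer(0),
    accessibility = character(0),
    disorder = numeric(0),
    pssm = matrix(numeric(0), 0, 0)
  )
)

setValidity("Substrate", function(object) {
  msgs <- character(0)
  n <- nchar(object@sequence)
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "'id' must be a single non-empty string")
  if (length(object@sequence) != 1L)
    msgs <- c(msgs, "'sequence' must be a single string")
  bad <- setdiff(strsplit(object@sequence, "")[[1]], c(AA_STANDARD20, "X"))
  if (length(bad))
    msgs <- c(msgs, paste0("non-standard residue letters: ",
                           paste(unique(bad), collapse = ", ")))
  cp <- object@cleavagePositions
  if (length(cp) && (any(cp < 1L) || any(cp >= n)))
    msgs <- c(msgs, "cleavage positions must satisfy 1 <= p < sequence length")
  if (anyDuplicated(cp))
    msgs <- c(msgs, "duplicated cleavage positions")
  if (length(object@accessibility) && length(object@accessibility) != n)
    msgs <- c(msgs, "accessibility profile length != sequence length")
  if (length(object@accessibility) &&
      !all(object@accessibility %in% c("b", "e")))
    msgs <- c(msgs, "accessibility classes must be 'b' or 'e'")
  if (length(object@disorder) && length(object@disorder) != n)
    msgs <- c(msgs, "disorder profile length != sequence length")
  if (length(object@disorder) &&
      (any(object@disorder < 0) || any(object@disorder > 1)))
    msgs <- c(msgs, "disorder probabilities must lie in [0, 1]")
  if (nrow(object@pssm) && (nrow(object@pssm) != n || ncol(object@pssm) != 20L))
    msgs <- c(msgs, "pssm must be a (sequence length) x 20 matrix")
  if (length(msgs)) msgs else TRUE
})

#' DomainDataset: labelled cleavage windows for one protease domain
#'
#' A set of 16-residue cleavage windows (P8..P1 | P1'..P8') with binary
#' labels, as produced by [sampleNegatives()]. The `windows` data frame has
#' columns `substrateId`, `p1Position`, `residues`, `label`
#' ("positive"/"negative").
#'
#' @slot name protease/domain name, e.g. "MMP-7".
#' @slot role `"source"` or `"target"`.
#' @slot windows data.frame of windows (see above).
#' @slot negativeShortage `TRUE` when fewer negative candidates existed than
#'   the requested negatives:positives ratio, so all were kept.
#' @export
setClass("DomainDataset",
  representation(
    name = "character",
    role = "character",
    windows = "data.frame",
    negativeShortage = "logical"
  ),
  prototype(role = "source", negativeShortage = FALSE)
)

setValidity("DomainDataset", function(object) {
  msgs <- character(0)
  need <- c("substrateId", "p1Position", "residues", "label")
  if (!all(need %in% names(object@windows)))
    msgs <- c(msgs, paste0("'windows' must have columns ",
                           paste(need, collapse = ", ")))
  if (!object@role %in% c("source", "target"))
    msgs <- c(msgs, "'role' must be \"source\" or \"target\"")
  if (all(need %in% names(object@windows)) && nrow(object@windows)) {
    if (!all(nchar(object@windows$residues) == 16L))
      msgs <- c(msgs, "all windows must be 16 residues long")
    if (!all(object@windows$label %in% c("positive", "negative")))
      msgs <- c(msgs, "labels must be \"positive\" or \"negative\"")
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: encoded windows
#'
#' Rows are windows, columns are scheme-qualified named features (the full
#' eight-scheme concatenation has 4461 columns). Labels are +1 (cleaved) /
#' -1 (not cleaved).
#'
#' @slot data numeric matrix with feature column names and window row names.
#' @slot labels numeric vector of +1/-1, or `numeric(0)` for unlabelled data.
#' @export
setClass("FeatureMatrix",
  representation(data = "matrix", labels = "numeric"),
  prototype(labels = numeric(0))
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character(0)
  if (is.null(colnames(object@data)))
    msgs <- c(msgs, "feature columns must be named")
  if (anyDuplicated(colnames(object@data)))
    msgs <- c(msgs, "duplicated feature names")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@data))
    msgs <- c(msgs, "labels length != number of rows")
  if (length(object@labels) && !all(object@labels %in% c(-1, 1)))
    msgs <- c(msgs, "labels must be +1 or -1")
  if (length(msgs)) msgs else TRUE
})

#' FeatureRanking: an ordered mRMR feature ranking
#'
#' @slot features ordered feature names, best first.
#' @slot relevance mutual information with the label (bits), per feature.
#' @slot score mRMR (MID) score at the step each feature was selected;
#'   for the first feature this equals its relevance.
#' @export
setClass("FeatureRanking",
  representation(features = "character", relevance = "numeric",
                 score = "numeric")
)

setValidity("FeatureRanking", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@features))
    msgs <- c(msgs, "duplicated feature names in ranking")
  if (length(object@relevance) != length(object@features) ||
      length(object@score) != length(object@features))
    msgs <- c(msgs, "features, relevance and score must have equal length")
  if (length(msgs)) msgs else TRUE
})

#' SVRConfig: support-vector-regression training configuration
#'
#' @slot cost SVR cost parameter c (> 0).
#' @slot gamma RBF kernel width (> 0).
#' @slot epsilon epsilon-insensitive loss width.
#' @slot costGrid,gammaGrid candidate values for grid search.
#' @slot cutoff classification threshold on the regression score.
#' @slot cvFolds number of cross-validation folds (>= 2).
#' @slot seed integer seed controlling fold assignment.
#' @export
setClass("SVRConfig",
  representation(
    cost = "numeric", gamma = "numeric", epsilon = "numeric",
    costGrid = "numeric", gammaGrid = "numeric",
    cutoff = "numeric", cvFolds = "integer", seed = "integer"
  )
)

setValidity("SVRConfig", function(object) {
  msgs <- character(0)
  if (object@cost <= 0 || object@gamma <= 0)
    msgs <- c(msgs, "cost and gamma must be positive")
  if (any(object@costGrid <= 0) || any(object@gammaGrid <= 0))
    msgs <- c(msgs, "grid values must be positive")
  if (object@cvFolds < 2L)
    msgs <- c(msgs, "cvFolds must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' TrainedSVR: a fitted SVR classifier
#'
#' Wraps an epsilon-SVR fit (RBF kernel) together with the exact ordered
#' feature set it was trained on and the training-fold standardisation
#' statistics, so prediction reproduces the training-time feature space.
#'
#' @slot featureNames ordered feature names the model requires.
#' @slot fit the underlying [e1071::svm] object.
#' @slot center,scale per-feature standardisation statistics (training rows
#'   only).
#' @slot config the [SVRConfig-class] used.
#' @slot fingerprint digest of the training data (row/column counts and
#'   checksums) for provenance.
#' @export
setClass("TrainedSVR",
  representation(
    featureNames = "character", fit = "ANY",
    center = "numeric", scale = "numeric",
    config = "SVRConfig", fingerprint = "character"
  )
)

#' CommonKnowledge: features transferred from the source domain
#'
#' The top-m mRMR features (default 50) selected on the pooled, labelled
#' source-domain data.
#'
#' @slot features ordered feature names.
#' @slot score mRMR score of each feature at selection.
#' @slot sourceNames names of the source datasets pooled.
#' @export
setClass("CommonKnowledge",
  representation(features = "character", score = "numeric",
                 sourceNames = "character")
)

setValidity("CommonKnowledge", function(object) {
  if (anyDuplicated(object@features)) "duplicated features" else TRUE
})

#' TransferResult: outcome of AUC-driven forward selection on the target
#'
#' @slot candidateList ordered candidate features: common knowledge first,
#'   then deduplicated target-ranked features.
#' @slot origin `"common"` or `"target_novel"` per candidate feature.
#' @slot aucTrace mean cross-validated AUC for each prefix length
#'   1..length(candidateList).
#' @slot aucTraceSD per-prefix standard deviation of fold AUCs.
#' @slot bestPrefixLength the AUC-maximising prefix (ties -> shortest).
#' @slot model the final [TrainedSVR-class] refitted on all target rows with
#'   the best prefix.
#' @export
setClass("TransferResult",
  representation(
    candidateList = "character", origin = "character",
    aucTrace = "numeric", aucTraceSD = "numeric",
    bestPrefixLength = "integer", model = "ANY"
  )
)

setValidity("TransferResult", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@candidateList))
    msgs <- c(msgs, "candidateList must not contain duplicates")
  if (length(object@origin) != length(object@candidateList))
    msgs <- c(msgs, "origin must annotate every candidate")
  if (length(object@aucTrace) != length(object@candidateList))
    msgs <- c(msgs, "aucTrace must cover every prefix length")
  if (length(object@bestPrefixLength) &&
      (object@bestPrefixLength < 1L ||
       object@bestPrefixLength > length(object@candidateList)))
    msgs <- c(msgs, "bestPrefixLength out of range")
  if (length(msgs)) msgs else TRUE
})

#' MetricsReport: confusion-matrix metrics plus ROC AUC
#'
#' Zero-denominator metrics are reported as `NA` (flagged, never silently 0).
#' `fScore` is the standard F1 = 2TP/(2TP+FP+FN); `fScoreAsPrinted` is the
#' 2TP/(2TP+FP+TN) variant that some reports print, kept for fidelity.
#'
#' @slot counts named numeric: TP, TN, FP, FN.
#' @slot sensitivity,specificity,accuracy,fScore,fScoreAsPrinted,mcc reals
#'   (NA when undefined).
#' @slot auc area under the ROC curve (NA when not computed).
#' @slot folds optional per-fold breakdown (data.frame).
#' @export
setClass("MetricsReport",
  representation(
    counts = "numeric",
    sensitivity = "numeric", specificity = "numeric", accuracy = "numeric",
    fScore = "numeric", fScoreAsPrinted = "numeric", mcc = "numeric",
    auc = "numeric", folds = "data.frame"
  ),
  prototype(auc = NA_real_, folds = data.frame())
)

#' EntropyProfile: per-position cleavage entropy of a protease
#'
#' Shannon entropy (bits, plug-in frequencies over the 20 standard residues)
#' of each P8..P8' position across a protease's positive windows. High
#' entropy means low positional specificity; `specificity` is the inverted
#' convention log2(20) - entropy.
#'
#' @slot protease protease name.
#' @slot entropy 16 per-position entropies (bits), names P8..P8'.
#' @slot average mean of the 16 entropies (the "Avg" column).
#' @slot specificity log2(20) - entropy, per position.
#' @slot nWindows number of positive windows profiled.
#' @export
setClass("EntropyProfile",
  representation(
    protease = "character", entropy = "numeric", average = "numeric",
    specificity = "numeric", nWindows = "integer"
  )
)

setValidity("EntropyProfile", function(object) {
  msgs <- character(0)
  if (length(object@entropy) != 16L)
    msgs <- c(msgs, "entropy must have 16 positions")
  if (any(object@entropy < -1e-9) || any(object@entropy > log2(20) + 1e-9))
    msgs <- c(msgs, "entropies must lie in [0, log2(20)]")
  if (length(msgs)) msgs else TRUE
})

#' MotifSpec: a position-specific residue preference
#'
#' Each listed window position carries a residue weight map that is
#' normalised to a distribution; sampling mixes this motif distribution with
#' the background at mixing coefficient `strength` (`0` = pure background).
#'
#' @slot positions named list: window position label (e.g. "P1", "P1p") ->
#'   named numeric residue weights.
#' @slot background named numeric distribution over the 20 standard residues.
#' @slot strength mixing coefficient in `[0, 1]`.
#' @export
setClass("MotifSpec",
  representation(positions = "list", background = "numeric",
                 strength = "numeric")
)

setValidity("MotifSpec", function(object) {
  msgs <- character(0)
  if (object@strength < 0 || object@strength > 1)
    msgs <- c(msgs, "strength must lie in [0, 1]")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-8)
    msgs <- c(msgs, "background must be a distribution over 20 residues")
  badpos <- setdiff(names(object@positions), WINDOW_POSITIONS)
  if (length(badpos))
    msgs <- c(msgs, paste0("unknown window positions: ",
                           paste(badpos, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' ScenarioSpec: a synthetic source/target study design
#'
#' Describes a family of protease domains sharing one cleavage motif, each
#' with a private position-specific signal, used to generate substrate sets
#' with planted cleavage sites.
#'
#' @slot nSourceDomains number of source domains (the scenario adds 1 target).
#' @slot nSubstrates substrates per domain (length `nSourceDomains + 1`).
#' @slot nSites total planted cleavage sites per domain (same length).
#' @slot lengthRange min/max substrate length.
#' @slot sharedMotif the [MotifSpec-class] common to all domains.
#' @slot privateMotifs per-domain private [MotifSpec-class] objects.
#' @slot seed integer master seed; generation is fully deterministic given it.
#' @export
setClass("ScenarioSpec",
  representation(
    nSourceDomains = "integer", nSubstrates = "integer", nSites = "integer",
    lengthRange = "integer", sharedMotif = "MotifSpec",
    privateMotifs = "list", seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msgs <- character(0)
  nd <- object@nSourceDomains + 1L
  if (length(object@nSubstrates) != nd || length(object@nSites) != nd)
    msgs <- c(msgs, "nSubstrates and nSites must cover every domain (+ target)")
  if (length(object@privateMotifs) != nd)
    msgs <- c(msgs, "privateMotifs must cover every domain (+ target)")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] < 18L ||
      object@lengthRange[1] > object@lengthRange[2])
    msgs <- c(msgs, "lengthRange must be c(min, max) with min >= 18")
  if (length(msgs)) msgs else TRUE
})
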