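# mRMR feature ranking: discretisation, mutual information, greedy MID.

#' Discretise a feature matrix for mutual-information estimation
#'
#' Binary 0/1 columns pass through unchanged. Every other column is binned
#' into three states at mean +/- sd: below `m - s` -> 0, within -> 1, above
#' `m + s` -> 2 (the discretisation conventionally used with mRMR on
#' continuous data). A constant column collapses to a single state.
#'
#' @param x numeric matrix (rows = samples) or [FeatureMatrix-class].
#' @return integer matrix of the same shape with values in 0..2.
#' @export
discretizeFeatures <- function(x) {
  if (is(x, "FeatureMatrix")) x <- featureData(x)
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (all(v %in% c(0, 1))) {
      out[, j] <- as.integer(v)
    } else {
      m <- mean(v); s <- stats::sd(v)
      out[, j] <- (v > m - s) + (v > m + s)
    }
  }
  out
}

#' Plug-in mutual information between two discrete vectors
#'
#' @param x,y discrete vectors of equal length (any atomic type).
#' @return mutual information in bits (non-negative up to rounding).
#' @export
mutualInformation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  xf <- match(x, unique(x))
  yf <- match(y, unique(y))
  nx <- max(xf); ny <- max(yf)
  joint <- tabulate((xf - 1L) * ny + yf, nx * ny) / length(x)
  J <- matrix(joint, nx, ny, byrow = TRUE)
  px <- rowSums(J); py <- colSums(J)
  terms <- J * (log2(J) - log2(outer(px, py)))
  sum(terms[J > 0])
}

# Indicator representation of a discretised matrix: list of three n x p
# numeric 0/1 matrices, one per state.
stateIndicators <- function(disc) {
  lapply(0:2, function(u) (disc == u) * 1)
}

# MI (bits) of every column of the indicator set against one discrete
# variable given as an n x k indicator matrix B. Vectorised over columns via
# crossprod.
miColumnsVs <- function(ind, B, n) {
  py <- colSums(B) / n
  mi <- numeric(ncol(ind[[1]]))
  for (u in 1:3) {
    C <- crossprod(ind[[u]], B) / n          # p x k joint probabilities
    px <- rowSums(C)
    denom <- outer(px, py)
    term <- C * (log2(C) - log2(denom))
    term[C == 0] <- 0
    mi <- mi + rowSums(term)
  }
  mi
}

indicatorOf <- function(v) {
  f <- match(v, sort(unique(v)))
  k <- max(f)
  m <- matrix(0, length(v), k)
  m[cbind(seq_along(v), f)] <- 1
  m
}

#' Greedy mRMR feature ranking (MID scheme)
#'
#' Ranks `m` features by minimum-redundancy maximum-relevance with the MID
#' (mutual-information difference) objective: the first pick maximises
#' relevance `I(f; y)`; each subsequent pick maximises
#' `I(f; y) - mean over selected s of I(f; s)`. Mutual information is the
#' plug-in estimate (bits) on the [discretizeFeatures()] states. Ties are
#' broken by column order; the procedure is fully deterministic and
#' invariant to row order.
#'
#' @param x [FeatureMatrix-class], or numeric matrix with named columns.
#' @param labels class labels (+1/-1); taken from `x` when it is a
#'   `FeatureMatrix`.
#' @param m number of features to rank (1 <= m <= ncol).
#' @return a [FeatureRanking-class].
#' @export
mrmrRank <- function(x, labels = NULL, m) {
  if (is(x, "FeatureMatrix")) {
    labels <- sampleLabels(x)
    x <- featureData(x)
  }
  if (length(m) != 1L || m < 1L) stop("'m' must be a positive integer")
  if (m > ncol(x)) stop("'m' exceeds the number of feature columns")
  if (!length(labels) || length(labels) != nrow(x))
    stop("labels must be supplied for every row")
  disc <- discretizeFeatures(x)
  ind <- stateIndicators(disc)
  n <- nrow(disc)
  relevance <- miColumnsVs(ind, indicatorOf(labels), n)
  p <- ncol(disc)
  selected <- integer(0)
  scores <- numeric(0)
  redundancySum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(m)) {
    objective <- if (step == 1L) relevance else
      relevance - redundancySum / length(selected)
    objective[!remaining] <- -Inf
    pick <- which.max(objective)
    selected <- c(selected, pick)
    scores <- c(scores, objective[pick])
    remaining[pick] <- FALSE
    if (step < m) {
      Bm <- cbind(ind[[1]][, pick], ind[[2]][, pick], ind[[3]][, pick])
      Bm <- Bm[, colSums(Bm) > 0, drop = FALSE]
      redundancySum <- redundancySum + miColumnsVs(ind, Bm, n)
    }
  }
  new("FeatureRanking",
      features = colnames(x)[selected],
      relevance = relevance[selected],
      score = scores)
}

#' Export a feature ranking to TSV
#'
#' Columns: rank, feature, relevance_bits, mrmr_score.
#'
#' @param ranking a [FeatureRanking-class].
#' @param path output file path.
#' @export
writeRanking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking@features),
                   feature = ranking@features,
                   relevance_bits = ranking@relevance,
                   mrmr_score = ranking@score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
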