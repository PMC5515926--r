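# Per-position cleavage-entropy profiling of P8-P8' windows.

#' Cleavage-entropy profile of a protease
#'
#' For each of the 16 window positions P8..P8', computes the Shannon entropy
#' (bits) of the residue distribution observed across the protease's
#' cleaved (positive) windows, using plug-in frequencies over the 20
#' standard residues; pad/non-standard characters are excluded per position.
#' Low entropy at a position means the protease is stringent there; the
#' profile also carries the inverted specificity score `log2(20) - entropy`
#' for heatmaps drawn in that convention. `average` is the mean over the 16
#' positions (the "Avg" column of a specificity heatmap).
#'
#' @param x positive windows: a character vector of 16-mers, a window
#'   data.frame, or a [DomainDataset-class] (its positive windows are used).
#' @param protease protease name for the profile.
#' @param normalized divide entropies by log2(20) so they lie in `[0, 1]`.
#' @return an [EntropyProfile-class].
#' @export
cleavageEntropy <- function(x, protease = "protease", normalized = FALSE) {
  if (is(x, "DomainDataset")) {
    if (protease == "protease") protease <- datasetName(x)
    w <- windows(x)
    x <- w$residues[w$label == "positive"]
  } else if (is.data.frame(x)) {
    x <- x$residues[x$label %in% c("positive", NA)]
  }
  if (!length(x)) stop("at least one positive window is required")
  stopifnot(all(nchar(x) == 16L))
  chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  ent <- vapply(seq_len(16L), function(i) {
    col <- chars[, i]
    col <- col[col %in% AA_STANDARD20]
    if (!length(col)) return(0)
    p <- tabulate(match(col, AA_STANDARD20), 20) / length(col)
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  if (normalized) ent <- ent / log2(20)
  maxEnt <- if (normalized) 1 else log2(20)
  names(ent) <- WINDOW_POSITIONS
  new("EntropyProfile", protease = protease, entropy = ent,
      average = mean(ent), specificity = maxEnt - ent,
      nWindows = length(x))
}

#' Export entropy profiles as heatmap data
#'
#' One row per protease: the 16 per-position entropies plus the Avg column,
#' tab-separated.
#'
#' @param profiles list of [EntropyProfile-class] objects.
#' @param path output TSV path.
#' @export
writeEntropyProfiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(protease = p@protease, t(p@entropy), Avg = p@average,
               check.names = FALSE))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Positional residue counts of positive windows
#'
#' The 20 x 16 count table underlying sequence logos and the entropy
#' profile, exported for external plotting.
#'
#' @inheritParams cleavageEntropy
#' @return integer matrix, rows = residues, columns = positions P8..P8'.
#' @export
positionalCounts <- function(x) {
  if (is(x, "DomainDataset")) {
    w <- windows(x)
    x <- w$residues[w$label == "positive"]
  }
  chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  counts <- vapply(seq_len(16L), function(i) {
    tabulate(match(chars[, i], AA_STANDARD20), 20)
  }, integer(20))
  dimnames(counts) <- list(AA_STANDARD20, WINDOW_POSITIONS)
  counts
}
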