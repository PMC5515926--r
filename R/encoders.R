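# Feature encoders for 16-residue cleavage windows.
#
# Each encoder is a pure function of (window, resources) returning a named
# numeric vector whose names are scheme-qualified (e.g. "Binary.P1.G"),
# with dimensionalities: AAindex 1024, AAPair 20, Binary 336, BLOSUM 336,
# CHARGE_Hyd 9, CKSAAP 2400, DISOPRED 16, PSSM 320; total 4461.

ENCODER_SCHEMES <- c("AAindex", "AAPair", "Binary", "BLOSUM", "CHARGE_Hyd",
                     "CKSAAP", "DISOPRED", "PSSM")

.pkgCache <- new.env(parent = emptyenv())

checkWindow <- function(window) {
  if (!is.character(window) || length(window) != 1L || nchar(window) != 16L)
    stop("'window' must be a single 16-residue string")
  splitResidues(window)
}

#' Default AAindex physicochemical table
#'
#' A 64 x 20 table of amino-acid physicochemical indices used by the AAindex
#' encoder: the first 64 indices of the AAindex database (as shipped with
#' the \pkg{seqinr} package), in accession order, that are complete for all
#' 20 standard residues. Any user table of the same shape (rows = indices,
#' columns = residues in alphabetical one-letter order) may be supplied
#' instead, e.g. via [readAAindexTable()].
#'
#' @return numeric matrix, rownames = AAindex accessions, colnames = the 20
#'   standard residues.
#' @export
defaultAAindexTable <- function() {
  if (!is.null(.pkgCache$aaindexTable)) return(.pkgCache$aaindexTable)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  three <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
             G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
             M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
             S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  acc <- vapply(aaindex, function(e) e$H, character(1))
  rows <- lapply(aaindex, function(e) unname(e$I[three[AA_STANDARD20]]))
  complete <- vapply(rows, function(v) !anyNA(v) && length(v) == 20L,
                     logical(1))
  ord <- order(acc)
  keep <- ord[complete[ord]][seq_len(64)]
  tab <- do.call(rbind, rows[keep])
  dimnames(tab) <- list(acc[keep], AA_STANDARD20)
  .pkgCache$aaindexTable <- tab
  tab
}

#' Read a user AAindex table
#'
#' Tab-separated file: one row per index, first column the index id, then 20
#' columns named by the standard residues (alphabetical one-letter order).
#'
#' @param path TSV path.
#' @return numeric matrix as in [defaultAAindexTable()].
#' @export
readAAindexTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  if (!all(AA_STANDARD20 %in% colnames(df)))
    stop("AAindex table must have one column per standard residue")
  as.matrix(df[, AA_STANDARD20, drop = FALSE])
}

blosum62Matrix <- function() {
  if (is.null(.pkgCache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .pkgCache$blosum62 <- env$BLOSUM62
  }
  .pkgCache$blosum62
}

#' Binary one-hot encoding (336 features)
#'
#' Each residue becomes a 21-slot indicator: the 20 standard residues in
#' alphabetical order plus one slot for non-standard residues, so 'X' (and
#' terminal padding) carries all zeros in the standard slots and a 1 in slot
#' 21.
#'
#' @param window 16-residue string.
#' @return named numeric vector of length 16 x 21 = 336.
#' @export
encodeBinary <- function(window) {
  res <- checkWindow(window)
  slots <- c(AA_STANDARD20, "nonstd")
  out <- numeric(16L * 21L)
  names(out) <- paste("Binary", rep(WINDOW_POSITIONS, each = 21L),
                      rep(slots, 16L), sep = ".")
  hit <- match(res, AA_STANDARD20)
  hit[is.na(hit)] <- 21L
  out[(seq_len(16L) - 1L) * 21L + hit] <- 1
  out
}

#' AAindex physicochemical encoding (1024 features)
#'
#' Each residue contributes its 64 physicochemical index values; 'X' and
#' padding are imputed with the per-index mean over the 20 standard residues.
#' A table with a different number of indices yields a 16 x n block and a
#' warning (non-canonical dimension).
#'
#' @param window 16-residue string.
#' @param indexTable indices x 20 matrix (default [defaultAAindexTable()]).
#' @return named numeric vector of length 16 x nrow(indexTable).
#' @export
encodeAAindex <- function(window, indexTable = defaultAAindexTable()) {
  res <- checkWindow(window)
  if (nrow(indexTable) != 64L)
    warning("AAindex table has ", nrow(indexTable),
            " indices; non-canonical dimension ", 16L * nrow(indexTable))
  means <- rowMeans(indexTable)
  cols <- vapply(res, function(r) {
    if (r %in% colnames(indexTable)) indexTable[, r] else means
  }, numeric(nrow(indexTable)))
  out <- as.vector(cols)
  names(out) <- paste("AAindex", rep(WINDOW_POSITIONS, each = nrow(indexTable)),
                      rep(rownames(indexTable), 16L), sep = ".")
  out
}

#' Amino-acid composition encoding (20 features)
#'
#' Frequency of each standard residue within the window; non-standard
#' residues and padding are excluded from both numerator and denominator, so
#' the frequencies sum to 1 whenever any standard residue is present.
#'
#' @param window 16-residue string.
#' @return named numeric vector of length 20.
#' @export
encodeAAPair <- function(window) {
  res <- checkWindow(window)
  std <- res[res %in% AA_STANDARD20]
  out <- setNames(numeric(20), paste("AAPair", AA_STANDARD20, sep = "."))
  if (length(std))
    out[paste("AAPair", AA_STANDARD20, sep = ".")] <-
      tabulate(match(std, AA_STANDARD20), 20) / length(std)
  out
}

#' BLOSUM62 encoding (336 features)
#'
#' Each residue contributes its BLOSUM62 substitution row over the 20
#' standard residues plus the matrix's 'X' (non-standard) column; 'X' and
#' padding use the matrix's own 'X' row.
#'
#' @param window 16-residue string.
#' @return named numeric vector of length 16 x 21 = 336.
#' @export
encodeBLOSUM <- function(window) {
  res <- checkWindow(window)
  bl <- blosum62Matrix()
  cols <- c(AA_STANDARD20, "X")
  rows <- ifelse(res %in% AA_STANDARD20, res, "X")
  out <- as.vector(t(bl[rows, cols, drop = FALSE]))
  names(out) <- paste("BLOSUM", rep(WINDOW_POSITIONS, each = 21L),
                      rep(cols, 16L), sep = ".")
  out
}

#' Charge / hydrophobicity summary encoding (9 features)
#'
#' Three properties -- mean net charge, aromatic content (fraction of
#' F/W/Y/H), and the charge:hydrophobicity ratio
#' `|mean charge| / (mean Kyte-Doolittle + offset)` -- each evaluated over
#' three segments: the full window, the N-half (P8-P1) and the C-half
#' (P1'-P8'). Padding is excluded from every mean; an all-pad segment scores
#' 0.
#'
#' @param window 16-residue string.
#' @param chargeScale,hydScale named per-residue scales (defaults: K/R +1,
#'   D/E -1, H +0.1; Kyte-Doolittle hydropathy).
#' @param aromaticResidues residues counted as aromatic.
#' @param hydOffset shift added to the mean hydropathy so the ratio
#'   denominator stays positive (default 5.0 > |min Kyte-Doolittle|).
#' @return named numeric vector of length 3 x 3 = 9.
#' @export
encodeChargeHyd <- function(window, chargeScale = RESIDUE_CHARGE,
                            hydScale = KYTE_DOOLITTLE,
                            aromaticResidues = AROMATIC_RESIDUES,
                            hydOffset = 5.0) {
  res <- checkWindow(window)
  segs <- list(full = res, Nhalf = res[1:8], Chalf = res[9:16])
  vals <- lapply(segs, function(s) {
    s <- s[s %in% AA_STANDARD20]
    if (!length(s)) return(c(netCharge = 0, aromatic = 0, chargeHydRatio = 0))
    ch <- mean(chargeScale[s])
    ar <- mean(s %in% aromaticResidues)
    hy <- mean(hydScale[s])
    c(netCharge = ch, aromatic = ar, chargeHydRatio = abs(ch) / (hy + hydOffset))
  })
  out <- c(vapply(vals, `[[`, numeric(1), "netCharge"),
           vapply(vals, `[[`, numeric(1), "aromatic"),
           vapply(vals, `[[`, numeric(1), "chargeHydRatio"))
  names(out) <- paste("CHARGE_Hyd",
                      rep(c("netCharge", "aromatic", "chargeHydRatio"),
                          each = 3L),
                      rep(c("full", "Nhalf", "Chalf"), 3L), sep = ".")
  out
}

#' Composition of k-spaced amino-acid pairs (2400 features)
#'
#' For each spacing `k`, the frequency of every ordered residue pair
#' `(i, i + k + 1)` among the 400 standard pairs, normalised by the number
#' of countable pairs `N_Total`. For a full 16-mer `N_Total` is
#' `16 - k - 1` (15, 14, 13, 12, 11, 10 at k = 0..5); pairs touching a pad
#' or non-standard residue are excluded and `N_Total` reduced accordingly.
#'
#' @param window 16-residue string.
#' @param kValues spacings to include, a subset of 0..5 (default all six).
#' @return named numeric vector of length 400 x length(kValues).
#' @export
encodeCKSAAP <- function(window, kValues = 0:5) {
  res <- checkWindow(window)
  stopifnot(all(kValues %in% 0:5))
  pairNames <- paste0(rep(AA_STANDARD20, each = 20L), rep(AA_STANDARD20, 20L))
  std <- match(res, AA_STANDARD20)      # NA for pads / non-standard
  blocks <- lapply(kValues, function(k) {
    i <- seq_len(16L - k - 1L)
    j <- i + k + 1L
    ok <- !is.na(std[i]) & !is.na(std[j])
    counts <- numeric(400)
    if (any(ok))
      counts <- tabulate((std[i][ok] - 1L) * 20L + std[j][ok], 400)
    nTotal <- sum(ok)
    v <- if (nTotal > 0) counts / nTotal else counts
    names(v) <- paste0("CKSAAP.k", k, ".", pairNames)
    v
  })
  unlist(blocks)
}

#' Disorder-probability encoding (16 features)
#'
#' The per-residue predicted disorder probabilities aligned to the window.
#' Missing values (no profile, or pad positions outside the substrate) are
#' filled with the uninformative 0.5.
#'
#' @param window 16-residue string.
#' @param disorderProfile numeric vector of 16 probabilities aligned to the
#'   window (NAs allowed), or `NULL` when no profile exists.
#' @return named numeric vector of length 16.
#' @export
encodeDisorder <- function(window, disorderProfile = NULL) {
  checkWindow(window)
  v <- if (is.null(disorderProfile)) rep(0.5, 16L) else {
    stopifnot(length(disorderProfile) == 16L)
    ifelse(is.na(disorderProfile), 0.5, disorderProfile)
  }
  setNames(v, paste("DISOPRED", WINDOW_POSITIONS, sep = "."))
}

#' PSSM evolutionary encoding (320 features)
#'
#' Each window residue contributes its 20 PSI-BLAST log-odds scores squashed
#' to (0, 1) by the logistic function `1 / (1 + exp(-x))`; pad positions and
#' missing profiles are filled with 0.5 (the logistic image of score 0).
#'
#' @param window 16-residue string.
#' @param pssmProfile 16 x 20 matrix of raw scores aligned to the window
#'   (NA rows allowed), or `NULL`.
#' @return named numeric vector of length 16 x 20 = 320.
#' @export
encodePSSM <- function(window, pssmProfile = NULL) {
  checkWindow(window)
  m <- if (is.null(pssmProfile)) matrix(NA_real_, 16L, 20L) else {
    stopifnot(nrow(pssmProfile) == 16L, ncol(pssmProfile) == 20L)
    pssmProfile
  }
  sq <- 1 / (1 + exp(-m))
  sq[is.na(sq)] <- 0.5
  out <- as.vector(t(sq))
  names(out) <- paste("PSSM", rep(WINDOW_POSITIONS, each = 20L),
                      rep(AA_STANDARD20, 16L), sep = ".")
  out
}

#' Encode one window with all (or a subset of) schemes
#'
#' Concatenates the requested encoders in the fixed canonical order AAindex,
#' AAPair, Binary, BLOSUM, CHARGE_Hyd, CKSAAP, DISOPRED, PSSM. With all
#' eight schemes and the default resources the result has exactly
#' 1024 + 20 + 336 + 336 + 9 + 2400 + 16 + 320 = 4461 uniquely named
#' features.
#'
#' @param window 16-residue string.
#' @param schemes character subset of the eight scheme names.
#' @param aaindexTable table for the AAindex encoder.
#' @param disorderProfile,pssmProfile optional aligned profiles (see
#'   [encodeDisorder()], [encodePSSM()]).
#' @return named numeric vector.
#' @export
encodeWindow <- function(window, schemes = ENCODER_SCHEMES,
                         aaindexTable = defaultAAindexTable(),
                         disorderProfile = NULL, pssmProfile = NULL) {
  schemes <- match.arg(schemes, ENCODER_SCHEMES, several.ok = TRUE)
  schemes <- ENCODER_SCHEMES[ENCODER_SCHEMES %in% schemes]
  parts <- lapply(schemes, function(s) switch(s,
    AAindex    = encodeAAindex(window, aaindexTable),
    AAPair     = encodeAAPair(window),
    Binary     = encodeBinary(window),
    BLOSUM     = encodeBLOSUM(window),
    CHARGE_Hyd = encodeChargeHyd(window),
    CKSAAP     = encodeCKSAAP(window),
    DISOPRED   = encodeDisorder(window, disorderProfile),
    PSSM       = encodePSSM(window, pssmProfile)))
  unlist(parts)
}

# Slice a substrate's per-residue profile to the 16 window positions of a
# window at P1 position p (NA outside the substrate).
windowProfileSlice <- function(values, p1, n) {
  idx <- (p1 - 7L):(p1 + 8L)
  ok <- idx >= 1L & idx <= n
  out <- rep(NA_real_, 16L)
  out[ok] <- values[idx[ok]]
  out
}

#' Encode a domain dataset into a FeatureMatrix
#'
#' Applies [encodeWindow()] to every window of a [DomainDataset-class] (or a
#' window data.frame) and stacks the rows. Disorder and PSSM profiles are
#' sliced from the parent [Substrate-class] objects when `substrates` is
#' supplied; otherwise those encoders use their documented fallback fills.
#'
#' @param dataset a `DomainDataset` or a window data.frame.
#' @param substrates optional list of `Substrate` objects (profiles source).
#' @param schemes encoder subset (default: all eight).
#' @param aaindexTable table for the AAindex encoder.
#' @return a [FeatureMatrix-class]; labels are +1/-1 mapped from the window
#'   labels.
#' @export
encodeWindows <- function(dataset, substrates = NULL,
                          schemes = ENCODER_SCHEMES,
                          aaindexTable = defaultAAindexTable()) {
  win <- if (is(dataset, "DomainDataset")) windows(dataset) else dataset
  if (!nrow(win)) stop("no windows to encode")
  subMap <- if (!is.null(substrates))
    setNames(substrates, vapply(substrates, function(s) s@id, character(1)))
  rows <- lapply(seq_len(nrow(win)), function(i) {
    dis <- pss <- NULL
    if (!is.null(subMap) && win$substrateId[i] %in% names(subMap)) {
      s <- subMap[[win$substrateId[i]]]
      n <- nchar(s@sequence)
      if (length(s@disorder))
        dis <- windowProfileSlice(s@disorder, win$p1Position[i], n)
      if (nrow(s@pssm)) {
        idx <- (win$p1Position[i] - 7L):(win$p1Position[i] + 8L)
        pss <- matrix(NA_real_, 16L, 20L)
        ok <- idx >= 1L & idx <= n
        pss[ok, ] <- s@pssm[idx[ok], , drop = FALSE]
      }
    }
    encodeWindow(win$residues[i], schemes = schemes,
                 aaindexTable = aaindexTable,
                 disorderProfile = dis, pssmProfile = pss)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- windowIds(win)
  labels <- if ("label" %in% names(win))
    ifelse(win$label == "positive", 1, -1) else numeric(0)
  new("FeatureMatrix", data = mat, labels = as.numeric(labels))
}
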