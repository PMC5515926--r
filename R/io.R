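# Substrate input, redundancy reduction, window extraction and negative
# sampling.

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an explicit integer 'seed' is required")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read substrates with cleavage annotations and optional profiles
#'
#' Reads substrate sequences from a FASTA file and 1-based P1 cleavage
#' positions from a tab-separated annotation file with header columns
#' `substrate_id` and `p1_position`. When `profileDir` is given, per-substrate
#' profile files are attached if present: `<id>.acc` (NetSurfP-style solvent
#' accessibility; the first whitespace-delimited field of each data line is
#' the class, 'b' buried / 'e' exposed), `<id>.diso` (DISOPRED-style
#' disorder; fields: residue number, residue, '*'/'.' state, probability) and
#' `<id>.pssm` (PSI-BLAST ASCII matrix; the first 20 score columns, reordered
#' to alphabetical residue order).
#'
#' @param fastaPath path to the substrate FASTA file.
#' @param annotationPath path to the annotation TSV.
#' @param profileDir optional directory of profile files.
#' @return a list of [Substrate-class] objects, in FASTA order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sub1", "GPLGLWAQGPLGLWAQ"), fa)
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("substrate_id\tp1_position", "sub1\t8"), tsv)
#' subs <- readSubstrates(fa, tsv)
#' cleavageSites(subs[[1]])
#' @export
readSubstrates <- function(fastaPath, annotationPath, profileDir = NULL) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotationPath, header = TRUE,
                           colClasses = c("character", "integer"))
  if (!all(c("substrate_id", "p1_position") %in% names(ann)))
    stop("annotation file must have columns 'substrate_id' and 'p1_position'")
  unknown <- setdiff(ann$substrate_id, ids)
  if (length(unknown))
    stop("annotation references unknown substrate id(s): ",
         paste(unknown, collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    id <- ids[i]
    seq <- as.character(seqs[[i]])
    pos <- sort(unique(ann$p1_position[ann$substrate_id == id]))
    bad <- pos[pos < 1L | pos >= nchar(seq)]
    if (length(bad))
      stop(sprintf("substrate '%s': P1 position(s) %s out of range [1, %d)",
                   id, paste(bad, collapse = ", "), nchar(seq)))
    sub <- new("Substrate", id = id, sequence = seq,
               cleavagePositions = as.integer(pos))
    if (!is.null(profileDir)) sub <- attachProfiles(sub, profileDir)
    sub
  })
}

attachProfiles <- function(substrate, profileDir) {
  id <- substrate@id
  acc <- file.path(profileDir, paste0(id, ".acc"))
  if (file.exists(acc))
    substrate@accessibility <- readAccessibilityProfile(acc)
  diso <- file.path(profileDir, paste0(id, ".diso"))
  if (file.exists(diso))
    substrate@disorder <- readDisorderProfile(diso)
  pssm <- file.path(profileDir, paste0(id, ".pssm"))
  if (file.exists(pssm))
    substrate@pssm <- readPSSMProfile(pssm)
  validObject(substrate)
  substrate
}

readAccessibilityProfile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cls <- vapply(strsplit(trimws(lines), "\\s+"), `[`, character(1), 1L)
  tolower(cls)
}

readDisorderProfile <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*[0-9]+\\s", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  as.numeric(vapply(fields, `[`, character(1), 4L))
}

readPSSMProfile <- function(path) {
  lines <- readLines(path)
  header <- grep("^\\s*A\\s+R\\s+N|(\\s[A-Z]){20}", lines, value = TRUE)[1]
  order20 <- if (!is.na(header)) {
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    toks[seq_len(20)]
  } else AA_STANDARD20
  rows <- lines[grepl("^\\s*[0-9]+\\s+[A-Zx]\\s", lines)]
  scores <- t(vapply(strsplit(trimws(rows), "\\s+"), function(f)
    as.numeric(f[3:22]), numeric(20)))
  colnames(scores) <- order20
  scores[, AA_STANDARD20, drop = FALSE]
}

#' Reduce substrate redundancy by greedy identity clustering
#'
#' Clusters substrates whose global pairwise sequence identity meets
#' `identityThreshold` and keeps one representative per cluster. Clustering
#' is greedy longest-first: sequences are visited in decreasing length and
#' join the first existing cluster whose representative they match, otherwise
#' found a new cluster. Identity is matches / alignment length of a global
#' alignment scored match = 1, mismatch = 0, gap = -1.
#'
#' Alternatively a CD-HIT `.clstr` file may be supplied, in which case its
#' representatives (the `*`-marked members) are honoured verbatim.
#'
#' @param substrates list of [Substrate-class] objects.
#' @param identityThreshold identity in (0, 1] above which sequences cluster
#'   together (default 0.70).
#' @param clusterFile optional CD-HIT `.clstr` file path.
#' @return the representative substrates, in input order.
#' @export
reduceRedundancy <- function(substrates, identityThreshold = 0.70,
                             clusterFile = NULL) {
  if (!length(substrates)) return(substrates)
  if (!is.null(clusterFile)) {
    reps <- readClstrRepresentatives(clusterFile)
    keep <- vapply(substrates, function(s) s@id %in% reps, logical(1))
    return(substrates[keep])
  }
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  lens <- vapply(substrates, function(s) nchar(s@sequence), integer(1))
  visit <- order(-lens)       # longest first, ties keep input order
  repIdx <- integer(0)
  for (i in visit) {
    matched <- FALSE
    for (r in repIdx) {
      if (pairwiseIdentity(substrates[[i]]@sequence,
                           substrates[[r]]@sequence) >= identityThreshold) {
        matched <- TRUE
        break
      }
    }
    if (!matched) repIdx <- c(repIdx, i)
  }
  substrates[sort(repIdx)]
}

# Global identity = matches / alignment length (PID1), alignment scored
# match 1 / mismatch 0 / gap -1.
pairwiseIdentity <- function(a, b) {
  letters <- c(AA_STANDARD20, "X")
  mat <- matrix(0, 21, 21, dimnames = list(letters, letters))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

readClstrRepresentatives <- function(path) {
  lines <- readLines(path)
  repLines <- lines[grepl("\\*\\s*$", lines)]
  sub(".*>([^.]+?)\\.{3}.*", "\\1", repLines)
}

#' Extract P8-P8' cleavage windows from a substrate
#'
#' Slides a window of `windowLength` residues over every peptide bond of the
#' substrate: the window at P1 position `p` covers residues
#' `p - windowLength/2 + 1` .. `p + windowLength/2`, so the scissile bond
#' sits exactly between the two central residues. Positions overrunning a
#' terminus are padded with `'X'`. A window is labelled `"positive"` when its
#' P1 position is annotated as a cleavage site, otherwise it is a negative
#' candidate.
#'
#' @param substrate a [Substrate-class].
#' @param windowLength even window size (default 16, i.e. P8-P8').
#' @return data.frame with columns `substrateId`, `p1Position`, `residues`,
#'   `label` and `p1Buried` (logical, `NA` without an accessibility profile).
#' @export
extractWindows <- function(substrate, windowLength = 16L) {
  stopifnot(windowLength %% 2 == 0)
  seq <- substrate@sequence
  n <- nchar(seq)
  if (n < 2L)
    return(data.frame(substrateId = character(0), p1Position = integer(0),
                      residues = character(0), label = character(0),
                      p1Buried = logical(0)))
  half <- windowLength %/% 2L
  res <- splitResidues(seq)
  p1 <- seq_len(n - 1L)
  windows <- vapply(p1, function(p) {
    idx <- (p - half + 1L):(p + half)
    chars <- ifelse(idx >= 1L & idx <= n, res[pmax(pmin(idx, n), 1L)], "X")
    paste(chars, collapse = "")
  }, character(1))
  lab <- ifelse(p1 %in% substrate@cleavagePositions, "positive", "negative")
  buried <- if (length(substrate@accessibility))
    substrate@accessibility[p1] == "b" else rep(NA, length(p1))
  data.frame(substrateId = substrate@id, p1Position = p1,
             residues = windows, label = lab, p1Buried = buried,
             stringsAsFactors = FALSE)
}

#' Sample negatives at a fixed negatives:positives ratio
#'
#' Keeps every positive window and draws `ratio` times as many negatives
#' from the negative candidates, without replacement. Candidates whose P1
#' residue is predicted buried ('b') are preferentially selected — buried
#' positions are unlikely to be genuine cleavage sites, making them reliable
#' negatives — with sampling weight `buriedWeight` against `exposedWeight`
#' for exposed/unknown P1 residues. Without accessibility information the
#' draw is uniform. When fewer candidates exist than requested, all are kept
#' and the dataset is flagged.
#'
#' @param windows data.frame of windows as returned by [extractWindows()]
#'   (rows from several substrates may be concatenated).
#' @param ratio negatives per positive (default 3).
#' @param seed explicit integer seed; the draw is deterministic given it.
#' @param buriedWeight,exposedWeight relative sampling weights (default 3:1).
#' @param name,role dataset name and domain role for the result.
#' @return a [DomainDataset-class].
#' @export
sampleNegatives <- function(windows, ratio = 3, seed, buriedWeight = 3,
                            exposedWeight = 1, name = "dataset",
                            role = c("target", "source")) {
  role <- match.arg(role)
  pos <- windows[windows$label == "positive", , drop = FALSE]
  neg <- windows[windows$label == "negative", , drop = FALSE]
  nWanted <- as.integer(round(ratio * nrow(pos)))
  shortage <- nrow(neg) < nWanted
  if (shortage) {
    chosen <- neg
  } else {
    w <- ifelse(!is.na(neg$p1Buried) & neg$p1Buried, buriedWeight,
                exposedWeight)
    idx <- withSeed(seed, sample.int(nrow(neg), nWanted, prob = w))
    chosen <- neg[sort(idx), , drop = FALSE]
  }
  win <- rbind(pos, chosen)
  win <- win[, c("substrateId", "p1Position", "residues", "label")]
  rownames(win) <- NULL
  new("DomainDataset", name = name, role = role, windows = win,
      negativeShortage = shortage)
}
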