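# Seeded synthetic substrate generator: source/target protease domains that
# share a position-specific cleavage motif and carry private, domain-specific
# signal, standing in for curated substrate databases in tests.

#' Construct a position-specific motif
#'
#' @param positions named list mapping window position labels (P8..P1,
#'   P1p..P8p) to named residue weight vectors; weights are normalised to a
#'   distribution per position.
#' @param background residue distribution (default: uniform over the 20
#'   standard residues; natural frequencies may be supplied instead).
#' @param strength mixing coefficient in `[0, 1]`: at a motif position a
#'   residue is drawn from the motif distribution with probability
#'   `strength` and from the background otherwise. 0 = pure background.
#' @return a [MotifSpec-class].
#' @export
motifSpec <- function(positions = list(),
                      background = setNames(rep(1 / 20, 20), AA_STANDARD20),
                      strength = 0.6) {
  positions <- lapply(positions, function(w) w / sum(w))
  background <- background[AA_STANDARD20] / sum(background)
  new("MotifSpec", positions = positions, background = background,
      strength = strength)
}

#' Default MMP-like study design
#'
#' Five source domains plus one target sharing the canonical MMP cleavage
#' preferences: glycine favoured at P7, P4, P1, P3' and P6', proline at P3
#' and P5', leucine at P1'. Each domain additionally carries two private
#' preferred positions (disjoint from the shared set, distinct across
#' domains). Dataset sizes follow the scale of curated MMP substrate sets:
#' 23-44 substrates and 85-290 cleavage sites per domain.
#'
#' @param strength shared/private motif strength (default 0.6).
#' @param seed master seed (default 1).
#' @return a [ScenarioSpec-class].
#' @export
defaultMMPLikeSpec <- function(strength = 0.6, seed = 1L) {
  shared <- motifSpec(
    positions = c(
      setNames(rep(list(c(G = 1)), 5), c("P7", "P4", "P1", "P3p", "P6p")),
      setNames(rep(list(c(P = 1)), 2), c("P3", "P5p")),
      list(P1p = c(L = 1))),
    strength = strength)
  freePos <- setdiff(WINDOW_POSITIONS, names(shared@positions))  # 8 left
  privateResidues <- c("R", "E", "S", "T", "V", "I")
  private <- lapply(seq_len(6), function(d) {
    pos <- freePos[((2 * (d - 1)) %% 8) + 1:2]
    motifSpec(positions = setNames(rep(list(setNames(1, privateResidues[d])),
                                       2), pos),
              strength = strength)
  })
  new("ScenarioSpec",
      nSourceDomains = 5L,
      nSubstrates = c(23L, 35L, 44L, 42L, 43L, 23L),
      nSites = c(85L, 115L, 132L, 142L, 290L, 178L),
      lengthRange = c(160L, 400L),
      sharedMotif = shared,
      privateMotifs = private,
      seed = as.integer(seed))
}

# Draw one residue per window position from strength * motif +
# (1 - strength) * background.
drawWindowResidues <- function(positions, background, strength) {
  vapply(WINDOW_POSITIONS, function(p) {
    if (!is.null(positions[[p]]) && stats::runif(1) < strength) {
      d <- positions[[p]]
      sample(names(d), 1, prob = d)
    } else {
      sample(AA_STANDARD20, 1, prob = background)
    }
  }, character(1))
}

#' Generate a synthetic source/target scenario
#'
#' Draws background substrate sequences per domain, plants non-overlapping
#' cleavage sites whose P8-P8' windows are overwritten with draws from the
#' domain's motif mixture (shared motif plus the domain's private motif),
#' extracts windows and samples negatives at the given ratio. Fully
#' deterministic given `spec@seed`.
#'
#' @param spec a [ScenarioSpec-class], e.g. [defaultMMPLikeSpec()].
#' @param ratio negatives per positive passed to [sampleNegatives()].
#' @return list with elements `substrates` (named list of per-domain
#'   substrate lists), `datasets` (named list of [DomainDataset-class];
#'   sources first, target last, named "target"), and `truth` (planted
#'   shared/private motif positions and residues, plus planted sites).
#' @export
generateScenario <- function(spec, ratio = 3) {
  validObject(spec)
  nDomains <- spec@nSourceDomains + 1L
  domainNames <- c(paste0("source", seq_len(spec@nSourceDomains)), "target")
  shared <- spec@sharedMotif
  substrates <- list()
  datasets <- list()
  planted <- list()
  for (d in seq_len(nDomains)) {
    nSub <- spec@nSubstrates[d]
    nSites <- spec@nSites[d]
    priv <- spec@privateMotifs[[d]]
    positions <- c(shared@positions, priv@positions)
    perSub <- rep(nSites %/% nSub, nSub)
    extra <- nSites %% nSub
    if (extra > 0) perSub[seq_len(extra)] <- perSub[seq_len(extra)] + 1L
    subs <- withSeed(childSeed(spec@seed, d), {
      lapply(seq_len(nSub), function(i) {
        len <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1)
        res <- sample(AA_STANDARD20, len, replace = TRUE,
                      prob = shared@background)
        allowed <- 8:(len - 8L)
        capacity <- (max(allowed) - min(allowed)) %/% 16L + 1L
        if (perSub[i] > capacity)
          stop("sites per substrate exceed sequence capacity")
        cand <- sample(allowed)
        sites <- integer(0)
        for (p in cand) {
          if (all(abs(p - sites) >= 16L)) sites <- c(sites, p)
          if (length(sites) == perSub[i]) break
        }
        if (length(sites) < perSub[i])  # random packing failed: space evenly
          sites <- as.integer(round(seq(min(allowed), max(allowed),
                                        length.out = perSub[i])))
        for (p in sort(sites)) {
          res[(p - 7L):(p + 8L)] <-
            drawWindowResidues(positions, shared@background, shared@strength)
        }
        new("Substrate",
            id = sprintf("%s_sub%02d", domainNames[d], i),
            sequence = paste(res, collapse = ""),
            cleavagePositions = sort(sites))
      })
    })
    win <- do.call(rbind, lapply(subs, extractWindows))
    datasets[[domainNames[d]]] <- sampleNegatives(
      win, ratio = ratio, seed = childSeed(spec@seed, 1000L + d),
      name = domainNames[d],
      role = if (d == nDomains) "target" else "source")
    substrates[[domainNames[d]]] <- subs
    planted[[domainNames[d]]] <- lapply(subs, function(s)
      list(id = s@id, sites = s@cleavagePositions))
  }
  sharedTruth <- vapply(shared@positions, function(w)
    names(w)[which.max(w)], character(1))
  privateTruth <- lapply(seq_len(nDomains), function(d)
    vapply(spec@privateMotifs[[d]]@positions, function(w)
      names(w)[which.max(w)], character(1)))
  names(privateTruth) <- domainNames
  list(substrates = substrates, datasets = datasets,
       truth = list(sharedPositions = sharedTruth,
                    privatePositions = privateTruth,
                    strength = shared@strength,
                    plantedSites = planted))
}

#' Write a scenario to FASTA + annotation files
#'
#' One `<domain>.fasta` and `<domain>.tsv` (columns `substrate_id`,
#' `p1_position`) per domain, readable by [readSubstrates()] unchanged,
#' plus `truth.json`.
#'
#' @param scenario result of [generateScenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (dom in names(scenario$substrates)) {
    subs <- scenario$substrates[[dom]]
    seqs <- Biostrings::AAStringSet(
      setNames(vapply(subs, function(s) s@sequence, character(1)),
               vapply(subs, function(s) s@id, character(1))))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(dom, ".fasta")))
    ann <- do.call(rbind, lapply(subs, function(s)
      if (length(s@cleavagePositions))
        data.frame(substrate_id = s@id, p1_position = s@cleavagePositions)))
    if (is.null(ann))
      ann <- data.frame(substrate_id = character(0),
                        p1_position = integer(0))
    utils::write.table(ann, file.path(dir, paste0(dom, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
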