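smallSpec <- function(strength, seed, nSub = c(8L, 8L), nSites = c(60L, 60L)) {
  base <- defaultMMPLikeSpec(strength = strength, seed = seed)
  sp <- new("ScenarioSpec", nSourceDomains = 1L,
            nSubstrates = nSub, nSites = nSites,
            lengthRange = c(200L, 400L),
            sharedMotif = base@sharedMotif,
            privateMotifs = base@privateMotifs[c(1, 6)],
            seed = as.integer(seed))
  sp
}

test_that("zero strength plants no positional signal", {
  sc <- generateScenario(smallSpec(0, seed = 7, nSub = c(100L, 100L),
                                   nSites = c(1000L, 1000L)))
  w <- windows(sc$datasets$target)
  counts <- positionalCounts(w$residues[w$label == "positive"])
  # chi-square against the uniform background at the planted P1 position
  p1 <- counts[, "P1"]
  expect_gt(stats::chisq.test(p1)$p.value, 0.001)
})

test_that("planted frequencies match the mixture expectation", {
  sc <- generateScenario(smallSpec(0.6, seed = 7, nSub = c(8L, 50L),
                                   nSites = c(60L, 500L)))
  w <- windows(sc$datasets$target)
  pos <- w$residues[w$label == "positive"]
  expect_equal(length(pos), 500)
  counts <- positionalCounts(pos)
  expected <- 0.6 + 0.4 / 20          # strength*1 + (1-strength)*uniform
  expect_lt(abs(counts["G", "P1"] / 500 - expected), 0.05)
  expect_lt(abs(counts["L", "P1p"] / 500 - expected), 0.05)
  expect_lt(abs(counts["P", "P3"] / 500 - expected), 0.05)
  # non-motif position stays near background
  expect_lt(abs(counts["G", "P2"] / 500 - 1 / 20), 0.05)
})

test_that("generation is deterministic: same spec + seed, same FASTA", {
  d1 <- tempfile(); d2 <- tempfile()
  writeScenario(generateScenario(smallSpec(0.6, seed = 3)), d1)
  writeScenario(generateScenario(smallSpec(0.6, seed = 3)), d2)
  f1 <- file.path(d1, "target.fasta")
  expect_identical(readLines(f1), readLines(file.path(d2, "target.fasta")))
  d3 <- tempfile()
  writeScenario(generateScenario(smallSpec(0.6, seed = 4)), d3)
  expect_false(identical(readLines(f1),
                         readLines(file.path(d3, "target.fasta"))))
})

test_that("the default spec mirrors curated MMP dataset scales", {
  sp <- defaultMMPLikeSpec()
  expect_equal(sp@nSourceDomains, 5L)
  expect_true(all(sp@nSubstrates >= 23 & sp@nSubstrates <= 44))
  expect_true(all(sp@nSites >= 85 & sp@nSites <= 290))
  expect_setequal(names(sp@sharedMotif@positions),
                  c("P7", "P4", "P1", "P3p", "P6p", "P3", "P5p", "P1p"))
  # each domain adds exactly two private positions outside the shared set
  for (pm in sp@privateMotifs) {
    expect_length(pm@positions, 2)
    expect_length(intersect(names(pm@positions),
                            names(sp@sharedMotif@positions)), 0)
  }
  # strength 0 collapses to the pure background (valid spec)
  expect_s4_class(motifSpec(strength = 0), "MotifSpec")
  expect_error(motifSpec(strength = 1.5), "strength")
})

test_that("domains share motif truth but draw distinct sequences", {
  sc <- generateScenario(smallSpec(0.6, seed = 9))
  expect_identical(sc$truth$sharedPositions,
                   c(P7 = "G", P4 = "G", P1 = "G", P3p = "G", P6p = "G",
                     P3 = "P", P5p = "P", P1p = "L"))
  s1 <- sc$substrates[[1]][[1]]@sequence
  s2 <- sc$substrates[[2]][[1]]@sequence
  expect_false(identical(s1, s2))
})

test_that("scenario output round-trips through the io module unchanged", {
  sc <- generateScenario(smallSpec(0.6, seed = 5))
  dir <- tempfile()
  writeScenario(sc, dir)
  subs <- readSubstrates(file.path(dir, "target.fasta"),
                         file.path(dir, "target.tsv"))
  expect_length(subs, length(sc$substrates$target))
  orig <- sc$substrates$target[[1]]
  back <- subs[[which(vapply(subs, function(s) s@id,
                             character(1)) == orig@id)]]
  expect_identical(substrateSequence(back), orig@sequence)
  expect_identical(cleavageSites(back), orig@cleavagePositions)
  # and through windowing: positives recovered exactly
  win <- do.call(rbind, lapply(subs, extractWindows))
  expect_equal(sum(win$label == "positive"),
               sum(lengths(lapply(sc$substrates$target, cleavageSites))))
})

test_that("impossible site packing errors out", {
  sp <- smallSpec(0.6, seed = 1)
  sp@lengthRange <- c(20L, 24L)
  sp@nSubstrates <- c(2L, 2L)
  sp@nSites <- c(10L, 10L)    # 5 sites on a ~20-mer cannot fit
  expect_error(generateScenario(sp), "capacity")
})
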