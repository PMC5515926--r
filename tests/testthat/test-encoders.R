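test_that("per-scheme dimensionalities match the canonical table", {
  set.seed(1)
  for (w in replicate(5, randomWindow())) {
    expect_length(encodeAAindex(w), 1024)
    expect_length(encodeAAPair(w), 20)
    expect_length(encodeBinary(w), 336)
    expect_length(encodeBLOSUM(w), 336)
    expect_length(encodeChargeHyd(w), 9)
    expect_length(encodeCKSAAP(w), 2400)
    expect_length(encodeDisorder(w), 16)
    expect_length(encodePSSM(w), 320)
    full <- encodeWindow(w)
    expect_length(full, 4461)
    expect_false(anyDuplicated(names(full)) > 0)
  }
})

test_that("binary encoding is a 21-slot alphabetical one-hot", {
  v <- encodeBinary(strrep("A", 16))
  expect_equal(unname(v[seq(1, 336, by = 21)]), rep(1, 16))  # A slot
  expect_equal(sum(v), 16)

  # non-standard residues zero out the 20 standard slots
  vx <- encodeBinary(strrep("X", 16))
  std <- !grepl("nonstd", names(vx))
  expect_true(all(vx[std] == 0))
  expect_equal(sum(vx[!std]), 16)
})

test_that("AAindex encoding tiles residue values and imputes 'X' by means", {
  tab <- defaultAAindexTable()
  expect_equal(dim(tab), c(64L, 20L))
  vG <- encodeAAindex(strrep("G", 16))
  expect_equal(unname(vG), rep(unname(tab[, "G"]), 16))
  w <- paste0(strrep("G", 8), "X", strrep("G", 7))
  vX <- encodeAAindex(w)
  expect_equal(unname(vX[(8 * 64 + 1):(9 * 64)]), unname(rowMeans(tab)))
  # non-canonical table size recomputes the dimension and warns
  expect_warning(v32 <- encodeAAindex(strrep("G", 16), tab[1:32, ]),
                 "non-canonical")
  expect_length(v32, 16 * 32)
})

test_that("amino-acid composition sums to one and excludes pads", {
  vA <- encodeAAPair(strrep("A", 16))
  expect_equal(unname(vA["AAPair.A"]), 1)
  expect_equal(sum(vA), 1)
  vAG <- encodeAAPair(paste0(strrep("A", 8), strrep("G", 8)))
  expect_equal(unname(vAG[c("AAPair.A", "AAPair.G")]), c(0.5, 0.5))
  set.seed(2)
  for (w in replicate(5, randomWindow()))
    expect_equal(sum(encodeAAPair(w)), 1, tolerance = 1e-12)
  # pads excluded from numerator and denominator
  vPad <- encodeAAPair(paste0("XXXX", strrep("A", 12)))
  expect_equal(unname(vPad["AAPair.A"]), 1)
  expect_equal(sum(encodeAAPair(strrep("X", 16))), 0)
})

test_that("BLOSUM encoding reproduces BLOSUM62 rows", {
  bl <- local({
    env <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = env); env$BLOSUM62
  })
  vW <- encodeBLOSUM(strrep("W", 16))
  expect_equal(unname(vW["BLOSUM.P1.W"]), unname(bl["W", "W"]))
  expect_equal(unname(bl["W", "W"]), 11)
  expect_equal(unname(vW["BLOSUM.P1.A"]), unname(bl["W", "A"]))
  # pads use the matrix's own X row
  vX <- encodeBLOSUM(strrep("X", 16))
  expect_equal(unname(vX["BLOSUM.P8.A"]), unname(bl["X", "A"]))
  # determinism
  w <- randomWindow()
  expect_identical(encodeBLOSUM(w), encodeBLOSUM(w))
})

test_that("charge/hydrophobicity summaries follow the stated scales", {
  vG <- encodeChargeHyd(strrep("G", 16))
  expect_equal(unname(vG[grepl("netCharge|aromatic", names(vG))]), rep(0, 6))
  v <- encodeChargeHyd(paste0(strrep("K", 8), strrep("D", 8)))
  expect_equal(unname(v["CHARGE_Hyd.netCharge.full"]), 0)
  expect_equal(unname(v["CHARGE_Hyd.netCharge.Nhalf"]), 1)
  expect_equal(unname(v["CHARGE_Hyd.netCharge.Chalf"]), -1)
  # hand-computed ratio for the K half: |1| / (KD(K) + 5) = 1 / 1.1
  expect_equal(unname(v["CHARGE_Hyd.chargeHydRatio.Nhalf"]), 1 / 1.1)
  vH <- encodeChargeHyd(strrep("H", 16))
  expect_equal(unname(vH["CHARGE_Hyd.netCharge.full"]), 0.1)
  expect_equal(unname(vH["CHARGE_Hyd.aromatic.full"]), 1)
})

test_that("CKSAAP counts k-spaced pairs with the right normalisation", {
  vA <- encodeCKSAAP(strrep("A", 16))
  expect_equal(unname(vA["CKSAAP.k0.AA"]), 1)        # 15/15
  for (k in 0:5) {
    block <- vA[grepl(paste0("k", k, "\\."), names(vA))]
    expect_length(block, 400)
    expect_equal(sum(block), 1)                      # pad-free windows
  }
  # "GAGA..." at k = 0: 8 GA pairs and 7 AG pairs over N_Total = 15
  vGA <- encodeCKSAAP(strrep("GA", 8))
  expect_equal(unname(vGA["CKSAAP.k0.GA"]), 8 / 15)
  expect_equal(unname(vGA["CKSAAP.k0.AG"]), 7 / 15)
  # pads shrink N_Total: XXXXXAAAAAAAAAAA has 10 AA pairs at k = 0
  vPad <- encodeCKSAAP(paste0("XXXXX", strrep("A", 11)))
  expect_equal(unname(vPad["CKSAAP.k0.AA"]), 1)      # 10/10
  set.seed(3)
  for (w in replicate(3, randomWindow()))
    for (k in 0:5)
      expect_equal(sum(encodeCKSAAP(w, k)), 1, tolerance = 1e-12)
})

test_that("profile encoders align, squash and fall back as documented", {
  w <- randomWindow()
  expect_equal(unname(encodeDisorder(w)), rep(0.5, 16))
  prof <- seq(0, 1, length.out = 16)
  expect_equal(unname(encodeDisorder(w, prof)), prof)
  prof[3] <- NA
  expect_equal(unname(encodeDisorder(w, prof))[3], 0.5)

  expect_equal(unname(encodePSSM(w)), rep(0.5, 320))
  m <- matrix(0, 16, 20)
  expect_equal(unname(encodePSSM(w, m)), rep(0.5, 320))  # logistic midpoint
  m[1, 1] <- 100
  expect_equal(unname(encodePSSM(w, m))[1], 1, tolerance = 1e-12)
})

test_that("window-level profile slicing feeds the encoders correctly", {
  seq <- paste(rep("G", 30), collapse = "")
  sub <- new("Substrate", id = "s", sequence = seq,
             cleavagePositions = 15L,
             disorder = seq(0, 1, length.out = 30))
  win <- extractWindows(sub)
  fm <- encodeWindows(win[win$p1Position == 15, ],
                      substrates = list(sub), schemes = "DISOPRED")
  expect_equal(unname(featureData(fm)[1, ]),
               sub@disorder[8:23], tolerance = 1e-12)
  # terminal window: positions outside the substrate fall back to 0.5
  fm2 <- encodeWindows(win[win$p1Position == 1, ],
                       substrates = list(sub), schemes = "DISOPRED")
  expect_equal(unname(featureData(fm2)[1, 1:7]), rep(0.5, 7))
})

test_that("encoders are pure: identical windows give identical rows", {
  w <- randomWindow()
  expect_identical(encodeWindow(w), encodeWindow(w))
  ds <- data.frame(substrateId = "s", p1Position = c(1L, 2L),
                   residues = c(w, w), label = c("positive", "negative"))
  fm <- encodeWindows(ds, schemes = c("AAPair", "Binary", "CKSAAP"))
  expect_equal(unname(featureData(fm)[1, ]), unname(featureData(fm)[2, ]))
  expect_equal(sampleLabels(fm), c(1, -1))
})
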