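# Small labelled feature matrices with planted signal columns.
makeFM <- function(n, p, seed, planted = character(0), shift = 1.5,
                   prefix = "f") {
  set.seed(seed)
  labels <- rep(c(1, -1), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("w", seq_len(n)),
                              paste0(prefix, seq_len(p))))
  for (f in planted) x[, f] <- x[, f] + shift * labels
  new("FeatureMatrix", data = x, labels = labels)
}

test_that("common knowledge from one source reduces to plain mRMR", {
  fm <- makeFM(60, 10, seed = 1, planted = "f2")
  ck <- extractCommonKnowledge(list(a = fm), mCommon = 5)
  expect_identical(rankedFeatures(ck),
                   rankedFeatures(mrmrRank(fm, m = 5)))
  expect_identical(ck@sourceNames, "a")
})

test_that("a feature informative in all sources enters the common set", {
  hits <- vapply(1:10, function(seed) {
    fms <- lapply(1:3, function(d)
      makeFM(50, 12, seed = seed * 100 + d, planted = "f4", shift = 1.2))
    names(fms) <- paste0("s", 1:3)
    "f4" %in% rankedFeatures(extractCommonKnowledge(fms, mCommon = 3))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate common-knowledge requests behave as specified", {
  fm <- makeFM(40, 6, seed = 2)
  empty <- extractCommonKnowledge(list(a = fm), mCommon = 0)
  expect_length(rankedFeatures(empty), 0)
  expect_error(extractCommonKnowledge(list(a = fm), mCommon = 7), "exceeds")
  expect_error(extractCommonKnowledge(list(), 5), "at least one")
  # pooling requires a shared feature universe
  other <- makeFM(40, 6, seed = 3, prefix = "g")
  expect_error(extractCommonKnowledge(list(a = fm, b = other), 2),
               "same feature columns")
})

test_that("candidate lists put common features first, deduplicated", {
  common <- paste0("c", 1:5)
  target <- paste0("t", 1:10)
  disjoint <- buildCandidateList(common, target, mTarget = 10)
  expect_identical(as.character(disjoint), c(common, target))
  expect_identical(attr(disjoint, "origin"),
                   rep(c("common", "target_novel"), c(5, 10)))

  # full overlap: the list is exactly the common knowledge
  full <- buildCandidateList(common, common[5:1], mTarget = 10)
  expect_identical(as.character(full), common)

  # one shared feature sits at its common-list position only
  shared <- buildCandidateList(common, c("t1", "c3", "t2"), mTarget = 100)
  expect_identical(as.character(shared), c(common, "t1", "t2"))
  expect_equal(sum(shared == "c3"), 1)
  expect_equal(which(shared == "c3"), 3)
})

test_that("forward selection maximises the CV AUC trace", {
  fm <- makeFM(60, 6, seed = 4, planted = "f1", shift = 2.5)
  cfg <- svrConfig(cost = 4, gamma = 0.3, cvFolds = 5L, seed = 1L)

  one <- forwardSelect("f1", fm, cfg, gridSearch = FALSE)
  expect_equal(bestPrefixLength(one), 1L)
  expect_identical(selectedFeatures(one), "f1")

  # (strong signal, pure noise): the noise feature is not kept
  two <- forwardSelect(c("f1", "f3"), fm, cfg, gridSearch = FALSE)
  expect_equal(bestPrefixLength(two), 1L)
  expect_gte(aucTrace(two)[1], aucTrace(two)[2] - 0.05)

  # the final model's features are a prefix of the candidate list
  many <- forwardSelect(paste0("f", c(1, 4, 2)), fm, cfg, gridSearch = FALSE)
  expect_identical(selectedFeatures(many),
                   many@candidateList[seq_len(bestPrefixLength(many))])

  # determinism under a fixed seed
  again <- forwardSelect(c("f1", "f3"), fm, cfg, gridSearch = FALSE)
  expect_identical(aucTrace(two), aucTrace(again))

  tiny <- makeFM(12, 3, seed = 5)
  expect_error(forwardSelect("f1", tiny, cfg), "per class per fold")
  expect_error(forwardSelect(character(0), fm, cfg), "empty")
  expect_error(forwardSelect("nope", fm, cfg), "absent")
})

test_that("the target never contributes to common knowledge", {
  # target-only signal column f9; source-shared signal f2
  sources <- lapply(1:3, function(d) makeFM(60, 10, seed = 40 + d,
                                            planted = "f2", shift = 2))
  names(sources) <- paste0("s", 1:3)
  target <- makeFM(60, 10, seed = 50, planted = "f9", shift = 3)
  datasets <- c(sources, list(tgt = target))
  cfg <- svrConfig(cost = 4, gamma = 0.3, cvFolds = 5L, seed = 1L)
  res <- transferLearn(datasets, "tgt", mCommon = 2, mTarget = 3,
                       config = cfg, gridSearch = FALSE)
  commonFeats <- res@candidateList[res@origin == "common"]
  expect_identical(commonFeats,
                   rankedFeatures(extractCommonKnowledge(sources, 2)))
  expect_false("f9" %in% commonFeats)
  expect_true("f9" %in% res@candidateList[res@origin == "target_novel"])
})

test_that("zero common knowledge degenerates to target-only selection", {
  sources <- list(s1 = makeFM(40, 8, seed = 61), s2 = makeFM(40, 8, seed = 62))
  target <- makeFM(60, 8, seed = 63, planted = "f5", shift = 2)
  cfg <- svrConfig(cost = 4, gamma = 0.3, cvFolds = 5L, seed = 1L)
  res <- transferLearn(c(sources, list(tgt = target)), "tgt",
                       mCommon = 0, mTarget = 4, config = cfg,
                       gridSearch = FALSE)
  expect_identical(res@candidateList,
                   rankedFeatures(mrmrRank(target, m = 4)))
  expect_true(all(res@origin == "target_novel"))
})

test_that("the baseline reduces to top-m mRMR + SVR on a single dataset", {
  fm <- makeFM(60, 8, seed = 7, planted = "f3", shift = 2)
  cfg <- svrConfig(cost = 4, gamma = 0.3, cvFolds = 5L, seed = 1L)
  bl <- trainBaseline(list(only = fm), "only", m = 4, config = cfg,
                      gridSearch = FALSE)
  expect_identical(rankedFeatures(bl$ranking),
                   rankedFeatures(mrmrRank(fm, m = 4)))
  expect_s4_class(bl$metrics, "MetricsReport")
  expect_identical(selectedFeatures(bl$model), rankedFeatures(bl$ranking))
  # deterministic under a fixed config seed
  bl2 <- trainBaseline(list(only = fm), "only", m = 4, config = cfg,
                       gridSearch = FALSE)
  expect_equal(bl$metrics@auc, bl2$metrics@auc)
  # target-only selection flag ranks on the target alone
  two <- list(a = makeFM(40, 8, seed = 8), b = fm)
  blT <- trainBaseline(two, "b", m = 4, config = cfg, gridSearch = FALSE,
                       targetOnlySelection = TRUE)
  expect_identical(rankedFeatures(blT$ranking),
                   rankedFeatures(mrmrRank(fm, m = 4)))
})

test_that("transfer results export traces and summaries", {
  fm <- makeFM(60, 5, seed = 9, planted = "f1", shift = 2)
  cfg <- svrConfig(cost = 4, gamma = 0.3, cvFolds = 5L, seed = 1L)
  res <- forwardSelect(c("f1", "f2"), fm, cfg, gridSearch = FALSE)
  trace <- tempfile(fileext = ".tsv")
  summ <- tempfile(fileext = ".json")
  writeTransferResult(res, trace, summ)
  df <- read.delim(trace)
  expect_identical(names(df), c("prefix_length", "mean_auc", "sd_auc"))
  expect_equal(df$mean_auc, aucTrace(res))
  js <- jsonlite::read_json(summ, simplifyVector = TRUE)
  expect_equal(js$best_prefix_length, bestPrefixLength(res))
})
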