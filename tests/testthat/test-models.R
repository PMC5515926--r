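test_that("SVR separates a separable toy problem and is deterministic", {
  d <- separableData(n = 40, seed = 1)
  cfg <- svrConfig(cost = 8, gamma = 0.5)
  model <- trainSVR(d$x, d$labels, cfg)
  s <- predictScores(model, d$x)
  expect_equal(rocAUC(s, d$labels), 1)
  expect_identical(s, predictScores(trainSVR(d$x, d$labels, cfg), d$x))
  expect_error(trainSVR(d$x, rep(1, nrow(d$x)), cfg), "single class")
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 40
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
    labels <- sample(rep(c(1, -1), n / 2))
    cv <- crossValidate(x, labels, svrConfig(cost = 1, gamma = 0.3,
                                             seed = seed))
    cv@auc
  }, numeric(1))
  # permutation null: mean AUC ~ 0.5 within 3 standard errors
  expect_lt(abs(mean(aucs) - 0.5), 3 * stats::sd(aucs) / sqrt(length(aucs)))
})

test_that("grid search maximises CV AUC with the stated tie-breaks", {
  d <- separableData(n = 40, seed = 2)
  one <- svrConfig(costGrid = 4, gammaGrid = 0.2, cvFolds = 5L, seed = 1L)
  got <- gridSearchSVR(d$x, d$labels, one)
  expect_equal(c(got@cost, got@gamma), c(4, 0.2))

  cfg <- svrConfig(costGrid = c(1, 4, 16), gammaGrid = c(0.05, 0.5),
                   cvFolds = 5L, seed = 1L)
  best <- gridSearchSVR(d$x, d$labels, cfg)
  grid <- attr(best, "grid")
  # exhaustive oracle: winner's mean AUC >= every evaluated point
  expect_true(all(attr(best, "cvAUC") >= grid$meanAUC - 1e-12))
  winner <- grid[grid$cost == best@cost & grid$gamma == best@gamma, ]
  expect_equal(winner$meanAUC, attr(best, "cvAUC"))

  # all-tie degenerate data -> smallest cost then smallest gamma
  xdeg <- matrix(1, 20, 2, dimnames = list(NULL, c("a", "b")))
  ldeg <- rep(c(1, -1), 10)
  deg <- gridSearchSVR(xdeg, ldeg, cfg)
  expect_equal(c(deg@cost, deg@gamma), c(1, 0.05))
})

test_that("classification cutoff behaves monotonically", {
  expect_identical(classifyScores(c(-1, 0.5), 0), c(-1L, 1L))
  expect_true(all(classifyScores(rnorm(50), Inf) == -1L))
  s <- rnorm(100)
  counts <- vapply(sort(s), function(ct) sum(classifyScores(s, ct) == 1L),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("AUC is invariant to strictly increasing score transforms", {
  d <- separableData(n = 30, seed = 3)
  model <- trainSVR(d$x, d$labels, svrConfig(cost = 2, gamma = 0.4))
  s <- predictScores(model, d$x)
  expect_equal(rocAUC(s, d$labels), rocAUC(exp(2 * s) + 5, d$labels))
})

test_that("standardisation uses training rows only (no CV leakage)", {
  set.seed(9)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  labels <- rep(c(1, -1), 15)
  model <- trainSVR(x[1:20, ], labels[1:20], svrConfig(cost = 1, gamma = 0.5))
  expect_equal(unname(model@center), unname(colMeans(x[1:20, ])))
  # scores on held-out rows are unaffected by arbitrary shifts of those rows
  s1 <- predictScores(model, x[21:30, ])
  model2 <- trainSVR(x[1:20, ], labels[1:20], svrConfig(cost = 1, gamma = 0.5))
  expect_identical(model@center, model2@center)
  expect_identical(s1, predictScores(model2, x[21:30, ]))
})

test_that("stratified folds preserve class balance and seeds", {
  labels <- rep(c(1, -1), c(20, 60))
  f <- stratifiedFolds(labels, 5, seed = 4)
  expect_true(all(table(f[labels == 1]) == 4))
  expect_true(all(table(f[labels == -1]) == 12))
  expect_identical(f, stratifiedFolds(labels, 5, seed = 4))
  expect_false(identical(f, stratifiedFolds(labels, 5, seed = 5)))
})

test_that("models round-trip through single-file serialization", {
  d <- separableData(n = 30, seed = 5)
  model <- trainSVR(d$x, d$labels, svrConfig(cost = 4, gamma = 0.3))
  path <- tempfile(fileext = ".json")
  saveTrainedSVR(model, path)
  back <- loadTrainedSVR(path)
  expect_identical(back@featureNames, model@featureNames)
  expect_equal(predictScores(back, d$x), predictScores(model, d$x),
               tolerance = 1e-10)
  expect_error(suppressWarnings(loadTrainedSVR(tempfile())), regexp = ".")
})
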