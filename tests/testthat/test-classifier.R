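# Split, PSO search, SVM training/evaluation and the level sweep.

test_that("stratified split is disjoint, exhaustive and proportionate", {
  labs <- factor(rep(c("RIGOR", "AGED", "SPOILED"), c(30, 40, 30)))
  sp <- splitDataset(labs, seed = 1)
  expect_length(sp$train, 66L)
  expect_length(sp$test, 34L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  # class proportions preserved within one sample
  for (cl in levels(labs)) {
    expect_lte(abs(sum(labs[sp$test] == cl) - 34 * mean(labs == cl)), 1)
  }
  # determinism and seed sensitivity
  expect_identical(splitDataset(labs, seed = 1), sp)
  expect_false(identical(splitDataset(labs, seed = 2)$test, sp$test))
  expect_error(splitDataset(labs[1:99]), "expected 100")
})

test_that("PSO bookkeeping: monotone best trace, degenerate box, tiny swarm", {
  set.seed(61)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))

  res <- psoSearch(X, y, pso = psoConfig(swarm = 6, iterations = 8, seed = 2))
  expect_true(all(diff(res$trace) >= 0))
  expect_equal(res$fitness, max(res$trace))

  # one-point search box returns that point
  eps <- 1e-9
  boxed <- psoSearch(X, y, pso = psoConfig(
    swarm = 3, iterations = 2, logC = c(1, 1 + eps),
    logSigma = c(0, eps), seed = 1))
  expect_equal(boxed$C, 10, tolerance = 1e-6)
  expect_equal(boxed$sigma, 1, tolerance = 1e-6)

  # swarm of 2, one iteration still returns an evaluated particle
  tiny <- psoSearch(X, y, pso = psoConfig(swarm = 2, iterations = 1, seed = 3))
  expect_true(tiny$C >= 1e-2 && tiny$C <= 1e4)

  expect_error(psoSearch(X, factor(rep("a", 40))), "degenerate")
})

test_that("PSO-selected parameters are at least as good as a fixed default", {
  coh <- simulateCohort(seed = 21)
  labs <- droplevels(stageLabels(coh))
  feats <- featureMatrix(coh, "db5", 4)
  sp <- splitDataset(labs, seed = 3)
  tr <- sp$train
  pso <- psoConfig(swarm = 10, iterations = 10, seed = 5)
  best <- psoSearch(feats[tr, ], labs[tr], pso = pso)
  # compare on the PSO's own cross-validated objective, same folds
  folds <- local({
    set.seed(pso$seed)
    porkHSI:::.cvFolds(labs[tr], 5L)
  })
  fitDefault <- porkHSI:::.cvAccuracy(feats[tr, ], labs[tr], 1, 1, folds)
  expect_gte(best$fitness, fitDefault)
})

test_that("SVM training separates blobs and overfits when asked to", {
  set.seed(62)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  y <- factor(rep(c("a", "b"), each = 30))
  m <- trainStageSVM(X, y, list(C = 1, sigma = 1))
  expect_equal(evaluateAccuracy(m, X, y), 100)

  # memorising regime: tiny kernel width, huge penalty
  Xhard <- matrix(rnorm(80), 40, 2)
  yhard <- factor(rep(c("a", "b"), 20))
  mh <- trainStageSVM(Xhard, yhard, list(C = 1e6, sigma = 0.01))
  expect_equal(evaluateAccuracy(mh, Xhard, yhard), 100)
})

test_that("accuracy is a percentage with two decimals", {
  set.seed(63)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  y <- factor(rep(c("a", "b"), each = 30))
  m <- trainStageSVM(X, y, list(C = 1, sigma = 1))
  # craft a 34-sample verification set with exactly one / two planted errors
  X34 <- rbind(matrix(rnorm(34, 0), 17, 2), matrix(rnorm(34, 5), 17, 2))
  y34 <- factor(rep(c("a", "b"), each = 17))
  expect_equal(evaluateAccuracy(m, X34, y34), 100)
  yerr1 <- y34; yerr1[1] <- "b"
  expect_equal(evaluateAccuracy(m, X34, yerr1), 97.06)
  yerr2 <- yerr1; yerr2[2] <- "b"
  expect_equal(evaluateAccuracy(m, X34, yerr2), 94.12)
  expect_error(evaluateAccuracy(m, X34[0, , drop = FALSE], y34[0]), "empty")
})

test_that("the feature scaler is fitted on calibration data only", {
  coh <- simulateCohort(seed = 22)
  labs <- droplevels(stageLabels(coh))
  feats <- featureMatrix(coh, "db5", 4)
  sp <- splitDataset(labs, seed = 1)
  m <- trainStageSVM(feats[sp$train, ], labs[sp$train], list(C = 10, sigma = 3))
  expect_equal(m@center, colMeans(feats[sp$train, ]), tolerance = 1e-12)
  expect_equal(m@scale, apply(feats[sp$train, ], 2, sd), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m@center, colMeans(feats))))
})

test_that("models round-trip through serialization with identical predictions", {
  coh <- simulateCohort(seed = 23)
  labs <- droplevels(stageLabels(coh))
  feats <- featureMatrix(coh, "db5", 4)
  m <- trainStageSVM(feats, labs, list(C = 10, sigma = 3), wavelet = "db5",
                     level = 4L, wavelengths = wavelengths(coh))
  path <- tempfile(fileext = ".rds")
  saveStageModel(m, path)
  m2 <- readStageModel(path)
  expect_identical(predictStages(m2, feats), predictStages(m, feats))
  expect_identical(m2@hyperparams, m@hyperparams)

  # fingerprint enforcement
  expect_error(predictStages(m, feats[, 1:10]), "dimension")
})

test_that("the level sweep reports the expected dimensions and is seeded", {
  coh <- simulateCohort(seed = 24)
  pso <- psoConfig(swarm = 4, iterations = 3, seed = 2)
  sw <- levelSweep(coh, levels = 2:7, pso = pso, split_seed = 2)
  expect_identical(sw$dimension[sw$decomposition != "original spectra" &
                                  sw$decomposition != "1-level"],
                   c(232L, 124L, 70L, 44L, 30L, 24L))
  # wide inputs are reported but not fitted under the default cap
  expect_false(any(sw$feasible[sw$dimension > 300]))
  expect_true(all(sw$feasible[sw$dimension <= 300]))
  expect_true(all(sw$test_acc[sw$feasible] >= 0 &
                    sw$test_acc[sw$feasible] <= 100))
  # exact fractions accompany the percentages
  ok <- sw$feasible
  expect_equal(sw$test_acc[ok],
               round(100 * sw$test_correct[ok] / sw$test_n[ok], 2))

  sw2 <- levelSweep(coh, levels = 2:7, pso = pso, split_seed = 2)
  keep <- setdiff(names(sw), "seconds")  # wall time is not reproducible
  expect_identical(sw[keep], sw2[keep])
})
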