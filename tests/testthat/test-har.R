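test_that("an untrained model with a zeroed head predicts uniform probabilities", {
  fw <- makeRandomWindows(n = 5, Tn = 12, seed = 2)
  mdl <- initHarModel(fw, harConfig(dModel = 8, nHeads = 2, dff = 8,
                                    dGcn = 4, subFrames = 3, seed = 1),
                      zeroHead = TRUE)
  pr <- classifyWindows(mdl, fw)$probabilities
  expect_equal(unname(pr), matrix(0.5, 5, 2), tolerance = 1e-12)
})

test_that("class probabilities sum to one and prediction is deterministic", {
  fw <- makeRandomWindows(n = 8, Tn = 12, seed = 3)
  mdl <- initHarModel(fw, harConfig(dModel = 8, nHeads = 2, dff = 8,
                                    dGcn = 4, subFrames = 3, seed = 2))
  a <- classifyWindows(mdl, fw)
  b <- classifyWindows(mdl, fw)
  expect_equal(unname(rowSums(a$probabilities)), rep(1, 8),
               tolerance = 1e-6)
  expect_identical(a$probabilities, b$probabilities)
})

test_that("the analytic backward pass matches numerical gradients", {
  cfg <- harConfig(dModel = 8, nHeads = 2, nLayers = 1, dff = 10,
                   dGcn = 4, subFrames = 3, seed = 5)
  fw <- makeRandomWindows(n = 4, Tn = 12, seed = 3)
  g <- skeletonGraph()
  feats <- wearHAR:::.windowNodeFeatures(fw, graphNodes(g), 3)
  Ahat <- buildNormalizedAdjacency(g)
  p <- wearHAR:::.initHarParams(cfg, lapply(feats, ncol), 2)
  y <- c(1L, 2L, 1L, 2L)
  fwd <- wearHAR:::.harForward(p, feats, Ahat, cfg, 4)
  gv <- wearHAR:::.flattenParams(
    wearHAR:::.harBackward(p, feats, Ahat, cfg, 4, fwd, y)$grad)
  pv <- wearHAR:::.flattenParams(p)
  lossAt <- function(v) {
    pp <- wearHAR:::.unflattenParams(p, v)
    f <- wearHAR:::.harForward(pp, feats, Ahat, cfg, 4)
    pr <- wearHAR:::.softmaxRows(f$logits)
    -mean(log(pr[cbind(1:4, y)]))
  }
  set.seed(9)
  idx <- sort(sample(length(pv), 40))
  num <- vapply(idx, function(i) {
    e <- rep(0, length(pv)); e[i] <- 1e-5
    (lossAt(pv + e) - lossAt(pv - e)) / 2e-5
  }, 0)
  expect_lt(max(abs(num - gv[idx])), 1e-6)
})

test_that("training reduces the loss and beats chance on a small separable set", {
  fw <- syntheticHarDataset(nSubjects = 2, seed = 31)
  z <- zscoreFitApply(fw)
  mdl <- trainHarModel(z$train,
                       harConfig(dModel = 16, nHeads = 2, dff = 32,
                                 dGcn = 8, subFrames = 4, seed = 1),
                       epochs = 15, lr = 0.02)
  expect_lt(tail(mdl@log$loss, 1), mdl@log$loss[1])
  expect_gt(tail(mdl@log$train_acc, 1), 60)
})

test_that("the subject-level split is disjoint, exhaustive, stratified 7:2:1 and seed-stable", {
  fw <- makeRandomWindows(n = 40, Tn = 12, seed = 4)
  fw@subject <- rep(sprintf("s%02d", 1:10), each = 4)
  sp <- splitDataset(fw, seed = 3)
  subjOf <- function(x) unique(windowSubjects(x))
  expect_length(subjOf(sp$train), 7)
  expect_length(subjOf(sp$validation), 2)
  expect_length(subjOf(sp$test), 1)
  all3 <- c(subjOf(sp$train), subjOf(sp$validation), subjOf(sp$test))
  expect_setequal(all3, unique(fw@subject))
  expect_equal(anyDuplicated(all3), 0)
  expect_equal(nWindows(sp$train) + nWindows(sp$validation) +
                 nWindows(sp$test), nWindows(fw))
  sp2 <- splitDataset(fw, seed = 3)
  expect_identical(subjOf(sp$train), subjOf(sp2$train))
  fw3 <- subsetWindows(fw, fw@subject %in% c("s01", "s02"))
  expect_error(splitDataset(fw3), "3 subjects")
})

test_that("cross-validation partitions subjects and returns the winning configuration", {
  fw <- syntheticHarDataset(nSubjects = 5, seed = 41)
  grid <- list(harConfig(dModel = 16, nHeads = 2, dff = 16, dGcn = 4,
                         subFrames = 4, seed = 1))
  cv <- crossValidate(fw, grid, k = 5, seed = 2, epochs = 4, lr = 0.02)
  expect_identical(cv$best, grid[[1]])
  expect_equal(sort(unique(cv$folds$fold)), 1:5)
  expect_equal(nrow(cv$folds), 5)
  expect_error(crossValidate(fw, list(), k = 2), "non-empty")
})

test_that("evaluation metrics match hand counts and flag absent classes", {
  r <- evaluateClassifier(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  pc <- perClassMetrics(r)
  expect_equal(pc$precision[pc$class == "B"], 100 * 2 / 3,
               tolerance = 1e-9)
  expect_equal(pc$recall[pc$class == "B"], 100)
  expect_equal(pc$f1[pc$class == "B"], 80)
  expect_equal(overallAccuracy(r), 75)
  expect_equal(sum(confusionMatrix(r)), 4)
  expect_equal(unname(rowSums(confusionMatrix(r))), pc$support)
  ## perfect predictions
  rp <- evaluateClassifier(c("A", "B"), c("A", "B"))
  expect_equal(overallAccuracy(rp), 100)
  expect_true(all(perClassMetrics(rp)$f1 == 100))
  ## class absent from truth: NA, not zero
  ra <- evaluateClassifier(factor(c("A", "C"), levels = c("A", "B", "C")),
                           factor(c("A", "A"), levels = c("A", "B", "C")))
  expect_true(is.na(perClassMetrics(ra)$recall[2]))
  expect_error(evaluateClassifier("A", c("A", "B")), "equal length")
})
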