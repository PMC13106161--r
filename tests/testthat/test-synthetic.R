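test_that("sampling-rate policy maps intensity to the documented levels", {
  expect_equal(sampleRatePolicy(0.05), 50)
  expect_equal(sampleRatePolicy(0.95), 200)
  grid <- sampleRatePolicy(seq(0, 1, length.out = 101))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 50 & grid <= 200))
  expect_error(sampleRatePolicy(1.2), "intensity")
})

test_that("zero-intensity rest gives gravity-plus-noise and resting heart rate", {
  sc <- actionScript("rest", 10, 0)
  su <- virtualSubject(restingHr = 62)
  st <- simulateSession(sc, su, seed = 1)
  sig <- signalMatrix(st)
  expect_equal(mean(sig["wrist_az", ]), 9.81, tolerance = 0.05)
  expect_equal(mean(sig["wrist_ax", ]), 0, tolerance = 0.05)
  expect_lt(sd(sig["wrist_ax", ]), 0.5)     # noise only
  expect_equal(mean(sig["heart_rate", ]), 62, tolerance = 2)
})

test_that("simulation is bit-identical under a fixed seed and rejects unknown labels", {
  sc <- actionScript(c("running", "rest"), c(4, 4), c(0.8, 0))
  a <- simulateSession(sc, virtualSubject(), seed = 9)
  b <- simulateSession(sc, virtualSubject(), seed = 9)
  expect_identical(signalMatrix(a), signalMatrix(b))
  expect_identical(streamTimes(a), streamTimes(b))
  expect_error(actionScript("moonwalk", 5, 0.5), "moonwalk")
})

test_that("per-action accelerometer signatures are separable by periodogram", {
  sc <- actionScript(c("running", "squat"), c(8, 8), c(0.8, 0.8))
  st <- simulateSession(sc, virtualSubject(), seed = 42, rate = 200)
  lab <- sampleLabels(st)
  x <- signalMatrix(st)["wrist_ax", ]
  fRun <- dominantFreq(x[lab == "running"], 200)
  fSquat <- dominantFreq(x[lab == "squat"], 200)
  expect_gt(fRun, fSquat)
  ## argmax recovers the generator's configured frequencies
  expect_equal(fRun, 2.8, tolerance = 0.2)
  expect_equal(fSquat, 0.6, tolerance = 0.2)
})

test_that("interference is confined to its window and deterministic", {
  sc <- actionScript("walking", 20, 0.5)
  st <- simulateSession(sc, virtualSubject(), seed = 3, rate = 100)
  ## magnitude 0 leaves the stream untouched
  z <- injectInterference(st, interferenceSpec("emi", 0, 5, 5), seed = 1)
  expect_equal(signalMatrix(z), signalMatrix(st))
  ## emi raises in-window RMS on accel channels, leaves outside untouched
  em <- injectInterference(st, interferenceSpec("emi", 2, 5, 5), seed = 1)
  tt <- streamTimes(st) - streamTimes(st)[1]
  inW <- tt >= 5 & tt <= 10
  delta <- signalMatrix(em)["wrist_ax", ] - signalMatrix(st)["wrist_ax", ]
  expect_true(all(delta[!inW] == 0))
  expect_gt(sqrt(mean(delta[inW]^2)), 1)
  em2 <- injectInterference(st, interferenceSpec("emi", 2, 5, 5), seed = 1)
  expect_identical(signalMatrix(em), signalMatrix(em2))
  ## temperature drift reaches the configured delta at the window end
  td <- injectInterference(st, interferenceSpec("temp_drift", 10, 2, 8),
                           seed = 1)
  dT <- signalMatrix(td)["skin_temp", ] - signalMatrix(st)["skin_temp", ]
  expect_equal(max(dT), 10, tolerance = 1e-9)
  expect_equal(dT[which(inW <- tt >= 2 & tt <= 10)[1]], 0, tolerance = 1e-9)
  ## window outside the span is rejected
  expect_error(
    injectInterference(st, interferenceSpec("emi", 1, 18, 5), seed = 1),
    "span")
})

test_that("segment drop-out masks the expected fraction and keeps ground truth", {
  sc <- actionScript("walking", 10, 0.5)
  st <- simulateSession(sc, virtualSubject(), seed = 4, rate = 100)
  d0 <- dropSegments(st, 0, seed = 1)
  expect_false(any(missingMask(d0)))
  d <- dropSegments(st, 0.1, seed = 1)
  nMasked <- sum(missingMask(d)["wrist_ax", ])
  ## binomial 99% interval around 0.1 * 1000
  bounds <- qbinom(c(0.005, 0.995), ncol(d), 0.1)
  expect_gte(nMasked, bounds[1])
  expect_lte(nMasked, bounds[2])
  d2 <- dropSegments(st, 0.1, seed = 1)
  expect_identical(missingMask(d), missingMask(d2))
  ## masked values are NA but retained as ground truth
  expect_true(anyNA(signalMatrix(d)))
  expect_false(anyNA(metadata(d)$truth))
  expect_error(dropSegments(st, 1, seed = 1), "rate")
})

test_that("contiguous drop-out runs have the requested mean length", {
  sc <- actionScript("walking", 60, 0.5)
  st <- simulateSession(sc, virtualSubject(), seed = 5, rate = 100)
  d <- dropSegments(st, 0.05, seed = 2, mean_gap = 20)
  m <- missingMask(d)["wrist_ax", ]
  runs <- rle(m)
  gapLens <- runs$lengths[runs$values]
  expect_gt(mean(m), 0.02)        # correlated process: wide bounds
  expect_lt(mean(m), 0.10)
  expect_gt(mean(gapLens), 5)     # genuinely contiguous, not iid
})

test_that("nearest-centroid baseline separates the default classes", {
  fw <- syntheticHarDataset(nSubjects = 4, seed = 21)
  subj <- windowSubjects(fw)
  train <- subsetWindows(fw, subj != "s04")
  test <- subsetWindows(fw, subj == "s04")
  z <- zscoreFitApply(train, test = test)
  nc <- nearestCentroidClassifier(z$train, z$test)
  expect_gt(nc$accuracy, 80)
})
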