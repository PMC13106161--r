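test_that("resampling a signal already on the target grid is the identity", {
  st <- makeTinyStream(sin(1:100), rate = 50)
  out <- resampleStream(st, 50)
  expect_equal(signalMatrix(out)[1, ], signalMatrix(st)[1, ],
               tolerance = 1e-12)
})

test_that("linear interpolation reproduces ramps exactly at midpoints", {
  tt <- seq_len(100) / 50
  st <- makeTinyStream(2 * tt, rate = 50)
  out <- resampleStream(st, 100)
  gr <- streamTimes(out)
  expect_equal(signalMatrix(out)[1, ], 2 * gr, tolerance = 1e-12)
})

test_that("downsampling a slow sine stays within 1e-3 of the analytic curve", {
  tt <- seq_len(1000) / 200
  st <- makeTinyStream(sin(2 * pi * 1 * tt), rate = 200)
  out <- resampleStream(st, 50)
  expect_lt(max(abs(signalMatrix(out)[1, ] -
                      sin(2 * pi * streamTimes(out)))), 1e-3)
})

test_that("missing spans stay masked through resampling", {
  st <- makeTinyStream(sin(1:100), rate = 50)
  st <- dropSegments(st, 0.3, seed = 1)
  out <- resampleStream(st, 100)
  expect_true(any(missingMask(out)))
  expect_true(all(is.na(signalMatrix(out)[missingMask(out)])))
  expect_error(resampleStream(makeTinyStream(1, rate = 50), 50), "2 samples")
})

test_that("window segmentation arithmetic matches the stated layout", {
  ## 4 s at 100 Hz -> 3 windows of 200 samples starting 1 s apart
  sc <- actionScript("walking", 4, 0.5)
  st <- simulateSession(sc, virtualSubject(), seed = 1, rate = 100)
  fw <- segmentWindows(st, 2, 0.5)
  expect_equal(nWindows(fw), 3)
  expect_equal(dim(windowArray(fw))[1], 200)
  expect_equal(diff(fw@startTime), c(1, 1), tolerance = 1e-9)
  ## a 2-s stream gives exactly one window
  sc2 <- actionScript("walking", 2, 0.5)
  st2 <- simulateSession(sc2, virtualSubject(), seed = 1, rate = 100)
  expect_equal(nWindows(segmentWindows(st2, 2, 0.5)), 1)
  ## shorter than one window: zero windows with a warning
  sc3 <- actionScript("walking", 1, 0.5)
  st3 <- simulateSession(sc3, virtualSubject(), seed = 1, rate = 100)
  expect_warning(fw3 <- segmentWindows(st3, 2, 0.5), "shorter")
  expect_equal(nWindows(fw3), 0)
})

test_that("windows take the majority label with ties going to the earlier label", {
  vals <- rnorm(40)
  ## 20 samples of A then 20 of B at 10 Hz; the 2-4 s window is a 10/10 tie
  st <- makeTinyStream(vals, rate = 10,
                       labels = rep(c("running", "rest"), each = 20))
  fw <- segmentWindows(st, 2, 0.5)
  labs <- as.character(windowLabels(fw))
  expect_equal(labs[1], "running")
  expect_equal(labs[3], "rest")
  expect_equal(labs[2], "running")   # tie resolves to the earlier label
})

test_that("Z-score statistics are fit on training data and applied to other splits", {
  ## column {1,2,3}: population-sd standardisation
  arr <- array(c(1, 2, 3), dim = c(3, 1, 1))
  fw <- new("FeatureWindows", windows = arr, labels = factor("a"),
            subject = "s", startTime = 0, channels = "x", rate = 100,
            normCenter = numeric(0), normScale = numeric(0))
  z <- zscoreFitApply(fw)
  expect_equal(as.numeric(z$train@windows), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  ## already-standardised training data: identity
  z2 <- zscoreFitApply(z$train)
  expect_equal(z2$train@windows, z$train@windows, tolerance = 1e-9)
  ## validation transformed with training stats, not its own
  arrV <- array(c(11, 12, 13), dim = c(3, 1, 1))
  fwV <- new("FeatureWindows", windows = arrV, labels = factor("a"),
             subject = "s", startTime = 0, channels = "x", rate = 100,
             normCenter = numeric(0), normScale = numeric(0))
  z3 <- zscoreFitApply(fw, validation = fwV)
  expect_equal(as.numeric(z3$validation@windows),
               (c(11, 12, 13) - 2) / sqrt(2 / 3), tolerance = 1e-9)
  ## zero-variance feature kept with scale 1, with a message
  arrC <- array(rep(5, 6), dim = c(3, 2, 1))
  arrC[, 2, ] <- c(1, 2, 3)
  fwC <- new("FeatureWindows", windows = arrC, labels = factor("a"),
             subject = "s", startTime = 0, channels = c("flat", "x"),
             rate = 100, normCenter = numeric(0), normScale = numeric(0))
  expect_message(zc <- zscoreFitApply(fwC), "flat")
  expect_equal(as.numeric(zc$train@windows[, 1, ]), c(0, 0, 0))
})
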