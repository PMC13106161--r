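test_that("db9 filter satisfies the orthonormal quadrature-mirror identities", {
  g <- wearHAR:::.DB9_SCALING
  expect_equal(sum(g), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(g^2), 1, tolerance = 1e-12)
  for (k in 1:8)                  # shift-orthogonality at even lags
    expect_equal(sum(g * c(rep(0, 2 * k), g)[seq_along(g)]), 0,
                 tolerance = 1e-12)
})

test_that("semi-soft threshold reproduces its three branches as printed", {
  expect_equal(semiSoftThreshold(0.5, 1, 3), 0)
  expect_equal(semiSoftThreshold(2, 1, 3), 1.5)     # 3*(2-1)/(3-1)
  expect_equal(semiSoftThreshold(-5, 1, 3), -4)     # sgn(-5)*(5-1)
})

test_that("semi-soft threshold is sign-preserving, shrinking, dead below the low cutoff, and jumps at the high cutoff", {
  d <- seq(-6, 6, by = 0.01)
  out <- semiSoftThreshold(d, 1, 3)
  expect_true(all(sign(out) == sign(d) | out == 0))
  expect_true(all(abs(out) <= abs(d) + 1e-12))
  expect_true(all(out[abs(d) <= 1] == 0))
  ## the printed rule is discontinuous at |d| = lambdaHigh: the middle
  ## branch tends to lambdaHigh while the top branch starts at
  ## lambdaHigh - lambdaLow, a jump of exactly lambdaLow
  below <- semiSoftThreshold(3 - 1e-9, 1, 3)
  at <- semiSoftThreshold(3, 1, 3)
  expect_equal(below, 3, tolerance = 1e-6)
  expect_equal(at, 2)
  ## the optional continuous variant closes the jump
  expect_equal(semiSoftThreshold(3, 1, 3, continuous = TRUE), 3)
  expect_equal(semiSoftThreshold(3 - 1e-9, 1, 3, continuous = TRUE), 3,
               tolerance = 1e-6)
})

test_that("wavelet round trip with zero thresholds is exact to 1e-8", {
  set.seed(1)
  for (n in c(300, 512, 1000)) {
    x <- rnorm(n)
    y <- denoiseWavelet(x, waveletParams(J = 4, lambdaLow = 0,
                                         lambdaHigh = 0, rule = "fixed"))
    expect_lt(max(abs(y - x)), 1e-8)
  }
})

test_that("universal-threshold denoising reduces pure-noise variance", {
  set.seed(2)
  x <- rnorm(1024)
  y <- denoiseWavelet(x, waveletParams(J = 4))
  expect_lt(var(y), var(x))
})

test_that("denoising a noisy sine improves SNR against the known clean component", {
  set.seed(3)
  t <- seq(0, 10, by = 1 / 100)
  clean <- sin(2 * pi * 2 * t)
  noisy <- clean + rnorm(length(t), 0, 0.5)
  den <- denoiseWavelet(noisy, waveletParams(J = 5))
  expect_gt(snrDb(den, clean), snrDb(noisy, clean))
})

test_that("signals too short for the requested depth are rejected naming the feasible depth", {
  expect_error(denoiseWavelet(rnorm(8), waveletParams(J = 4)), "J")
  expect_error(
    wearHAR:::.dwtForward(rnorm(64), 5), "maximum feasible J")
})
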