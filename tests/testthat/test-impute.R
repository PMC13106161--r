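test_that("a constant series with a gap is imputed back to the constant", {
  x <- rep(3, 400)
  x[200:210] <- NA
  fill <- imputeSeries(x, tau = 8, hidden = 8, epochs = 120, seed = 1)
  expect_lt(max(abs(fill[200:210] - 3)), 1e-2)
})

test_that("series without missing samples pass through untouched", {
  x <- rnorm(100)
  expect_identical(imputeSeries(x), x)
})

test_that("recurrent imputation beats linear interpolation on gapped AR(1) data", {
  g <- makeGappedAr1(n = 3000, phi = 0.9, sd = 0.1, seed = 11)
  xm <- g$x; xm[g$gap] <- NA
  fill <- imputeSeries(xm, tau = 10, hidden = 16, epochs = 150, seed = 1)
  lin <- imputeLinear(xm)
  mseRnn <- mean((fill[g$gap] - g$x[g$gap])^2)
  mseLin <- mean((lin[g$gap] - g$x[g$gap])^2)
  expect_lte(mseRnn, mseLin)
  ## observed samples are untouched
  expect_identical(fill[!g$gap], g$x[!g$gap])
})

test_that("gaps at the series start fall back to linear interpolation with a note", {
  set.seed(4)
  x <- rnorm(200)
  x[2:6] <- NA
  expect_message(fill <- imputeSeries(x, tau = 10, hidden = 8,
                                      epochs = 50, seed = 1),
                 "linear fallback")
  expect_false(anyNA(fill))
})

test_that("stream-level imputation clears the mask and records provenance", {
  sc <- actionScript("walking", 8, 0.5)
  st <- simulateSession(sc, virtualSubject(), seed = 6, rate = 50)
  dm <- dropSegments(st, 0.05, seed = 2, mean_gap = 10)
  imp <- imputeStream(dm, epochs = 30)
  expect_false(any(missingMask(imp)))
  expect_false(anyNA(signalMatrix(imp)))
  expect_equal(metadata(imp)$imputation$n_imputed,
               sum(missingMask(dm)))
  ## untouched where observed
  obs <- !missingMask(dm)
  expect_identical(signalMatrix(imp)[obs], signalMatrix(dm)[obs])
})
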