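## Shared fixtures and independent oracles, all built in code.

## a small single-channel uniform stream with explicit labels
makeTinyStream <- function(values, rate = 10, labels = NULL,
                           channel = "wrist_ax") {
  n <- length(values)
  sig <- matrix(values, 1, n, dimnames = list(channel, NULL))
  SensorStream(sig, time = seq_len(n) / rate, placement = "wrist",
               unit = "m/s^2", nominal_rate = max(50, min(rate, 200)),
               label = labels)
}

## independent DTW oracle: exhaustive enumeration of all monotone paths
## from (1,1) to (M,N) with steps (1,0), (0,1), (1,1); cost of a path is
## the sum of local costs over its cells
bruteForceDtw <- function(C) {
  M <- nrow(C); N <- ncol(C)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + C[i, j]
    if (acc >= best) return(invisible())
    if (i == M && j == N) {
      best <<- acc
      return(invisible())
    }
    if (i < M) recurse(i + 1, j, acc)
    if (j < N) recurse(i, j + 1, acc)
    if (i < M && j < N) recurse(i + 1, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

## stationary AR(1) series with contiguous drop-out runs; returns the
## clean series and the gap mask
makeGappedAr1 <- function(n = 3000, phi = 0.9, sd = 0.1, seed = 11,
                          runMean = 25, targetFrac = 0.05) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd))
  gap <- logical(n)
  i <- 200
  while (i < n - 100) {
    if (runif(1) < targetFrac / runMean * 1.05) {
      L <- rgeom(1, 1 / runMean) + 10
      gap[i:min(i + L, n - 30)] <- TRUE
      i <- i + L + 30
    }
    i <- i + 1
  }
  list(x = x, gap = gap)
}

## dominant periodogram frequency (Hz) of a uniform-rate series
dominantFreq <- function(x, rate) {
  s <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  s$freq[which.max(s$spec)] * rate
}

## a small FeatureWindows with the standard 12-channel layout
makeRandomWindows <- function(n = 6, Tn = 12, seed = 1,
                              labels = NULL, subject = "s") {
  set.seed(seed)
  lay <- wearHAR:::.channelLayout()
  arr <- array(rnorm(Tn * 12 * n), dim = c(Tn, 12, n))
  if (is.null(labels))
    labels <- rep(c("a", "b"), length.out = n)
  new("FeatureWindows", windows = arr, labels = factor(labels),
      subject = rep(subject, length.out = n), startTime = seq_len(n),
      channels = lay$channel, rate = 100,
      normCenter = numeric(0), normScale = numeric(0))
}
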