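## Daubechies-9 wavelet machinery.
##
## No wavelet package ships with this R installation, so the periodised
## orthogonal DWT is implemented directly. The db9 scaling (synthesis
## low-pass) filter below is the standard set of 18 constants from the
## Daubechies extremal-phase construction; the analysis and wavelet
## filters follow from the quadrature-mirror relations. Orthonormality and
## perfect reconstruction are asserted in the test suite.

.DB9_SCALING <- c(
  0.038077947363878345, 0.24383467461259034, 0.6048231236901112,
  0.6572880780513005, 0.13319738582500756, -0.2932737832791749,
  -0.09684078322297646, 0.14854074933810638, 0.03072568147933338,
  -0.06763282906132997, 0.00025094711483145197, 0.022361662123679096,
  -0.004723204757751397, -0.00428150368246343, 0.0018476468830562265,
  0.00023038576352319597, -0.0002519631889427101, 3.93473203162716e-05)

## wavelet (high-pass) filter by the QMF relation g1[m] = (-1)^m g[L-1-m]
.db9Wavelet <- function() {
  g <- .DB9_SCALING
  L <- length(g)
  (-1)^(seq_len(L) - 1) * rev(g)
}

## one periodised analysis step: x (even length n >= L) -> list(cA, cD)
.dwtStep <- function(x) {
  g <- .DB9_SCALING; g1 <- .db9Wavelet()
  n <- length(x); L <- length(g); half <- n / 2L
  cA <- numeric(half); cD <- numeric(half)
  for (m in seq_len(L)) {
    idx <- ((2 * (seq_len(half) - 1) + (m - 1)) %% n) + 1
    cA <- cA + g[m] * x[idx]
    cD <- cD + g1[m] * x[idx]
  }
  list(cA = cA, cD = cD)
}

## inverse of .dwtStep (transpose of the orthonormal analysis operator)
.idwtStep <- function(cA, cD) {
  g <- .DB9_SCALING; g1 <- .db9Wavelet()
  half <- length(cA); n <- 2L * half; L <- length(g)
  x <- numeric(n)
  for (m in seq_len(L)) {
    idx <- ((2 * (seq_len(half) - 1) + (m - 1)) %% n) + 1
    contrib <- g[m] * cA + g1[m] * cD
    ## scatter-add with possible repeated indices (n < 2L wraps)
    tt <- tapply(contrib, idx, sum)
    x[as.integer(names(tt))] <- x[as.integer(names(tt))] + as.numeric(tt)
  }
  x
}

## deepest feasible decomposition level for a signal of length n: each
## analysis step needs an even input no shorter than the filter
.maxWaveletLevel <- function(n) {
  L <- length(.DB9_SCALING)
  J <- 0L
  while (n >= L && n %% 2 == 0) { J <- J + 1L; n <- n / 2L }
  J
}

## multi-level periodised DWT after reflection-padding to a multiple of
## 2^J; returns coefficients plus the padding bookkeeping
.dwtForward <- function(x, J) {
  n0 <- length(x)
  mult <- 2^J
  nPad <- ceiling(n0 / mult) * mult
  if (nPad > n0) {
    extra <- nPad - n0
    pad <- rev(x)[seq_len(min(extra, n0))]
    while (length(pad) < extra) pad <- c(pad, rev(pad))[seq_len(extra)]
    x <- c(x, pad)
  }
  feas <- .maxWaveletLevel(length(x))
  if (J > feas)
    stop("signal too short for J = ", J,
         " decomposition levels; maximum feasible J is ", feas)
  details <- vector("list", J)
  cA <- x
  for (j in seq_len(J)) {
    st <- .dwtStep(cA)
    details[[j]] <- st$cD          # level 1 = finest
    cA <- st$cA
  }
  list(cA = cA, details = details, n = n0, nPad = nPad)
}

.dwtInverse <- function(dec) {
  cA <- dec$cA
  for (j in rev(seq_along(dec$details)))
    cA <- .idwtStep(cA, dec$details[[j]])
  cA[seq_len(dec$n)]
}

#' Semi-soft wavelet coefficient shrinkage
#'
#' The two-cutoff shrinkage rule applied to detail coefficients:
#' coefficients with \eqn{|d| \le \lambda_{low}} are zeroed; for
#' \eqn{\lambda_{low} < |d| < \lambda_{high}} the output is
#' \eqn{\lambda_{high} (|d| - \lambda_{low}) / (\lambda_{high} -
#' \lambda_{low}) \cdot sgn(d)}; for \eqn{|d| \ge \lambda_{high}} it is
#' \eqn{sgn(d) (|d| - \lambda_{low})}. As printed this rule is
#' discontinuous at \eqn{|d| = \lambda_{high}} (jump of size
#' \eqn{\lambda_{low}}); \code{continuous = TRUE} switches the top branch
#' to the conventional identity \eqn{d}, restoring continuity.
#'
#' @param d numeric coefficient(s)
#' @param lambdaLow,lambdaHigh cutoffs, \code{lambdaHigh > lambdaLow >= 0}
#' @param continuous use the continuous variant of the top branch
#' @return shrunk coefficient(s)
#' @examples
#' semiSoftThreshold(c(0.5, 2, -5), 1, 3)   # 0, 1.5, -4
#' @export
semiSoftThreshold <- function(d, lambdaLow, lambdaHigh,
                              continuous = FALSE) {
  .stopIfNot(lambdaLow >= 0, "lambdaLow must be >= 0")
  .stopIfNot(lambdaHigh > lambdaLow || (lambdaHigh == 0 && lambdaLow == 0),
             "lambdaHigh must exceed lambdaLow")
  if (lambdaHigh == 0) return(d)          # zero-threshold limit: identity
  a <- abs(d); s <- sign(d)
  out <- numeric(length(d))
  top <- a >= lambdaHigh
  mid <- a > lambdaLow & a < lambdaHigh
  out[top] <- if (continuous) d[top] else s[top] * (a[top] - lambdaLow)
  out[mid] <- lambdaHigh * (a[mid] - lambdaLow) /
    (lambdaHigh - lambdaLow) * s[mid]
  out
}

#' Multi-scale wavelet denoising with semi-soft shrinkage
#'
#' Decomposes the signal over \code{J} scales of the periodised
#' Daubechies-9 DWT, applies \code{\link{semiSoftThreshold}} to the detail
#' coefficients only (the coarse approximation is untouched) and
#' reconstructs. With \code{rule = "universal"} the cutoffs are derived
#' from the finest detail scale: \eqn{\hat\sigma} = MAD/0.6745,
#' \eqn{\lambda_{high} = \hat\sigma\sqrt{2\log N}},
#' \eqn{\lambda_{low} = \lambda_{high}/2}.
#'
#' @param x numeric signal
#' @param params a \linkS4class{WaveletParams}
#' @param continuous passed to \code{\link{semiSoftThreshold}}
#' @return denoised signal, same length as \code{x}
#' @export
denoiseWavelet <- function(x, params = waveletParams(),
                           continuous = FALSE) {
  stopifnot(is(params, "WaveletParams"))
  validObject(params)
  .stopIfNot(length(x) >= 2^params@J,
             "signal length ", length(x), " is shorter than 2^J; ",
             "maximum feasible J is ", floor(log2(max(length(x), 1))))
  dec <- .dwtForward(x, params@J)
  if (params@rule == "universal") {
    sigma <- mad(dec$details[[1]], center = 0)   # MAD / 0.6745 scaling
    lu <- sigma * sqrt(2 * log(dec$nPad))
    lHigh <- lu; lLow <- lu / 2
  } else {
    lHigh <- params@lambdaHigh; lLow <- params@lambdaLow
  }
  ## threshold details at scales j0..J only (finer scales than j0 are
  ## still details here; j0 indexes the coarsest retained approximation)
  dec$details <- lapply(dec$details, semiSoftThreshold,
                        lambdaLow = lLow, lambdaHigh = lHigh,
                        continuous = continuous)
  .dwtInverse(dec)
}

#' Signal-to-noise ratio against a known clean component
#'
#' \eqn{SNR = 10 \log_{10}(\sum clean^2 / \sum (x - clean)^2)} in dB; the
#' oracle metric used to score denoising on synthetic signals.
#'
#' @param x observed (noisy or denoised) signal
#' @param clean known clean component
#' @return SNR in dB
#' @export
snrDb <- function(x, clean) {
  10 * log10(sum(clean^2) / sum((x - clean)^2))
}
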