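## Dynamic time warping alignment.
##
## The cumulative-cost recursion D(i,j) = C(i,j) + min(D(i-1,j),
## D(i,j-1), D(i-1,j-1)) with D(1,1) = C(1,1) and first row/column
## accumulating along their only feasible direction; the optimal monotone
## path is recovered by backtracking. Implemented directly (no DTW
## package ships with this R installation) and checked in the tests
## against brute-force enumeration of all monotone paths.

#' Align two sequences by dynamic time warping
#'
#' @param reference numeric vector or matrix (rows = time) -- the
#'   reference sequence (length M)
#' @param query numeric vector or matrix -- the sequence to align
#'   (length N)
#' @param cost local cost: \code{"squared"} (squared Euclidean, default),
#'   \code{"abs"} (absolute difference / L1), or a function
#'   \code{f(xi, yj)} of two observations
#' @param band optional Sakoe-Chiba band radius (samples); \code{NULL}
#'   disables the constraint. The pipeline uses
#'   \code{0.25 * max(M, N)}; oracle tests disable it.
#' @return a \linkS4class{DtwAlignment}
#' @examples
#' a <- alignDtw(c(1, 2, 3), c(1, 3), cost = "abs")
#' totalCost(a)   # 1
#' @export
alignDtw <- function(reference, query, cost = "squared", band = NULL) {
  X <- if (is.matrix(reference)) reference else matrix(reference, ncol = 1)
  Y <- if (is.matrix(query)) query else matrix(query, ncol = 1)
  M <- nrow(X); N <- nrow(Y)
  .stopIfNot(M >= 1 && N >= 1, "both sequences must be non-empty")
  C <- if (is.function(cost)) {
    outerC <- matrix(0, M, N)
    for (i in seq_len(M)) for (j in seq_len(N))
      outerC[i, j] <- cost(X[i, ], Y[j, ])
    outerC
  } else if (cost == "squared") {
    outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  } else if (cost == "abs") {
    D <- matrix(0, M, N)
    for (k in seq_len(ncol(X)))
      D <- D + abs(outer(X[, k], Y[, k], "-"))
    D
  } else stop("unknown cost '", cost, "'")
  C <- pmax(C, 0)                       # guard tiny negatives (squared)

  inBand <- function(i, j)
    is.null(band) || abs(i * N / M - j) <= band + 1e-9
  D <- matrix(Inf, M, N)
  D[1, 1] <- C[1, 1]
  for (j in seq_len(N)[-1])
    if (inBand(1, j)) D[1, j] <- D[1, j - 1] + C[1, j]
  for (i in seq_len(M)[-1]) {
    if (inBand(i, 1)) D[i, 1] <- D[i - 1, 1] + C[i, 1]
    for (j in seq_len(N)[-1]) {
      if (!inBand(i, j)) next
      D[i, j] <- C[i, j] +
        min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
    }
  }

  ## backtrack, preferring the diagonal on ties
  path <- matrix(c(M, N), 1, 2)
  i <- M; j <- N
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1 }
    else if (j == 1) { i <- i - 1 }
    else {
      cand <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      k <- which.min(cand)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) { i <- i - 1 }
      else { j <- j - 1 }
    }
    path <- rbind(c(i, j), path)
  }
  storage.mode(path) <- "integer"
  colnames(path) <- c("reference", "query")
  new("DtwAlignment", costMatrix = C, cumulativeCost = D,
      path = path, totalCost = D[M, N])
}

#' Median warping offset of an alignment
#'
#' The median of (query index - reference index) along the optimal path:
#' an estimate (in samples) of a constant lag between the channels. A
#' query that is the reference delayed by k samples gives +k.
#'
#' @param alignment a \linkS4class{DtwAlignment}
#' @return lag in samples (positive: query lags the reference)
#' @export
dtwLag <- function(alignment) {
  p <- alignmentPath(alignment)
  median(p[, 2] - p[, 1])
}

#' Align physiological channels to the acceleration reference
#'
#' Warps a lagging channel onto the timeline of the acceleration
#' reference: both series are z-scored, aligned by
#' \code{\link{alignDtw}}, and the query is re-indexed by averaging the
#' query samples matched to each reference index.
#'
#' @param reference numeric reference series (e.g. acceleration magnitude)
#' @param query numeric series to align (e.g. heart rate)
#' @param band Sakoe-Chiba radius; default \code{0.25 * max(M, N)}
#' @return list(aligned = warped query on the reference timeline,
#'   alignment = \linkS4class{DtwAlignment}, lag = estimated lag in
#'   samples)
#' @export
alignChannel <- function(reference, query,
                         band = 0.25 * max(length(reference),
                                           length(query))) {
  zs <- function(x) (x - mean(x)) / max(sd(x), 1e-12)
  al <- alignDtw(zs(reference), zs(query), cost = "squared", band = band)
  p <- alignmentPath(al)
  aligned <- as.numeric(tapply(query[p[, 2]], p[, 1], mean))
  list(aligned = aligned, alignment = al, lag = dtwLag(al))
}
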