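## Recurrent-network gap imputation.
##
## A sliding window of the tau preceding samples is pushed through a
## single-layer recurrence h_t = tanh(W_h h_{t-1} + W_x x_t + b) and a
## linear readout xhat = W_o h + b_o predicts the next sample; the model
## is trained by backpropagation through time (Adam) on mean squared
## error over the observed regions. Gaps are filled by rolling the
## predictor forward; for interior gaps the same model is also rolled
## backward over the time-reversed series, and forward roll, backward
## roll and linear bridge are combined by least-squares weights
## calibrated on synthetic gaps cut from the observed stretches
## (documented in the methods vignette).

#' ImputerModel: recurrent gap-filling model
#'
#' @slot tau input window length, samples
#' @slot hidden hidden-state dimension
#' @slot params named list (Wh, Wx, b, Wo, bo)
#' @slot center,scale normalisation of the training series
#' @slot loss final training MSE (normalised units)
#' @exportClass ImputerModel
setClass("ImputerModel", representation(
  tau = "numeric", hidden = "numeric", params = "list",
  center = "numeric", scale = "numeric", loss = "numeric"))

setValidity("ImputerModel", function(object) {
  p <- object@params
  need <- c("Wh", "Wx", "b", "Wo", "bo")
  if (!all(need %in% names(p)))
    return(sprintf("params needs %s", paste(need, collapse = ", ")))
  h <- object@hidden
  if (!all(dim(p$Wh) == c(h, h))) return("Wh must be hidden x hidden")
  if (length(p$Wx) != h || length(p$b) != h || length(p$Wo) != h)
    return("Wx, b, Wo must have length hidden")
  if (!is.finite(object@loss)) return("training loss must be finite")
  TRUE
})

## batched forward pass: X tau x M -> list(H = list of hidden states, y)
.rnnForward <- function(p, X) {
  tau <- nrow(X); M <- ncol(X); h <- length(p$b)
  H <- vector("list", tau)
  Ht <- matrix(0, h, M)
  for (t in seq_len(tau)) {
    Ht <- tanh(p$Wh %*% Ht + p$Wx %*% X[t, , drop = FALSE] + p$b)
    H[[t]] <- Ht
  }
  y <- as.numeric(crossprod(p$Wo, Ht) + p$bo)
  list(H = H, y = y)
}

.rnnGrad <- function(p, X, target) {
  fw <- .rnnForward(p, X)
  tau <- nrow(X); M <- ncol(X)
  dy <- matrix(2 * (fw$y - target) / M, 1, M)
  g <- list(Wh = 0 * p$Wh, Wx = 0 * p$Wx, b = 0 * p$b,
            Wo = as.numeric(fw$H[[tau]] %*% t(dy)), bo = sum(dy))
  dH <- p$Wo %*% dy
  for (t in rev(seq_len(tau))) {
    dZ <- dH * (1 - fw$H[[t]]^2)
    Hprev <- if (t > 1) fw$H[[t - 1]] else matrix(0, length(p$b), M)
    g$Wh <- g$Wh + dZ %*% t(Hprev)
    g$Wx <- g$Wx + dZ %*% t(X[t, , drop = FALSE])
    g$b <- g$b + rowSums(dZ)
    dH <- crossprod(p$Wh, dZ)
  }
  list(grad = g, loss = mean((fw$y - target)^2))
}

#' Train the recurrent gap imputer
#'
#' Trains on all length-\code{tau} windows of consecutive observed
#' samples (subsampled to \code{max_windows}), minimising the mean
#' squared one-step-ahead prediction error with Adam. The series is
#' z-normalised internally.
#'
#' @param x numeric series; \code{NA} marks missing samples (excluded
#'   from training)
#' @param tau input window length, samples (default 10)
#' @param hidden hidden dimension (default 16)
#' @param epochs full-batch Adam steps
#' @param lr Adam learning rate
#' @param seed integer seed for weight initialisation
#' @param max_windows cap on training windows
#' @return an \linkS4class{ImputerModel}
#' @export
trainImputer <- function(x, tau = 10, hidden = 16, epochs = 150,
                         lr = 0.02, seed = 1, max_windows = 500) {
  obs <- !is.na(x)
  ctr <- mean(x[obs]); scl <- max(sd(x[obs]), 1e-12)
  z <- (x - ctr) / scl
  ## candidate windows: tau observed samples followed by an observed target
  ok <- which(vapply(seq_len(length(z) - tau), function(s)
    all(obs[s:(s + tau)]), logical(1)))
  .stopIfNot(length(ok) >= 5,
             "not enough contiguous observed data to train the imputer")
  .withSeed(seed, {
    if (length(ok) > max_windows) ok <- sort(sample(ok, max_windows))
    X <- vapply(ok, function(s) z[s:(s + tau - 1)], numeric(tau))
    target <- z[ok + tau]
    p <- list(Wh = matrix(rnorm(hidden^2, 0, 0.3 / sqrt(hidden)),
                          hidden, hidden),
              Wx = matrix(rnorm(hidden, 0, 0.5), hidden, 1),
              b = rep(0, hidden),
              Wo = rnorm(hidden, 0, 0.3), bo = 0)
    m <- v <- lapply(p, function(w) 0 * w)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    loss <- Inf
    for (it in seq_len(epochs)) {
      gr <- .rnnGrad(p, X, target)
      loss <- gr$loss
      for (nm in names(p)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr$grad[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr$grad[[nm]]^2
        mh <- m[[nm]] / (1 - b1^it); vh <- v[[nm]] / (1 - b2^it)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    p$Wo <- as.numeric(p$Wo); p$Wx <- matrix(as.numeric(p$Wx), hidden, 1)
    new("ImputerModel", tau = tau, hidden = hidden, params = p,
        center = ctr, scale = scl, loss = loss)
  })
}

## one-step prediction from the tau samples preceding the target;
## history is a vector (one series) or a tau x M matrix (batch)
.predictNext <- function(model, history) {
  Z <- if (is.matrix(history)) history
  else matrix(history[(length(history) - model@tau + 1):length(history)],
              ncol = 1)
  Z <- (Z - model@center) / model@scale
  p <- model@params
  y <- .rnnForward(list(Wh = p$Wh, Wx = p$Wx, b = p$b,
                        Wo = matrix(p$Wo, ncol = 1), bo = p$bo), Z)$y
  y * model@scale + model@center
}

## roll the predictor forward through a gap of length L given the tau
## preceding values; returns the L predictions
.rollForward <- function(model, histVec, L) {
  out <- numeric(L)
  for (k in seq_len(L)) {
    out[k] <- .predictNext(model, histVec)
    histVec <- c(histVec[-1], out[k])
  }
  out
}

## horizon bin for the combiner: distance to the nearer gap edge
.horizonBin <- function(h) findInterval(h, c(1, 2, 3, 4, 7, 11, 16))

## Calibrate the gap combiner: cut synthetic gaps (lengths resampled
## from the real gap lengths) out of fully observed stretches, compute
## the forward roll, backward roll and linear bridge at every position,
## and fit least-squares weights per horizon bin. Because the linear
## bridge is in the span, the calibrated combination cannot be
## systematically worse than linear interpolation.
.calibrateCombiner <- function(model, x, gapLens, nGaps = 150,
                               seed = 1) {
  tau <- model@tau
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  feats <- list(); truths <- list(); bins <- list()
  .withSeed(seed, {
    obs <- which(runs$values & runs$lengths >= 2 * tau + 12)
    if (!length(obs)) return(NULL)
    for (g in seq_len(nGaps)) {
      L <- sample(gapLens, 1)
      r <- obs[sample.int(length(obs), 1)]
      lo <- starts[r] + tau; hi <- ends[r] - tau - L
      if (hi <= lo) next
      s <- sample(lo:hi, 1); e <- s + L - 1L
      fwd <- .rollForward(model, x[(s - tau):(s - 1)], L)
      bwd <- rev(.rollForward(model, rev(x[(e + 1):(e + tau)]), L))
      lin <- seq(x[s - 1], x[e + 1], length.out = L + 2)[2:(L + 1)]
      h <- pmin(seq_len(L), L + 1 - seq_len(L))
      feats[[length(feats) + 1L]] <- cbind(1, fwd, bwd, lin)
      truths[[length(truths) + 1L]] <- x[s:e]
      bins[[length(bins) + 1L]] <- .horizonBin(h)
    }
  })
  if (!length(feats)) return(NULL)
  FF <- do.call(rbind, feats)
  yy <- unlist(truths)
  bb <- unlist(bins)
  coefs <- matrix(rep(c(0, 0, 0, 1), each = 7), 7, 4)  # default: linear
  for (b in sort(unique(bb))) {
    sel <- bb == b
    if (sum(sel) < 12) next
    Xb <- FF[sel, , drop = FALSE]
    ## ridge-stabilised least squares
    G <- crossprod(Xb) + 1e-4 * sum(sel) * diag(4)
    coefs[b, ] <- as.numeric(solve(G, crossprod(Xb, yy[sel])))
  }
  coefs
}

#' Fill gaps in a series with the recurrent imputer
#'
#' Rolls the one-step predictor forward through each gap from the
#' preceding \code{tau} samples. With \code{bidirectional = TRUE}
#' (default) interior gaps are additionally predicted backward from the
#' following samples (the same model applied to the reversed series),
#' and the forward roll, backward roll and linear bridge are combined
#' by a stacked least-squares combiner calibrated on synthetic gaps cut
#' from the observed stretches (weights per distance-to-nearer-edge
#' bin). Gaps without \code{tau} samples of history (at the series
#' start, or when the model cannot be applied) fall back to linear
#' interpolation, and a message notes the fallback. Non-missing samples
#' are returned untouched.
#'
#' @param x numeric series with \code{NA} gaps
#' @param model an \linkS4class{ImputerModel}; \code{NULL} trains one on
#'   the observed part of \code{x}
#' @param bidirectional blend forward and backward predictions
#' @param ... passed to \code{\link{trainImputer}} when \code{model} is
#'   \code{NULL}
#' @return the filled series
#' @export
imputeSeries <- function(x, model = NULL, bidirectional = TRUE, ...) {
  if (!anyNA(x)) return(x)
  if (is.null(model)) model <- trainImputer(x, ...)
  tau <- model@tau
  n <- length(x)
  isna <- is.na(x)
  runs <- rle(isna)
  combiner <- NULL
  if (bidirectional) {
    gapLens <- runs$lengths[runs$values]
    combiner <- .calibrateCombiner(model, x, gapLens)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- x
  obsIdx <- which(!isna)
  linFill <- function(s, e) {
    lo <- if (s > 1) out[s - 1] else x[obsIdx[1]]
    hi <- if (e < n) out[e + 1] else x[obsIdx[length(obsIdx)]]
    seq(lo, hi, length.out = e - s + 3)[2:(e - s + 2)]
  }
  for (r in which(runs$values)) {
    s <- starts[r]; e <- ends[r]; L <- e - s + 1L
    if (s <= tau) {
      message("gap at series start (no history): linear fallback")
      out[s:e] <- linFill(s, e)
      next
    }
    fwd <- .rollForward(model, out[(s - tau):(s - 1)], L)
    hasFuture <- e + tau <= n && !anyNA(x[(e + 1):(e + tau)])
    if (bidirectional && hasFuture && !is.null(combiner) && s > 1 &&
        e < n) {
      bwd <- rev(.rollForward(model, rev(x[(e + 1):(e + tau)]), L))
      lin <- linFill(s, e)
      h <- pmin(seq_len(L), L + 1 - seq_len(L))
      cf <- combiner[.horizonBin(h), , drop = FALSE]
      out[s:e] <- cf[, 1] + cf[, 2] * fwd + cf[, 3] * bwd +
        cf[, 4] * lin
    } else {
      out[s:e] <- fwd
    }
  }
  out
}

#' Impute all missing samples of a stream
#'
#' Applies \code{\link{imputeSeries}} channel-by-channel (one model per
#' channel, trained on that channel's observed samples), clears the
#' missing mask and records the imputed sample count in
#' \code{metadata()$imputation}.
#'
#' @param stream a \linkS4class{SensorStream}
#' @param bidirectional blend forward and backward predictions
#' @param tau,hidden,epochs,seed training settings per channel; the
#'   default window is 1 s of samples at the stream rate
#' @return the imputed \linkS4class{SensorStream}
#' @export
imputeStream <- function(stream, bidirectional = TRUE,
                         tau = NULL, hidden = 12, epochs = 80,
                         seed = 1) {
  stopifnot(is(stream, "SensorStream"))
  mis <- missingMask(stream)
  if (!any(mis)) return(stream)
  sig <- signalMatrix(stream)
  if (is.null(tau)) tau <- max(4L, min(round(nominalRate(stream)), 20L))
  for (r in seq_len(nrow(sig))) {
    if (!any(mis[r, ])) next
    sig[r, ] <- imputeSeries(sig[r, ], bidirectional = bidirectional,
                             tau = tau, hidden = hidden,
                             epochs = epochs,
                             seed = .deriveSeed(seed, rownames(sig)[r]))
  }
  out <- stream
  assay(out, "signal") <- sig
  assay(out, "missing") <- matrix(FALSE, nrow(sig), ncol(sig),
                                  dimnames = dimnames(mis))
  metadata(out)$imputation <- list(n_imputed = sum(mis), tau = tau)
  out
}

#' Linear-interpolation gap filling (baseline)
#'
#' The reference method the recurrent imputer is scored against.
#'
#' @param x numeric series with \code{NA} gaps
#' @return the linearly interpolated series
#' @export
imputeLinear <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}
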