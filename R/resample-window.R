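## Resampling, window segmentation and Z-score standardisation.

#' Resample a stream to a uniform reference rate
#'
#' Linearly interpolates every channel onto a uniform grid at
#' \code{target_hz} spanning the stream's time range, starting at the
#' first timestamp. Values bracketed by a missing source sample stay
#' masked (and \code{NA}) in the output; interpolation itself uses the
#' non-missing samples only.
#'
#' @param stream a \linkS4class{SensorStream}
#' @param target_hz target rate, Hz (default 100, the pipeline reference)
#' @return a uniform-rate \linkS4class{SensorStream}
#' @export
resampleStream <- function(stream, target_hz = 100) {
  stopifnot(is(stream, "SensorStream"))
  tt <- streamTimes(stream)
  .stopIfNot(length(tt) >= 2, "need >= 2 samples to resample")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_hz)
  sig <- signalMatrix(stream)
  mis <- missingMask(stream)
  nsOut <- matrix(0, nrow(sig), length(grid),
                  dimnames = list(rownames(sig), NULL))
  misOut <- matrix(FALSE, nrow(sig), length(grid))
  ## bracketing source-sample indices of each grid point
  left <- findInterval(grid, tt, rightmost.closed = FALSE)
  left <- .clamp(left, 1L, length(tt))
  right <- .clamp(left + (grid > tt[left]), 1L, length(tt))
  for (r in seq_len(nrow(sig))) {
    ok <- !mis[r, ]
    .stopIfNot(sum(ok) >= 2, "channel '", rownames(sig)[r],
               "' has fewer than 2 non-missing samples")
    nsOut[r, ] <- approx(tt[ok], sig[r, ok], xout = grid,
                         rule = 2)$y
    misOut[r, ] <- mis[r, left] | mis[r, right]
    nsOut[r, misOut[r, ]] <- NA_real_
  }
  lab <- sampleLabels(stream)
  labOut <- if (is.null(lab)) NULL else lab[right]
  intn <- colData(stream)$intensity
  intOut <- if (is.null(intn)) NULL else intn[right]
  md <- metadata(stream)
  md$nominal_rate <- NULL
  SensorStream(nsOut, time = grid, placement = placements(stream),
               unit = as.character(rowData(stream)$unit),
               nominal_rate = target_hz, label = labOut,
               intensity = intOut, missing = misOut, metadata = md)
}

#' Segment a uniform-rate stream into overlapping windows
#'
#' Cuts fixed-length windows (default 2 s with 50\% overlap) from a
#' uniform-rate stream, producing the T x D x N feature-window array fed
#' to the classifier. Each window is labelled by per-sample majority (ties
#' go to the label occurring earlier in the window); a trailing partial
#' window is dropped. The stream must contain no missing samples (impute
#' first).
#'
#' @param stream a uniform-rate \linkS4class{SensorStream}
#' @param window_s window length, seconds
#' @param overlap fractional overlap in [0, 1)
#' @param subject subject id attached to every window
#' @return a \linkS4class{FeatureWindows} (possibly with zero windows,
#'   with a warning, if the stream is shorter than one window)
#' @export
segmentWindows <- function(stream, window_s = 2.0, overlap = 0.5,
                           subject = "s1") {
  stopifnot(is(stream, "SensorStream"))
  .stopIfNot(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  tt <- streamTimes(stream)
  dtv <- diff(tt)
  .stopIfNot(max(abs(dtv - dtv[1])) < 1e-6,
             "stream must be uniform-rate; resample first")
  .stopIfNot(!any(missingMask(stream)),
             "stream contains missing samples; impute before windowing")
  rate <- round(1 / dtv[1])
  wlen <- round(window_s * rate)
  stride <- max(1L, round((1 - overlap) * wlen))
  sig <- t(signalMatrix(stream))            # samples x channels
  N <- nrow(sig)
  if (N < wlen) {
    warning("stream shorter than one window; returning zero windows")
    starts <- integer(0)
  } else {
    starts <- seq(1L, N - wlen + 1L, by = stride)
  }
  lab <- sampleLabels(stream)
  arr <- array(0, dim = c(wlen, ncol(sig), length(starts)))
  labs <- character(length(starts)); st <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + wlen - 1L)
    arr[, , i] <- sig[idx, ]
    st[i] <- tt[starts[i]]
    labs[i] <- if (is.null(lab)) NA_character_ else {
      cnt <- table(factor(lab[idx], levels = unique(lab[idx])))
      names(cnt)[which.max(cnt)]     # which.max: first max = earlier label
    }
  }
  new("FeatureWindows", windows = arr,
      labels = factor(labs), subject = rep(subject, length(starts)),
      startTime = st, channels = channelNames(stream), rate = rate,
      normCenter = numeric(0), normScale = numeric(0))
}

#' Combine FeatureWindows objects
#'
#' @param ... \linkS4class{FeatureWindows} with identical T, D and rate
#' @return one concatenated \linkS4class{FeatureWindows}
#' @export
bindWindows <- function(...) {
  fws <- list(...)
  if (length(fws) == 1L && is.list(fws[[1]]) &&
      !is(fws[[1]], "FeatureWindows")) fws <- fws[[1]]
  d1 <- dim(fws[[1]]@windows)[1:2]
  arr <- array(0, dim = c(d1, sum(vapply(fws, nWindows, 0))))
  labs <- character(0); subj <- character(0); st <- numeric(0)
  off <- 0L
  for (fw in fws) {
    n <- nWindows(fw)
    if (n) arr[, , off + seq_len(n)] <- fw@windows
    off <- off + n
    labs <- c(labs, as.character(fw@labels))
    subj <- c(subj, fw@subject)
    st <- c(st, fw@startTime)
  }
  new("FeatureWindows", windows = arr, labels = factor(labs),
      subject = subj, startTime = st, channels = fws[[1]]@channels,
      rate = fws[[1]]@rate, normCenter = numeric(0),
      normScale = numeric(0))
}

#' Subset windows
#'
#' @param fw a \linkS4class{FeatureWindows}
#' @param idx integer or logical index over windows
#' @return the subset \linkS4class{FeatureWindows}
#' @export
subsetWindows <- function(fw, idx) {
  if (is.logical(idx)) idx <- which(idx)
  new("FeatureWindows", windows = fw@windows[, , idx, drop = FALSE],
      labels = factor(as.character(fw@labels)[idx],
                      levels = levels(fw@labels)),
      subject = fw@subject[idx], startTime = fw@startTime[idx],
      channels = fw@channels, rate = fw@rate,
      normCenter = fw@normCenter, normScale = fw@normScale)
}

#' Fit Z-score statistics on the training split and apply to all splits
#'
#' Per-feature (channel) mean and population standard deviation are
#' computed on the training windows only -- pooled over time steps and
#' windows -- then applied to every split, so validation/test are
#' transformed with training statistics and never their own.
#' Zero-variance features are kept with scale 1 (a message notes them).
#'
#' @param train training \linkS4class{FeatureWindows}
#' @param ... further splits to transform with the training statistics
#' @return list of transformed splits (named \code{train} plus the names
#'   of \code{...})
#' @export
zscoreFitApply <- function(train, ...) {
  stopifnot(is(train, "FeatureWindows"))
  w <- train@windows
  D <- dim(w)[2]
  flat <- matrix(aperm(w, c(1, 3, 2)), ncol = D)   # (T*N) x D
  ctr <- colMeans(flat)
  n <- nrow(flat)
  scl <- sqrt(colMeans(sweep(flat, 2, ctr)^2))     # population sd
  if (any(scl == 0)) {
    message("zero-variance feature(s) kept with scale 1: ",
            paste(train@channels[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  applyTo <- function(fw) {
    wz <- sweep(sweep(fw@windows, 2, ctr), 2, scl, "/")
    new("FeatureWindows", windows = wz, labels = fw@labels,
        subject = fw@subject, startTime = fw@startTime,
        channels = fw@channels, rate = fw@rate,
        normCenter = ctr, normScale = scl)
  }
  out <- c(list(train = applyTo(train)),
           lapply(list(...), applyTo))
  out
}
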