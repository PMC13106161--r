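## Synthetic multimodal stream generation.
##
## Signal model: each action has a characteristic dominant frequency and
## amplitude; accelerometer channels are sinusoid + Gaussian noise with
## placement-specific phase and gain, gravity on the z axes. Heart rate
## follows a first-order response toward an action/intensity-dependent
## target; GSR and skin temperature drift slowly with exertion. The model
## is deliberately simple so that tests have closed-form oracles
## (periodogram argmax recovers the configured frequency).

.ACTION_SIG <- data.frame(
  label = c("running", "jumping", "squat", "stretching", "bending",
            "walking", "rest"),
  freq  = c(2.8, 2.2, 0.6, 0.25, 0.45, 1.8, 0),      # Hz, dominant
  amp   = c(8.0, 10.0, 4.0, 1.5, 3.0, 3.5, 0),       # m/s^2 at intensity 1
  hrFrac = c(0.90, 0.85, 0.65, 0.30, 0.45, 0.50, 0), # HR-reserve fraction
  stringsAsFactors = FALSE)

.PLACEMENTS <- c("wrist", "chest", "ankle")
.PLACE_GAIN <- c(wrist = 1.0, chest = 0.45, ankle = 1.25)
.GRAVITY <- 9.81

.channelLayout <- function() {
  acc <- as.vector(t(outer(.PLACEMENTS, c("ax", "ay", "az"), paste,
                           sep = "_")))
  data.frame(
    channel = c(acc, "heart_rate", "gsr", "skin_temp"),
    placement = c(rep(.PLACEMENTS, each = 3), rep("body", 3)),
    unit = c(rep("m/s^2", 9), "bpm", "uS", "degC"),
    stringsAsFactors = FALSE)
}

#' Dynamic frequency-modulation sampling-rate policy
#'
#' Maps exercise intensity to the sensor sampling rate: a monotone
#' nondecreasing step function over the supported rate levels
#' \{50, 100, 150, 200\} Hz. Low-intensity activity is sampled at 50 Hz to
#' conserve power; high-intensity activity restores the full 200 Hz.
#'
#' @param intensity numeric in [0, 1] (vectorised)
#' @return sampling rate(s) in Hz
#' @examples
#' sampleRatePolicy(c(0.05, 0.5, 0.95))
#' @export
sampleRatePolicy <- function(intensity) {
  .stopIfNot(all(is.finite(intensity)) &&
               all(intensity >= 0 & intensity <= 1),
             "intensity must lie in [0, 1]")
  levels <- c(50, 100, 150, 200)
  idx <- findInterval(intensity, c(0, 0.25, 0.5, 0.75))
  levels[idx]
}

.hrTarget <- function(subject, label, intensity) {
  hrmax <- 220 - subject@age
  frac <- .ACTION_SIG$hrFrac[match(label, .ACTION_SIG$label)]
  subject@restingHr + frac * intensity * (hrmax - subject@restingHr)
}

#' Simulate a labelled multimodal sensor session
#'
#' Generates the 12-channel stream (9 accelerometer axes over wrist,
#' chest and ankle, plus heart rate, GSR and skin temperature) for an
#' \linkS4class{ActionScript} performed by a \linkS4class{VirtualSubject}.
#' Accelerometer channels follow the per-action sinusoid-plus-noise
#' signature; heart rate relaxes first-order (time constant
#' \code{hr_tau} s) toward an action/intensity-dependent target bounded by
#' 220 - age. Per-segment sampling rates follow
#' \code{\link{sampleRatePolicy}} unless \code{rate} is given. Output is
#' bit-identical for identical inputs and seed.
#'
#' @param script an \linkS4class{ActionScript}
#' @param subject a \linkS4class{VirtualSubject}
#' @param seed integer seed
#' @param rate optional fixed sampling rate in Hz; default \code{NULL}
#'   applies the dynamic rate policy per segment
#' @param noise_sd accelerometer noise standard deviation, m/s^2
#' @param hr_tau heart-rate response time constant, seconds
#' @return a \linkS4class{SensorStream} with per-sample \code{label} and
#'   \code{intensity} columns in \code{colData}
#' @examples
#' sc <- actionScript(c("running", "rest"), c(4, 4), c(0.9, 0))
#' st <- simulateSession(sc, virtualSubject(), seed = 1)
#' st
#' @export
simulateSession <- function(script, subject, seed, rate = NULL,
                            noise_sd = 0.3, hr_tau = 30) {
  stopifnot(is(script, "ActionScript"), is(subject, "VirtualSubject"))
  validObject(script)
  seg <- scriptSegments(script)
  .withSeed(seed, {
    lay <- .channelLayout()
    tAll <- numeric(0); labAll <- character(0); intAll <- numeric(0)
    segRate <- numeric(0)
    t0 <- 0
    for (i in seq_len(nrow(seg))) {
      r <- if (is.null(rate)) sampleRatePolicy(seg$intensity[i]) else rate
      n <- max(1L, round(seg$duration[i] * r))
      tt <- t0 + seq_len(n) / r
      tAll <- c(tAll, tt)
      labAll <- c(labAll, rep(seg$label[i], n))
      intAll <- c(intAll, rep(seg$intensity[i], n))
      segRate <- c(segRate, rep(r, n))
      t0 <- tt[n]
    }
    N <- length(tAll)
    sig <- matrix(0, nrow(lay), N, dimnames = list(lay$channel, NULL))

    rowSel <- function(pl, ax) which(lay$channel == paste(pl, ax, sep = "_"))
    for (pl in .PLACEMENTS) {
      g <- .PLACE_GAIN[[pl]]
      phase <- runif(3, 0, 2 * pi)     # per-axis placement phase
      for (k in 1:3) {
        ax <- c("ax", "ay", "az")[k]
        f <- .ACTION_SIG$freq[match(labAll, .ACTION_SIG$label)]
        a <- .ACTION_SIG$amp[match(labAll, .ACTION_SIG$label)] *
          intAll * g * c(1, 0.8, 0.9)[k]
        base <- if (ax == "az") .GRAVITY else 0
        sig[rowSel(pl, ax), ] <- base +
          a * sin(2 * pi * f * tAll + phase[k]) +
          rnorm(N, 0, noise_sd)
      }
    }

    ## heart rate: exact first-order relaxation between samples
    hr <- numeric(N)
    h <- subject@restingHr
    tPrev <- 0
    hrmax <- 220 - subject@age
    for (j in seq_len(N)) {
      dt <- tAll[j] - tPrev
      tgt <- .hrTarget(subject, labAll[j], intAll[j])
      h <- tgt + (h - tgt) * exp(-dt / hr_tau)
      hr[j] <- h
      tPrev <- tAll[j]
    }
    hr <- .clamp(hr + rnorm(N, 0, 0.8), 40, hrmax)
    sig["heart_rate", ] <- hr

    ## GSR: baseline + exertion-driven drift + noise
    load <- cumsum(c(0, diff(tAll)) * intAll) / 60   # intensity-minutes
    sig["gsr", ] <- 2 + 1.5 * tanh(load / 3) + 0.6 * intAll +
      rnorm(N, 0, 0.05)
    ## skin temperature: slow rise with load
    sig["skin_temp", ] <- 33 + 1.2 * tanh(load / 5) + rnorm(N, 0, 0.02)

    SensorStream(sig, time = tAll, placement = lay$placement,
                 unit = lay$unit, nominal_rate = max(segRate),
                 label = labAll, intensity = intAll,
                 metadata = list(seed = seed, segment_rate = segRate,
                                 subject_age = subject@age))
  })
}

#' Inject a windowed disturbance into a stream
#'
#' Modifies only the samples inside \code{[onset, onset + duration]}.
#' \code{emi} adds wide-band noise bursts to the accelerometer channels;
#' \code{motion_artifact} adds sparse large spikes to the accelerometer
#' channels; \code{temp_drift} ramps \code{skin_temp} linearly by
#' \code{magnitude} across the window; \code{humidity_drift} drifts the
#' GSR channel; \code{composite} applies EMI plus temperature drift (the
#' magnitude is used for both). Deterministic under \code{seed}; the
#' disturbance description is appended to
#' \code{metadata()$interference}.
#'
#' @param stream a \linkS4class{SensorStream}
#' @param spec an \linkS4class{InterferenceSpec}
#' @param seed integer seed
#' @return the disturbed \linkS4class{SensorStream}
#' @export
injectInterference <- function(stream, spec, seed) {
  stopifnot(is(stream, "SensorStream"), is(spec, "InterferenceSpec"))
  validObject(spec)
  tt <- streamTimes(stream)
  t0 <- tt[1]
  .stopIfNot(spec@onset + spec@duration <= tt[length(tt)] - t0 + 1e-9,
             "interference window [", spec@onset, ", ",
             spec@onset + spec@duration, "] exceeds the stream span")
  win <- which(tt - t0 >= spec@onset &
                 tt - t0 <= spec@onset + spec@duration)
  sig <- signalMatrix(stream)
  accRows <- which(placements(stream) != "body")
  .withSeed(seed, {
    nW <- length(win)
    addAcc <- function(noise) {
      for (r in accRows) sig[r, win] <<- sig[r, win] + noise()
    }
    applyKind <- function(kind, mag) {
      if (kind == "emi") {
        addAcc(function() rnorm(nW, 0, mag))
      } else if (kind == "motion_artifact") {
        addAcc(function() {
          sp <- rbinom(nW, 1, 0.05)
          sp * rnorm(nW, 0, 3 * mag)
        })
      } else if (kind == "temp_drift") {
        ramp <- seq(0, mag, length.out = nW)
        sig["skin_temp", win] <<- sig["skin_temp", win] + ramp
      } else if (kind == "humidity_drift") {
        ramp <- seq(0, mag, length.out = nW)
        sig["gsr", win] <<- sig["gsr", win] + ramp
      }
    }
    if (spec@kind == "composite") {
      applyKind("emi", spec@magnitude)
      applyKind("temp_drift", spec@magnitude)
    } else applyKind(spec@kind, spec@magnitude)
    out <- stream
    assay(out, "signal") <- sig
    metadata(out)$interference <- c(
      metadata(out)$interference,
      list(list(kind = spec@kind, magnitude = spec@magnitude,
                onset = spec@onset, duration = spec@duration,
                seed = seed)))
    out
  })
}

#' Drop samples from a stream to emulate discontinuous acquisition
#'
#' Marks a fraction of samples per channel as missing. With
#' \code{mean_gap = 1} drops are independent Bernoulli(\code{rate}) per
#' sample; with \code{mean_gap > 1} drops arrive as contiguous runs with
#' geometric mean length \code{mean_gap} and the same expected overall
#' fraction, emulating transmission drop-outs. Dropped values are replaced
#' by \code{NA} in the signal; the original values are retained in
#' \code{metadata()$truth} as ground truth for imputation scoring.
#'
#' @param stream a \linkS4class{SensorStream}
#' @param rate expected fraction of samples dropped, in [0, 1)
#' @param seed integer seed
#' @param mean_gap expected run length of each drop-out, samples
#' @return the masked \linkS4class{SensorStream}
#' @export
dropSegments <- function(stream, rate, seed, mean_gap = 1) {
  stopifnot(is(stream, "SensorStream"))
  .stopIfNot(is.numeric(rate) && rate >= 0 && rate < 1,
             "rate must lie in [0, 1)")
  sig <- signalMatrix(stream)
  mis <- missingMask(stream)
  .withSeed(seed, {
    N <- ncol(sig)
    for (r in seq_len(nrow(sig))) {
      if (rate == 0) next
      if (mean_gap <= 1) {
        drop <- runif(N) < rate
      } else {
        pExit <- 1 / mean_gap
        pEnter <- rate * pExit / (1 - rate)
        drop <- logical(N)
        state <- runif(1) < rate
        u <- runif(N)
        for (j in seq_len(N)) {
          drop[j] <- state
          state <- if (state) u[j] >= pExit else u[j] < pEnter
        }
      }
      mis[r, ] <- mis[r, ] | drop
    }
    out <- stream
    metadata(out)$truth <- sig
    sig[mis] <- NA_real_
    assay(out, "signal") <- sig
    assay(out, "missing") <- mis
    metadata(out)$drop_rate <- rate
    out
  })
}

#' Advance the virtual-subject physiology by one prescription step
#'
#' A deliberately simple, saturating physiology: heart rate relaxes
#' first-order toward an intensity-dependent target bounded by 220 - age;
#' fatigue accumulates superlinearly with intensity and decays
#' exponentially during rest/recovery; repeated training raises VO2max and
#' endurance with logistic diminishing returns toward fixed ceilings.
#' Within each step the prescribed work/rest structure is honoured: the
#' step is split into work bouts of \code{set_s} seconds separated by the
#' prescription's rest interval.
#'
#' @param subject a \linkS4class{VirtualSubject}
#' @param prescr a \linkS4class{Prescription}
#' @param dt step length, seconds (> 0)
#' @param seed integer seed (physiological noise)
#' @param heartRate current heart rate, bpm; \code{NULL} starts from the
#'   resting value
#' @param set_s work-bout length within the step, seconds
#' @param hr_tau heart-rate time constant, seconds
#' @return list(subject = updated \linkS4class{VirtualSubject},
#'   state = \linkS4class{UserState} observation at step end)
#' @export
stepPhysiology <- function(subject, prescr, dt, seed = NULL,
                           heartRate = NULL, set_s = 60, hr_tau = 30) {
  stopifnot(is(subject, "VirtualSubject"), is(prescr, "Prescription"))
  .stopIfNot(dt > 0, "dt must be > 0")
  .withSeed(seed, {
    hrmax <- 220 - subject@age
    recovery <- prescr@exerciseType %in% c("rest", "recovery")
    inten <- if (recovery) min(prescr@intensity, 0.2) else prescr@intensity
    hr <- if (is.null(heartRate)) subject@restingHr else heartRate
    fat <- subject@fatigue

    ## walk the step in 1-s ticks alternating work / prescribed rest
    cycle <- set_s + prescr@restInterval
    nTick <- max(1L, round(dt))
    for (s in seq_len(nTick)) {
      inWork <- inten > 0 && ((s - 1) %% max(cycle, 1)) < set_s
      iNow <- if (inWork) inten else 0
      tgt <- subject@restingHr +
        0.92 * iNow * (hrmax - subject@restingHr) * (1 + 0.15 * fat)
      tgt <- min(tgt, hrmax)
      hr <- tgt + (hr - tgt) * exp(-1 / hr_tau)
      if (iNow > 0) {
        fat <- fat + (1 / 60) * 0.085 * iNow^1.6 * (1 + 0.8 * fat)
      } else {
        fat <- fat * exp(-1 / 900)
      }
      fat <- .clamp(fat, 0, 1)
    }
    if (!is.null(seed)) hr <- hr + rnorm(1, 0, 0.5)
    hr <- .clamp(hr, 40, hrmax)

    ## chronic adaptation: logistic approach to a ceiling, driven by the
    ## session training load (intensity-minutes), attenuated by fatigue
    load <- inten * dt / 60
    vo2Ceil <- 62; repCeil <- 65
    gain <- 0.006 * load * (1 - 0.5 * fat)
    vo2 <- subject@vo2max + gain * (vo2Ceil - subject@vo2max)
    reps <- subject@enduranceReps +
      1.6 * gain * (repCeil - subject@enduranceReps)

    subj <- virtualSubject(
      age = subject@age, vo2max = vo2, enduranceReps = reps,
      restingHr = subject@restingHr, fatigue = fat,
      goalWeights = subject@goalWeights, targetHr = subject@targetHr)
    hrv <- .clamp(65 - 45 * fat - 0.15 * (hr - subject@restingHr) +
                    if (!is.null(seed)) rnorm(1, 0, 1) else 0, 5, 120)
    gsr <- 2 + 3 * fat + 1.2 * inten +
      (if (!is.null(seed)) rnorm(1, 0, 0.05) else 0)
    st <- userState(
      heartRate = hr, hrv = hrv, gsr = gsr,
      muscleActivation = .clamp(inten * (1 + 0.3 * fat), 0, 1),
      fatigueIndex = fat, age = subject@age, fitness = vo2)
    list(subject = subj, state = st)
  })
}

#' Nearest-centroid baseline classifier on window summary features
#'
#' A depth-0 reference classifier: each window is summarised by per-channel
#' mean and standard deviation; classes are predicted by the nearest class
#' centroid in the standardised summary space. Used as the sanity baseline
#' that any learned model must beat.
#'
#' @param train,test \linkS4class{FeatureWindows}
#' @return list(predictions = factor, accuracy = percent)
#' @export
nearestCentroidClassifier <- function(train, test) {
  summarise <- function(fw) {
    w <- windowArray(fw)
    t(apply(w, 3, function(m) c(colMeans(m), apply(m, 2, sd))))
  }
  Xtr <- summarise(train); Xte <- summarise(test)
  mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
  labs <- windowLabels(train)
  cent <- do.call(rbind, lapply(levels(labs), function(cl)
    colMeans(Xtr[labs == cl, , drop = FALSE])))
  d2 <- outer(rowSums(Xte^2), rowSums(cent^2), "+") - 2 * Xte %*% t(cent)
  pred <- factor(levels(labs)[max.col(-d2)], levels = levels(labs))
  acc <- 100 * mean(as.character(pred) ==
                      as.character(windowLabels(test)))
  list(predictions = pred, accuracy = acc)
}

#' Default labelled five-class synthetic dataset
#'
#' The study-condition dataset used throughout the examples and tests:
#' per subject, two 10-s bouts of each of the five exercise actions
#' (running, jumping, squat, stretching, bending) at per-bout intensities
#' drawn uniformly from [0.45, 1], simulated at 100 Hz, resampled to the
#' reference rate and cut into 2-s windows with 50\% overlap.
#'
#' @param nSubjects number of virtual subjects
#' @param seed integer seed
#' @param rate simulation and reference rate, Hz
#' @return a \linkS4class{FeatureWindows} over all subjects
#' @export
syntheticHarDataset <- function(nSubjects = 10, seed = 1, rate = 100) {
  acts <- c("running", "jumping", "squat", "stretching", "bending")
  fws <- lapply(seq_len(nSubjects), function(i) {
    sSeed <- .deriveSeed(seed, paste0("hards", i))
    sc <- .withSeed(sSeed, actionScript(
      rep(acts, each = 2), rep(10, 10), runif(10, 0.45, 1)))
    st <- simulateSession(sc, virtualSubject(), seed = sSeed + 1L,
                          rate = rate)
    segmentWindows(resampleStream(st, rate), 2, 0.5,
                   subject = sprintf("s%02d", i))
  })
  bindWindows(fws)
}
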