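## PPO-driven adaptive prescription: rollout environment over the
## virtual-subject physiology, actor-critic training with the clipped
## surrogate, and policy evaluation.
##
## The policy is a softmax-linear actor over a discrete intensity grid;
## the critic is linear in the same state features. The reward is the
## negative goal loss per step, minus a penalty per injury event, plus a
## terminal bonus for fitness gained over the session. Injury events are
## sampled with probability logistic in fatigue and executed intensity.
## Every proposed action passes through the hard safety override before
## execution.

.stateFeatures <- function(state, subject) {
  hrmax <- 220 - subject@age
  c(1,
    (state@heartRate - subject@restingHr) /
      max(hrmax - subject@restingHr, 1),
    state@fatigueIndex,
    state@hrv / 100)
}

.injuryProb <- function(fatigue, intensity) {
  1 / (1 + exp(-(-7 + 6 * fatigue + 3 * intensity)))
}

#' Roll out one prescription episode
#'
#' Steps the virtual-subject physiology for \code{nSteps} steps of
#' \code{dt} seconds. At each step \code{actFn(state, subject, t)}
#' proposes a prescription (and, for learned policies, the action index,
#' its probability and the feature vector); the proposal passes through
#' \code{\link{safetyOverride}} (with hysteresis persistence), the
#' physiology advances, an injury event is sampled, and the step reward
#' is the negative \code{\link{goalLoss}} minus
#' \code{injuryPenalty} per injury. A terminal fitness bonus
#' \code{5 * (VO2max gain)} is added to the last step.
#'
#' @param actFn function(state, subject, t) returning list(prescr, idx =
#'   action index or NA, prob, feat)
#' @param subject starting \linkS4class{VirtualSubject}
#' @param goals a \linkS4class{GoalSpec}
#' @param nSteps steps per episode
#' @param dt step length, seconds
#' @param restFloor minimum rest interval enforced on every executed
#'   prescription, seconds (0 disables the constraint)
#' @param injuryPenalty reward penalty per injury event
#' @param seed integer seed
#' @return list(records = data.frame per step, totalReward, subject =
#'   end-of-episode subject, trace = list of per-step detail)
#' @export
rolloutEpisode <- function(actFn, subject, goals, nSteps = 15,
                           dt = 180, restFloor = 0, injuryPenalty = 8,
                           seed = 1) {
  state <- userState(heartRate = subject@restingHr, hrv = 65, gsr = 2,
                     muscleActivation = 0, fatigueIndex = subject@fatigue,
                     age = subject@age, fitness = subject@vo2max)
  vo2Start <- subject@vo2max
  overrideActive <- FALSE
  rec <- vector("list", nSteps)
  trace <- vector("list", nSteps)
  for (t in seq_len(nSteps)) {
    act <- actFn(state, subject, t)
    prop <- act$prescr
    if (restFloor > 0)
      prop <- prescription(prop@exerciseType, prop@duration,
                           prop@intensity,
                           max(prop@restInterval, restFloor))
    ov <- safetyOverride(prop, state, active = overrideActive)
    overrideActive <- ov$override
    executed <- ov$prescription
    hrBefore <- state@heartRate
    st <- stepPhysiology(subject, executed, dt,
                         seed = .deriveSeed(seed, paste0("phys", t)),
                         heartRate = state@heartRate)
    subject <- st$subject; state <- st$state
    pInj <- .injuryProb(state@fatigueIndex, intensityOf(executed))
    injury <- .withSeed(.deriveSeed(seed, paste0("inj", t)),
                        runif(1) < pInj)
    ## risk-smoothed penalty: expected injury cost, not the sampled
    ## event, keeps the learning signal low-variance; events are still
    ## sampled and counted for the safety/ablation statistics
    reward <- -goalLoss(executed, state, goals, subject) -
      injuryPenalty * pInj
    if (t == nSteps) reward <- reward + 5 * (subject@vo2max - vo2Start)
    rec[[t]] <- data.frame(
      step = t, intensity = intensityOf(executed),
      proposed = intensityOf(prop), reward = reward,
      override = ov$override, injury = injury,
      hr = state@heartRate, hr_before = hrBefore,
      fatigue = state@fatigueIndex, rest = restIntervalOf(executed))
    trace[[t]] <- list(idx = act$idx, prob = act$prob, feat = act$feat)
  }
  records <- do.call(rbind, rec)
  list(records = records, totalReward = sum(records$reward),
       subject = subject, trace = trace)
}

## actFn factory for the softmax-linear actor
.ppoActFn <- function(W, actionGrid, restInterval, seed, greedy = FALSE) {
  force(W)
  function(state, subject, t) {
    feat <- .stateFeatures(state, subject)
    logits <- as.numeric(W %*% feat)
    pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
    idx <- if (greedy) which.max(pr)
    else .withSeed(.deriveSeed(seed, paste0("act", t)),
                   sample.int(length(pr), 1, prob = pr))
    list(prescr = prescription(exerciseType = "running", duration = 30,
                               intensity = actionGrid[idx],
                               restInterval = restInterval),
         idx = idx, prob = pr[idx], feat = feat)
  }
}

## actFn factory for the rule-based baselines (HR-rule carries state)
.baselineActFn <- function(kind, targetHr) {
  cur <- prescription(intensity = 0.5)
  function(state, subject, t) {
    cur <<- baselinePolicy(kind, state, current = cur,
                           targetHr = targetHr)
    list(prescr = cur, idx = NA_integer_, prob = NA_real_,
         feat = NULL)
  }
}

#' Train a PPO prescription policy
#'
#' Actor-critic training with the clipped surrogate
#' (\code{\link{ppoSurrogate}} gradient), generalised advantage
#' estimation and an entropy bonus, over the discrete intensity grid.
#' Deterministic under \code{seed}. The training log records per-episode
#' reward, override and injury counts and mean executed intensity;
#' summary statistics mirror the convergence/oscillation quantities used
#' to compare intervention strategies: \code{convergence} is the first
#' episode whose trailing-window mean reward is within 10\% of the final
#' window's mean, \code{oscillations} counts sign changes of the
#' smoothed mean-intensity trend.
#'
#' @param subject starting \linkS4class{VirtualSubject}
#' @param goals a \linkS4class{GoalSpec}
#' @param config a \linkS4class{PpoConfig}
#' @param episodes training episodes
#' @param nSteps,dt,restFloor,injuryPenalty passed to
#'   \code{\link{rolloutEpisode}}
#' @param actionGrid discrete intensity levels
#' @param seed integer seed
#' @return list(W = actor weights, v = critic weights, actionGrid,
#'   log = per-episode data.frame, convergence, oscillations,
#'   rewardVariance, finalReward, config)
#' @export
trainPpo <- function(subject, goals = goalSpec(), config = ppoConfig(),
                     episodes = 50, nSteps = 15, dt = 180,
                     restFloor = 0, injuryPenalty = 8,
                     actionGrid = seq(0.1, 1, by = 0.1), seed = 1) {
  stopifnot(is(config, "PpoConfig"))
  validObject(config)
  nA <- length(actionGrid)
  nF <- length(.stateFeatures(userState(), subject))
  W <- matrix(0, nA, nF)
  v <- rep(0, nF)
  logRows <- vector("list", episodes)
  for (ep in seq_len(episodes)) {
    epSeed <- .deriveSeed(seed, paste0("ep", ep))
    roll <- rolloutEpisode(
      .ppoActFn(W, actionGrid, restInterval = 50, seed = epSeed),
      subject, goals, nSteps = nSteps, dt = dt, restFloor = restFloor,
      injuryPenalty = injuryPenalty, seed = epSeed)
    r <- roll$records$reward
    feats <- do.call(rbind, lapply(roll$trace, `[[`, "feat"))
    idxs <- vapply(roll$trace, `[[`, 0L, "idx")
    probsOld <- vapply(roll$trace, `[[`, 0, "prob")
    Vs <- as.numeric(feats %*% v)
    Vnext <- c(Vs[-1], 0)
    delta <- r + config@gamma * Vnext - Vs
    adv <- numeric(nSteps); acc <- 0
    for (t in rev(seq_len(nSteps))) {
      acc <- delta[t] + config@gamma * config@gaeLambda * acc
      adv[t] <- acc
    }
    ret <- adv + Vs
    advN <- if (sd(adv) > 0) (adv - mean(adv)) / sd(adv) else adv
    if (any(!is.finite(advN))) stop("non-finite advantages: aborting")
    for (epoch in seq_len(config@epochs)) {
      gW <- 0 * W
      for (t in seq_len(nSteps)) {
        logits <- as.numeric(W %*% feats[t, ])
        pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
        ratio <- pr[idxs[t]] / probsOld[t]
        clipped <- (advN[t] > 0 && ratio > 1 + config@clip) ||
          (advN[t] < 0 && ratio < 1 - config@clip)
        dLogPi <- -pr; dLogPi[idxs[t]] <- dLogPi[idxs[t]] + 1
        gLogits <- if (clipped) 0 * pr
        else advN[t] * ratio * dLogPi
        ## entropy bonus gradient w.r.t. logits
        H <- -sum(pr * log(pmax(pr, 1e-12)))
        gEnt <- -pr * (log(pmax(pr, 1e-12)) + H)
        gW <- gW + outer(gLogits + config@entropy * gEnt,
                         feats[t, ]) / nSteps
      }
      if (any(!is.finite(gW))) stop("non-finite policy gradient: aborting")
      W <- W + config@lr * gW
    }
    vErr <- ret - as.numeric(feats %*% v)
    v <- v + 0.05 * as.numeric(crossprod(feats, vErr)) / nSteps
    logRows[[ep]] <- data.frame(
      episode = ep, reward = roll$totalReward,
      mean_intensity = mean(roll$records$intensity),
      overrides = sum(roll$records$override),
      injuries = sum(roll$records$injury))
  }
  log <- do.call(rbind, logRows)
  win <- max(3L, min(5L, episodes))
  trail <- vapply(seq_len(episodes), function(e)
    mean(log$reward[max(1, e - win + 1):e]), 0)
  finalMean <- trail[episodes]
  tol <- 0.1 * max(abs(finalMean), 1)
  convergence <- which(abs(trail - finalMean) <= tol)[1]
  smooth <- stats::filter(log$mean_intensity, rep(1 / win, win),
                          sides = 1)
  dtr <- diff(smooth[!is.na(smooth)])
  oscillations <- sum(diff(sign(dtr[dtr != 0])) != 0)
  list(W = W, v = v, actionGrid = actionGrid, log = log,
       convergence = convergence, oscillations = oscillations,
       rewardVariance = var(log$reward),
       finalReward = finalMean, config = config)
}

#' Evaluate a trained or rule-based policy
#'
#' Runs evaluation episodes and returns the mean total reward plus
#' rollout safety statistics.
#'
#' @param policy either the list returned by \code{\link{trainPpo}} or a
#'   baseline kind ("FIS", "HR-rule", "Fatigue-rule")
#' @param subject starting \linkS4class{VirtualSubject}
#' @param goals a \linkS4class{GoalSpec}
#' @param episodes evaluation episodes
#' @param nSteps,dt,restFloor,injuryPenalty passed to the rollout
#' @param seed integer seed
#' @param greedy use the argmax action for learned policies
#' @return list(meanReward, rewards, records = bound per-step records)
#' @export
evaluatePolicy <- function(policy, subject, goals = goalSpec(),
                           episodes = 5, nSteps = 15, dt = 180,
                           restFloor = 0, injuryPenalty = 8, seed = 1,
                           greedy = TRUE) {
  rewards <- numeric(episodes)
  recs <- vector("list", episodes)
  for (ep in seq_len(episodes)) {
    epSeed <- .deriveSeed(seed, paste0("eval", ep))
    actFn <- if (is.character(policy))
      .baselineActFn(policy, targetHr = subject@targetHr)
    else .ppoActFn(policy$W, policy$actionGrid, restInterval = 50,
                   seed = epSeed, greedy = greedy)
    roll <- rolloutEpisode(actFn, subject, goals, nSteps = nSteps,
                           dt = dt, restFloor = restFloor,
                           injuryPenalty = injuryPenalty, seed = epSeed)
    rewards[ep] <- roll$totalReward
    recs[[ep]] <- cbind(episode = ep, roll$records)
  }
  list(meanReward = mean(rewards), rewards = rewards,
       records = do.call(rbind, recs))
}
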