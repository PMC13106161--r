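## Prescription generation: goal-weighted objective, safety override,
## fatigue index and the rule-based baseline policies.

#' Clipped PPO surrogate objective contribution
#'
#' \eqn{\min(r \hat A, \mathrm{clip}(r, 1-\epsilon, 1+\epsilon) \hat A)}
#' for a probability ratio \eqn{r > 0} and advantage estimate
#' \eqn{\hat A}: equals \eqn{\hat A} at \eqn{r = 1} and is bounded above
#' by \eqn{r \hat A} everywhere.
#'
#' @param r probability ratio (new over old policy), > 0
#' @param advantage advantage estimate \eqn{\hat A}
#' @param clip clipping threshold \eqn{\epsilon}
#' @return the surrogate contribution (vectorised)
#' @examples
#' ppoSurrogate(1.5, 1, 0.2)    # 1.2
#' ppoSurrogate(0.5, -1, 0.2)   # -0.8
#' @export
ppoSurrogate <- function(r, advantage, clip = 0.2) {
  .stopIfNot(all(r > 0), "probability ratio must be positive")
  pmin(r * advantage, .clamp(r, 1 - clip, 1 + clip) * advantage)
}

## default goal components; all take (prescr, state, subject) and return
## a finite scalar loss contribution (lower = better for that goal)
.fMuscleDefault <- function(prescr, state, subject) {
  ## negative expected strength-adaptation increment: moderate-to-high
  ## intensity while fresh drives adaptation
  -intensityOf(prescr) * (1 - 0.7 * state@fatigueIndex)
}
.fFatlossDefault <- function(prescr, state, subject) {
  ## negative expected energy expenditure (normalised to session scale)
  i <- intensityOf(prescr)
  -(0.4 * i + 0.6 * i^2)
}
.fFatigueDefault <- function(prescr, state, subject) {
  ## predicted end-of-step fatigue under the proposed intensity
  .clamp(state@fatigueIndex +
           0.11 * intensityOf(prescr)^1.6 *
           (1 + 0.8 * state@fatigueIndex), 0, 1)
}

#' Goal-weighted prescription loss
#'
#' \eqn{L_{goal} = w_1 f_{muscle} + w_2 f_{fatloss} + w_3 f_{fatigue}}
#' with the component functions of the \linkS4class{GoalSpec} (package
#' defaults when not supplied).
#'
#' @param prescr a \linkS4class{Prescription}
#' @param state a \linkS4class{UserState}
#' @param goals a \linkS4class{GoalSpec}
#' @param subject optional \linkS4class{VirtualSubject} passed to the
#'   components
#' @return scalar loss
#' @export
goalLoss <- function(prescr, state, goals,
                     subject = virtualSubject()) {
  stopifnot(is(goals, "GoalSpec"))
  validObject(goals)
  comp <- list(
    fMuscle = goals@components$fMuscle %||% .fMuscleDefault,
    fFatloss = goals@components$fFatloss %||% .fFatlossDefault,
    fFatigue = goals@components$fFatigue %||% .fFatigueDefault)
  vals <- vapply(names(comp), function(nm) {
    v <- comp[[nm]](prescr, state, subject)
    .stopIfNot(is.finite(v), "goal component '", nm,
               "' returned a non-finite value")
    v
  }, 0)
  sum(goals@weights * vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## squared normalised distance between consecutive prescriptions
.adaptLoss <- function(x, xPrev) {
  (intensityOf(x) - intensityOf(xPrev))^2 +
    ((x@duration - xPrev@duration) / 60)^2 +
    ((restIntervalOf(x) - restIntervalOf(xPrev)) / 300)^2 +
    as.numeric(x@exerciseType != xPrev@exerciseType)
}

#' Smoothness-constrained prescription optimisation
#'
#' Picks \eqn{\hat x_{t+1} = \arg\min_x E[L_{goal}(x)] + \lambda
#' L_{adapt}(x, x_t)} over a candidate set; the expectation is estimated
#' by physiology-model rollouts under fixed per-candidate-independent
#' seeds, and \eqn{L_{adapt}} is the squared normalised distance from the
#' current prescription. Ties break toward the smaller change from
#' \eqn{x_t}.
#'
#' @param current the current \linkS4class{Prescription} \eqn{x_t}
#' @param goals a \linkS4class{GoalSpec}
#' @param candidates non-empty list of candidate
#'   \linkS4class{Prescription}s
#' @param subject the \linkS4class{VirtualSubject} rolled out
#' @param state current \linkS4class{UserState}
#' @param lambda smoothness weight \eqn{\lambda \ge 0}
#' @param nRollouts physiology rollouts per candidate
#' @param dt rollout step, seconds
#' @param seed integer seed (same rollout seeds across candidates)
#' @return the selected \linkS4class{Prescription}
#' @export
optimizePrescription <- function(current, goals, candidates,
                                 subject = virtualSubject(),
                                 state = userState(), lambda = 0.1,
                                 nRollouts = 5, dt = 120, seed = 1) {
  .stopIfNot(length(candidates) >= 1, "candidate set must be non-empty")
  score <- vapply(candidates, function(cand) {
    ls <- vapply(seq_len(nRollouts), function(r) {
      st <- stepPhysiology(subject, cand, dt,
                           seed = .deriveSeed(seed, paste0("roll", r)),
                           heartRate = state@heartRate)
      goalLoss(cand, st$state, goals, subject)
    }, 0)
    mean(ls) + lambda * .adaptLoss(cand, current)
  }, 0)
  dist <- vapply(candidates, .adaptLoss, 0, xPrev = current)
  best <- which(score <= min(score) + 1e-12)
  candidates[[best[which.min(dist[best])]]]
}

#' Hard physiological safety override
#'
#' If the heart rate exceeds 90\% of the theoretical maximum (220 - age),
#' or severe movement deformation is flagged, the proposed prescription
#' is bypassed and a mandatory low-intensity recovery prescription is
#' returned. Once triggered, the override persists (pass
#' \code{active = TRUE}) until the heart rate re-enters bounds (below
#' \code{release} times the maximum).
#'
#' @param proposed the policy's proposed \linkS4class{Prescription}
#' @param state current \linkS4class{UserState}
#' @param deformity severe-movement-deformation flag
#' @param active was the override active at the previous step
#' @param cap recovery intensity cap
#' @param release hysteresis release fraction of max heart rate
#' @return list(prescription, override = logical)
#' @examples
#' s <- userState(heartRate = 175, age = 30)
#' safetyOverride(prescription(intensity = 0.9), s)$override  # TRUE
#' @export
safetyOverride <- function(proposed, state, deformity = FALSE,
                           active = FALSE, cap = 0.2, release = 0.85) {
  hrmax <- 220 - state@age
  trigger <- state@heartRate > 0.9 * hrmax || deformity
  stay <- active && state@heartRate >= release * hrmax
  if (trigger || stay) {
    list(prescription = prescription(
      exerciseType = "recovery", duration = proposed@duration,
      intensity = min(cap, proposed@intensity),
      restInterval = max(90, proposed@restInterval)),
      override = TRUE)
  } else {
    list(prescription = proposed, override = FALSE)
  }
}

#' Composite fatigue index from GSR and HRV series
#'
#' The declared closed form: the standardised rise of skin conductance
#' minus the standardised rise of heart-rate variability, squashed by the
#' logistic function. Rises are (mean of the last quarter - mean of the
#' first quarter) divided by the series standard deviation. Bounded in
#' (0, 1); increasing in GSR, decreasing in HRV; all-constant inputs give
#' the neutral value 0.5 (with a message).
#'
#' @param gsr numeric skin-conductance series, microsiemens
#' @param hrv numeric heart-rate-variability series, ms
#' @return fatigue index in [0, 1]
#' @export
fatigueIndex <- function(gsr, hrv) {
  .stopIfNot(length(gsr) >= 1 && length(hrv) >= 1,
             "both series must be non-empty")
  rise <- function(x) {
    if (length(x) == 1L || sd(x) == 0) return(NA_real_)
    q <- max(1L, floor(length(x) / 4))
    (mean(x[(length(x) - q + 1):length(x)]) - mean(x[1:q])) / sd(x)
  }
  zg <- rise(gsr); zh <- rise(hrv)
  if (is.na(zg) && is.na(zh))
    message("all-constant GSR and HRV: neutral fatigue index 0.5")
  zg <- if (is.na(zg)) 0 else zg
  zh <- if (is.na(zh)) 0 else zh
  1 / (1 + exp(-(zg - zh)))
}

#' Rule-based baseline prescription policies
#'
#' \code{"FIS"} (fixed-intensity strategy) returns the same preset
#' prescription regardless of state. \code{"HR-rule"} steps intensity up
#' when the heart rate is below the target zone and down when above.
#' \code{"Fatigue-rule"} switches to low-intensity recovery when the
#' fatigue index exceeds the threshold, otherwise keeps a moderate
#' prescription.
#'
#' @param kind one of "FIS", "HR-rule", "Fatigue-rule"
#' @param state a \linkS4class{UserState}
#' @param current the current \linkS4class{Prescription} (stepped by the
#'   HR rule)
#' @param targetHr target heart rate, bpm (zone is +/- \code{zone})
#' @param zone half-width of the target zone, bpm
#' @param threshold fatigue threshold of the fatigue rule
#' @param fisIntensity preset intensity of the fixed strategy
#' @return a \linkS4class{Prescription}
#' @export
baselinePolicy <- function(kind, state,
                           current = prescription(intensity = 0.5),
                           targetHr = 125, zone = 8, threshold = 0.8,
                           fisIntensity = 0.8) {
  stopifnot(is(state, "UserState"))
  if (kind == "FIS") {
    prescription(exerciseType = "running", duration = 30,
                 intensity = fisIntensity, restInterval = 50)
  } else if (kind == "HR-rule") {
    step <- if (state@heartRate < targetHr - zone) 0.1
    else if (state@heartRate > targetHr + zone) -0.1 else 0
    prescription(exerciseType = current@exerciseType,
                 duration = current@duration,
                 intensity = .clamp(current@intensity + step, 0.1, 1),
                 restInterval = current@restInterval)
  } else if (kind == "Fatigue-rule") {
    if (state@fatigueIndex > threshold)
      prescription(exerciseType = "recovery", duration = 30,
                   intensity = 0.15, restInterval = 120)
    else
      prescription(exerciseType = "running", duration = 30,
                   intensity = 0.7, restInterval = 60)
  } else stop("unknown baseline kind '", kind, "'")
}
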