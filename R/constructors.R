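#' Construct a SensorStream
#'
#' Low-level constructor wrapping a channels x samples signal matrix into
#' the \linkS4class{SensorStream} container. Most users obtain streams from
#' \code{\link{simulateSession}} or \code{\link{readStream}}.
#'
#' @param signal numeric matrix, channels x samples; rownames are channel
#'   names
#' @param time numeric vector of per-sample timestamps (seconds, strictly
#'   increasing)
#' @param placement character vector, one placement per channel (one of
#'   wrist, chest, ankle for accelerometer axes; "body" for physiological
#'   channels)
#' @param unit character vector of per-channel units
#' @param nominal_rate nominal sampling rate in Hz, in [50, 200]
#' @param label optional per-sample activity labels
#' @param intensity optional per-sample intensity in [0, 1]
#' @param missing logical matrix of the same shape as \code{signal}
#' @param metadata extra metadata list entries
#' @return a \linkS4class{SensorStream}
#' @export
SensorStream <- function(signal, time, placement, unit,
                         nominal_rate = 100,
                         label = NULL, intensity = NULL,
                         missing = NULL, metadata = list()) {
  if (is.null(missing))
    missing <- matrix(FALSE, nrow(signal), ncol(signal))
  cd <- DataFrame(time = time)
  if (!is.null(label)) cd$label <- label
  if (!is.null(intensity)) cd$intensity <- intensity
  rd <- DataFrame(channel = rownames(signal), placement = placement,
                  unit = unit)
  md <- c(list(nominal_rate = nominal_rate), metadata)
  se <- SummarizedExperiment(
    assays = list(signal = signal, missing = missing),
    rowData = rd, colData = cd, metadata = md)
  new("SensorStream", se)
}

#' Construct an ActionScript
#'
#' @param label character vector of segment labels
#' @param duration numeric vector of segment durations (seconds)
#' @param intensity numeric vector of segment intensities in [0, 1]
#' @return an \linkS4class{ActionScript}
#' @examples
#' actionScript(c("running", "rest"), c(30, 15), c(0.8, 0))
#' @export
actionScript <- function(label, duration, intensity) {
  bad <- setdiff(unique(as.character(label)), .ACTIONS)
  if (length(bad))
    stop("unknown action label(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(.ACTIONS, collapse = ", "), ")")
  new("ActionScript", segments = data.frame(
    label = as.character(label), duration = as.numeric(duration),
    intensity = as.numeric(intensity)))
}

#' Construct a VirtualSubject
#'
#' Defaults describe a healthy sedentary adult consistent with the
#' simulated cohort (age around 35, VO2max around 41 mL/kg/min, ~23
#' push-ups); goal weights default to a muscle-gain-dominant profile.
#'
#' @param age years
#' @param vo2max mL/kg/min
#' @param enduranceReps maximum push-up repetitions
#' @param restingHr bpm
#' @param fatigue initial fatigue in [0, 1]
#' @param goalWeights numeric(3): muscle gain, fat loss, fatigue control
#' @param targetHr target training heart rate, bpm
#' @return a \linkS4class{VirtualSubject}
#' @export
virtualSubject <- function(age = 35, vo2max = 41.3, enduranceReps = 23,
                           restingHr = 68, fatigue = 0,
                           goalWeights = c(0.55, 0.30, 0.15),
                           targetHr = 125) {
  new("VirtualSubject", age = age, vo2max = vo2max,
      enduranceReps = enduranceReps, restingHr = restingHr,
      fatigue = fatigue, goalWeights = goalWeights, targetHr = targetHr)
}

#' Construct an InterferenceSpec
#'
#' @param kind one of emi, motion_artifact, temp_drift, humidity_drift,
#'   composite
#' @param magnitude disturbance magnitude (channel-appropriate units)
#' @param onset window start, seconds
#' @param duration window length, seconds
#' @return an \linkS4class{InterferenceSpec}
#' @export
interferenceSpec <- function(kind, magnitude, onset, duration) {
  new("InterferenceSpec", kind = kind, magnitude = magnitude,
      onset = onset, duration = duration)
}

#' Construct WaveletParams
#'
#' @param basis wavelet family; only "db9"
#' @param j0 coarsest retained scale
#' @param J decomposition depth
#' @param lambdaLow,lambdaHigh semi-soft cutoffs (used when
#'   \code{rule = "fixed"})
#' @param rule "universal" (default; data-driven cutoffs) or "fixed"
#' @return a \linkS4class{WaveletParams}
#' @export
waveletParams <- function(basis = "db9", j0 = 1, J = 4,
                          lambdaLow = 0, lambdaHigh = 0,
                          rule = c("universal", "fixed")) {
  rule <- match.arg(rule)
  new("WaveletParams", basis = basis, j0 = j0, J = J,
      lambdaLow = lambdaLow, lambdaHigh = lambdaHigh, rule = rule)
}

#' Construct a SkeletonGraph
#'
#' Default: the three sensor placements (wrist, chest, ankle) fully
#' connected, with self-loops added on construction.
#'
#' @param nodes character node names
#' @param adjacency optional node x node 0/1 matrix (self-loops are forced
#'   onto the diagonal); default fully connected
#' @return a \linkS4class{SkeletonGraph}
#' @export
skeletonGraph <- function(nodes = c("wrist", "chest", "ankle"),
                          adjacency = NULL) {
  n <- length(nodes)
  if (is.null(adjacency)) adjacency <- matrix(1, n, n)
  diag(adjacency) <- 1
  dimnames(adjacency) <- list(nodes, nodes)
  new("SkeletonGraph", nodes = nodes, adjacency = adjacency)
}

#' Construct a Prescription
#'
#' @param exerciseType action type, e.g. "running" or "recovery"
#' @param duration minutes
#' @param intensity in [0, 1]
#' @param restInterval seconds between sets
#' @return a \linkS4class{Prescription}
#' @export
prescription <- function(exerciseType = "running", duration = 30,
                         intensity = 0.5, restInterval = 60) {
  new("Prescription", exerciseType = exerciseType, duration = duration,
      intensity = intensity, restInterval = restInterval)
}

#' Construct a UserState
#'
#' @param heartRate bpm
#' @param hrv ms
#' @param gsr microsiemens
#' @param muscleActivation in [0, 1]
#' @param fatigueIndex in [0, 1]
#' @param age years
#' @param fitness VO2max summary, mL/kg/min
#' @return a \linkS4class{UserState}
#' @export
userState <- function(heartRate = 70, hrv = 45, gsr = 2,
                      muscleActivation = 0.1, fatigueIndex = 0,
                      age = 35, fitness = 41.3) {
  new("UserState", heartRate = heartRate, hrv = hrv, gsr = gsr,
      muscleActivation = muscleActivation, fatigueIndex = fatigueIndex,
      age = age, fitness = fitness)
}

#' Construct a GoalSpec
#'
#' @param weights numeric(3): muscle gain, fat loss, fatigue control
#' @param targetHr bpm
#' @param components optional named list(fMuscle, fFatloss, fFatigue) of
#'   component functions; empty list uses the package defaults
#' @return a \linkS4class{GoalSpec}
#' @export
goalSpec <- function(weights = c(0.55, 0.30, 0.15), targetHr = 125,
                     components = list()) {
  new("GoalSpec", weights = weights, targetHr = targetHr,
      components = components)
}

#' Construct a PpoConfig
#'
#' Defaults: clipping epsilon 0.2, discount 0.99, GAE lambda 0.95.
#'
#' @param clip clipping threshold epsilon
#' @param gamma discount factor
#' @param gaeLambda advantage-estimation lambda
#' @param lr learning rate
#' @param epochs gradient epochs per update
#' @param smoothness prescription-change penalty weight
#' @param entropy entropy-bonus coefficient
#' @return a \linkS4class{PpoConfig}
#' @export
ppoConfig <- function(clip = 0.2, gamma = 0.99, gaeLambda = 0.95,
                      lr = 0.08, epochs = 4, smoothness = 0.1,
                      entropy = 0.03) {
  new("PpoConfig", clip = clip, gamma = gamma, gaeLambda = gaeLambda,
      lr = lr, epochs = epochs, smoothness = smoothness, entropy = entropy)
}

#' Construct a ClientUpdate
#'
#' @param clientId client identifier
#' @param delta flattened parameter increment (local minus global)
#' @param nSamples local sample count
#' @param round federation round index
#' @return a \linkS4class{ClientUpdate}
#' @export
clientUpdate <- function(clientId, delta, nSamples, round = 1) {
  new("ClientUpdate", clientId = as.character(clientId),
      delta = as.numeric(delta), nSamples = nSamples, round = round)
}
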