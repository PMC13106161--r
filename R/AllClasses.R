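#' @import methods
#' @importFrom stats approx rnorm runif rbinom sd var median mad qnorm
#'   predict t.test wilcox.test chisq.test shapiro.test binom.test qt
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assay<-
NULL

## Action vocabulary shared by the generator and the classifier.
.ACTIONS <- c("running", "jumping", "squat", "stretching", "bending",
              "walking", "rest")

#' SensorStream: a multimodal wearable-sensor recording
#'
#' A \code{SensorStream} holds a synchronous multichannel recording as a
#' \linkS4class{SummarizedExperiment}: channels are rows (by default 9
#' accelerometer axes across the wrist/chest/ankle placements plus heart
#' rate, galvanic skin response and skin temperature), samples are columns.
#' Two assays are carried: \code{signal} (numeric) and \code{missing}
#' (logical drop-out mask). Per-sample timestamps, activity labels and
#' instantaneous intensity live in \code{colData}; channel name, placement
#' and unit live in \code{rowData}; the nominal sampling rate, any injected
#' interference provenance and (for simulated corruption) the pre-drop-out
#' ground truth live in \code{metadata()}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases SensorStream-class
#' @exportClass SensorStream
setClass("SensorStream", contains = "SummarizedExperiment")

.validSensorStream <- function(object) {
  msg <- NULL
  an <- names(assays(object))
  if (!all(c("signal", "missing") %in% an))
    msg <- c(msg, "assays must contain 'signal' and 'missing'")
  else {
    sig <- assay(object, "signal")
    mis <- assay(object, "missing")
    if (!is.logical(mis)) msg <- c(msg, "'missing' assay must be logical")
    if (any(!is.finite(sig[!mis])))
      msg <- c(msg, "non-missing signal values must be finite")
  }
  if (!"time" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'time' column (seconds)")
  else {
    tt <- colData(object)$time
    if (length(tt) > 1L && any(diff(tt) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  rate <- metadata(object)$nominal_rate
  if (is.null(rate) || !is.numeric(rate) || rate < 50 || rate > 200)
    msg <- c(msg, "metadata()$nominal_rate must lie in [50, 200] Hz")
  if (is.null(msg)) TRUE else msg
}
setValidity("SensorStream", .validSensorStream)

#' ActionScript: an ordered exercise session script
#'
#' Ordered segments of (label, duration, intensity) driving the synthetic
#' stream generator. Labels come from the seven-action vocabulary
#' (running, jumping, squat, stretching, bending, walking, rest).
#'
#' @slot segments data.frame with columns \code{label}, \code{duration}
#'   (seconds, > 0) and \code{intensity} (in [0, 1]).
#' @exportClass ActionScript
setClass("ActionScript", representation(segments = "data.frame"))

setValidity("ActionScript", function(object) {
  seg <- object@segments
  msg <- NULL
  need <- c("label", "duration", "intensity")
  if (!all(need %in% names(seg)))
    return(sprintf("segments needs columns %s", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L) msg <- c(msg, "script must contain >= 1 segment")
  bad <- setdiff(unique(as.character(seg$label)), .ACTIONS)
  if (length(bad))
    msg <- c(msg, sprintf("unknown action label(s): %s",
                          paste(bad, collapse = ", ")))
  if (any(seg$duration <= 0)) msg <- c(msg, "durations must be > 0")
  if (any(seg$intensity < 0 | seg$intensity > 1))
    msg <- c(msg, "intensity must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' VirtualSubject: a simulated trial participant
#'
#' Carries the physiological state and goal weighting of one virtual
#' participant: age, cardiorespiratory fitness (VO2max), muscular endurance
#' (push-up repetitions), resting heart rate, current fatigue in [0, 1],
#' the three health-goal weights (muscle gain, fat loss, fatigue control,
#' summing to 1) and the individual target heart rate.
#'
#' @slot age years
#' @slot vo2max mL/kg/min
#' @slot enduranceReps push-up repetitions
#' @slot restingHr bpm; must stay below the theoretical maximum 220 - age
#' @slot fatigue dimensionless, in [0, 1]
#' @slot goalWeights numeric(3) on the simplex
#' @slot targetHr bpm
#' @exportClass VirtualSubject
setClass("VirtualSubject", representation(
  age = "numeric", vo2max = "numeric", enduranceReps = "numeric",
  restingHr = "numeric", fatigue = "numeric", goalWeights = "numeric",
  targetHr = "numeric"))

setValidity("VirtualSubject", function(object) {
  msg <- NULL
  if (object@fatigue < 0 || object@fatigue > 1)
    msg <- c(msg, "fatigue must lie in [0, 1]")
  if (length(object@goalWeights) != 3L)
    msg <- c(msg, "goalWeights must have length 3")
  else if (abs(sum(object@goalWeights) - 1) > 1e-9 ||
           any(object@goalWeights < 0))
    msg <- c(msg, "goalWeights must be nonnegative and sum to 1 (+/- 1e-9)")
  if (object@restingHr >= 220 - object@age)
    msg <- c(msg, "restingHr must be below the theoretical maximum 220 - age")
  if (is.null(msg)) TRUE else msg
})

#' InterferenceSpec: a windowed disturbance to inject into a stream
#'
#' @slot kind one of emi, motion_artifact, temp_drift, humidity_drift,
#'   composite
#' @slot magnitude disturbance size in channel-appropriate units (EMI /
#'   motion artifact: additive accel amplitude in m/s^2; temp_drift: total
#'   skin-temperature delta in degrees C over the window)
#' @slot onset seconds from stream start
#' @slot duration seconds
#' @exportClass InterferenceSpec
setClass("InterferenceSpec", representation(
  kind = "character", magnitude = "numeric",
  onset = "numeric", duration = "numeric"))

.INTERFERENCE_KINDS <- c("emi", "motion_artifact", "temp_drift",
                         "humidity_drift", "composite")
setValidity("InterferenceSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% .INTERFERENCE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.INTERFERENCE_KINDS, collapse = ", ")))
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@onset < 0) msg <- c(msg, "onset must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' WaveletParams: semi-soft wavelet denoising parameters
#'
#' Parameters for multi-scale Daubechies-9 decomposition with semi-soft
#' coefficient shrinkage. The two cutoffs satisfy
#' \code{lambdaHigh > lambdaLow >= 0}; with \code{rule = "universal"} they
#' are derived per signal from the universal threshold
#' \eqn{\lambda_u = \hat\sigma \sqrt{2 \log N}} with the noise scale
#' \eqn{\hat\sigma} estimated as MAD/0.6745 of the finest detail scale
#' (then \code{lambdaHigh = lambda_u}, \code{lambdaLow = lambda_u / 2}).
#'
#' @slot basis wavelet family (only "db9" is implemented)
#' @slot j0 coarsest retained scale (approximation level), >= 1
#' @slot J maximum decomposition depth
#' @slot lambdaLow lower cutoff (coefficients below it are zeroed)
#' @slot lambdaHigh upper cutoff
#' @slot rule "fixed" (use the slots) or "universal" (per-signal estimate)
#' @exportClass WaveletParams
setClass("WaveletParams", representation(
  basis = "character", j0 = "numeric", J = "numeric",
  lambdaLow = "numeric", lambdaHigh = "numeric", rule = "character"))

setValidity("WaveletParams", function(object) {
  msg <- NULL
  if (!identical(object@basis, "db9"))
    msg <- c(msg, "only the 'db9' basis is implemented")
  if (!object@rule %in% c("fixed", "universal"))
    msg <- c(msg, "rule must be 'fixed' or 'universal'")
  if (object@rule == "fixed") {
    if (object@lambdaLow < 0) msg <- c(msg, "lambdaLow must be >= 0")
    if (object@lambdaHigh <= object@lambdaLow &&
        !(object@lambdaHigh == 0 && object@lambdaLow == 0))
      msg <- c(msg, "lambdaHigh must exceed lambdaLow")
  }
  if (object@j0 < 1 || object@J < object@j0)
    msg <- c(msg, "need 1 <= j0 <= J")
  if (is.null(msg)) TRUE else msg
})

#' DtwAlignment: result of a dynamic time warping alignment
#'
#' @slot costMatrix M x N local cost matrix C
#' @slot cumulativeCost M x N cumulative cost matrix D
#' @slot path integer matrix (steps x 2) of aligned index pairs, from
#'   (1, 1) to (M, N) with steps in {(1,0), (0,1), (1,1)}
#' @slot totalCost D[M, N]
#' @exportClass DtwAlignment
setClass("DtwAlignment", representation(
  costMatrix = "matrix", cumulativeCost = "matrix",
  path = "matrix", totalCost = "numeric"))

setValidity("DtwAlignment", function(object) {
  p <- object@path
  M <- nrow(object@costMatrix); N <- ncol(object@costMatrix)
  msg <- NULL
  if (!all(p[1, ] == c(1L, 1L)) || !all(p[nrow(p), ] == c(M, N)))
    msg <- c(msg, "path must run from (1,1) to (M,N)")
  if (nrow(p) > 1L) {
    st <- diff(p)
    if (any(st < 0 | st > 1) || any(rowSums(st) == 0))
      msg <- c(msg, "path steps must be (1,0), (0,1) or (1,1)")
  }
  if (object@totalCost < 0) msg <- c(msg, "totalCost must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' FeatureWindows: windowed spatiotemporal feature matrices
#'
#' The classifier input: one T x D feature matrix F per window (T time
#' steps, D channels), stacked into a T x D x N array, with per-window
#' majority labels, subject ids, window start times and (after
#' standardisation) the per-feature normalisation statistics that were fit
#' on the training split.
#'
#' @slot windows numeric array T x D x N
#' @slot labels factor of length N
#' @slot subject character of length N
#' @slot startTime numeric of length N, seconds
#' @slot channels character of length D
#' @slot rate sampling rate of the windows, Hz
#' @slot normCenter,normScale numeric(D) Z-score statistics (length 0
#'   before standardisation)
#' @exportClass FeatureWindows
setClass("FeatureWindows", representation(
  windows = "array", labels = "factor", subject = "character",
  startTime = "numeric", channels = "character", rate = "numeric",
  normCenter = "numeric", normScale = "numeric"))

setValidity("FeatureWindows", function(object) {
  d <- dim(object@windows)
  msg <- NULL
  if (length(d) != 3L) return("windows must be a T x D x N array")
  if (length(object@labels) != d[3]) msg <- c(msg, "labels length != N")
  if (length(object@subject) != d[3]) msg <- c(msg, "subject length != N")
  if (length(object@channels) != d[2]) msg <- c(msg, "channels length != D")
  if (length(object@normCenter) &&
      length(object@normCenter) != d[2]) msg <- c(msg, "normCenter length != D")
  if (any(!is.finite(object@windows))) msg <- c(msg, "windows must be finite")
  if (is.null(msg)) TRUE else msg
})

#' SkeletonGraph: sensor-placement body graph
#'
#' Nodes are sensor placements (wrist, chest, ankle by default); the
#' adjacency matrix carries self-loops on the diagonal, so the degree
#' matrix and the symmetric normalised operator
#' \eqn{\tilde D^{-1/2} \tilde A \tilde D^{-1/2}} are always defined.
#'
#' @slot nodes character node names
#' @slot adjacency symmetric 0/1 (or weighted, nonnegative) matrix with
#'   unit diagonal
#' @exportClass SkeletonGraph
setClass("SkeletonGraph", representation(
  nodes = "character", adjacency = "matrix"))

setValidity("SkeletonGraph", function(object) {
  A <- object@adjacency
  msg <- NULL
  n <- length(object@nodes)
  if (!all(dim(A) == c(n, n))) return("adjacency must be node x node")
  if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(A) != 1)) msg <- c(msg, "diagonal must be all ones (self-loops)")
  if (any(A < 0)) msg <- c(msg, "adjacency must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' HarModel: hybrid Transformer-GCN action classifier
#'
#' Graph-convolution spatial blocks over the placement graph feed a
#' Transformer encoder (multi-head self-attention with sinusoidal
#' positional encoding); mean pooling and a linear softmax head produce
#' class probabilities. Weights live in \code{params} as a named list of
#' matrices; \code{config} records the architecture.
#'
#' @slot config list(dModel, nHeads, nLayers, dff, nGcnLayers, subFrames,
#'   classes, seed, ...)
#' @slot params named list of weight matrices/vectors
#' @slot graph \linkS4class{SkeletonGraph}
#' @slot classes character class names
#' @slot trained logical
#' @slot log data.frame per-epoch training log
#' @exportClass HarModel
setClass("HarModel", representation(
  config = "list", params = "list", graph = "SkeletonGraph",
  classes = "character", trained = "logical", log = "data.frame"))

#' EvalReport: per-class classification metrics
#'
#' @slot perClass data.frame (class, precision, recall, f1, support),
#'   percentages; NA marks metrics undefined for classes absent from truth
#' @slot accuracy overall accuracy, percent
#' @slot confusion class x class count matrix (rows = truth)
#' @exportClass EvalReport
setClass("EvalReport", representation(
  perClass = "data.frame", accuracy = "numeric", confusion = "matrix"))

setValidity("EvalReport", function(object) {
  msg <- NULL
  if (object@accuracy < 0 || object@accuracy > 100)
    msg <- c(msg, "accuracy must lie in [0, 100]")
  if (!all(rowSums(object@confusion) == object@perClass$support))
    msg <- c(msg, "confusion row sums must equal per-class support")
  if (is.null(msg)) TRUE else msg
})

#' ClientUpdate: one client's federated parameter increment
#'
#' Carries only the parameter delta (local minus global, flattened), the
#' local sample count and the round index -- never raw client data.
#'
#' @slot clientId character
#' @slot delta numeric parameter increment vector
#' @slot nSamples positive integer local sample count
#' @slot round integer federation round
#' @exportClass ClientUpdate
setClass("ClientUpdate", representation(
  clientId = "character", delta = "numeric",
  nSamples = "numeric", round = "numeric"))

setValidity("ClientUpdate", function(object) {
  msg <- NULL
  if (object@nSamples < 1) msg <- c(msg, "nSamples must be >= 1")
  if (any(!is.finite(object@delta))) msg <- c(msg, "delta must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Prescription: one exercise-prescription action
#'
#' @slot exerciseType one of the action vocabulary (excluding rest) or
#'   "recovery"
#' @slot duration minutes, > 0
#' @slot intensity in [0, 1]
#' @slot restInterval seconds between sets, >= 0
#' @exportClass Prescription
setClass("Prescription", representation(
  exerciseType = "character", duration = "numeric",
  intensity = "numeric", restInterval = "numeric"))

setValidity("Prescription", function(object) {
  msg <- NULL
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0 minutes")
  if (object@intensity < 0 || object@intensity > 1)
    msg <- c(msg, "intensity must lie in [0, 1]")
  if (object@restInterval < 0) msg <- c(msg, "restInterval must be >= 0 s")
  if (is.null(msg)) TRUE else msg
})

#' UserState: the observation the intervention policy sees
#'
#' @slot heartRate bpm
#' @slot hrv ms (RMSSD-like summary)
#' @slot gsr microsiemens
#' @slot muscleActivation in [0, 1]
#' @slot fatigueIndex in [0, 1]
#' @slot age years
#' @slot fitness historical fitness summary (VO2max, mL/kg/min)
#' @exportClass UserState
setClass("UserState", representation(
  heartRate = "numeric", hrv = "numeric", gsr = "numeric",
  muscleActivation = "numeric", fatigueIndex = "numeric",
  age = "numeric", fitness = "numeric"))

setValidity("UserState", function(object) {
  msg <- NULL
  vals <- c(object@heartRate, object@hrv, object@gsr,
            object@muscleActivation, object@fatigueIndex, object@age,
            object@fitness)
  if (any(!is.finite(vals))) msg <- c(msg, "all fields must be finite")
  if (object@fatigueIndex < 0 || object@fatigueIndex > 1)
    msg <- c(msg, "fatigueIndex must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' GoalSpec: weighted health-goal objective
#'
#' The goal loss is \eqn{L = w_1 f_{muscle} + w_2 f_{fatloss} +
#' w_3 f_{fatigue}}; weights live on the simplex. Component functions take
#' (prescription, state, subject) and return a finite scalar; \code{NULL}
#' components use the package defaults (negative expected
#' strength-adaptation increment, negative expected energy expenditure,
#' predicted end-of-session fatigue).
#'
#' @slot weights numeric(3), nonnegative, summing to 1
#' @slot targetHr bpm
#' @slot components named list(fMuscle, fFatloss, fFatigue) of functions
#'   (possibly empty to use defaults)
#' @exportClass GoalSpec
setClass("GoalSpec", representation(
  weights = "numeric", targetHr = "numeric", components = "list"))

setValidity("GoalSpec", function(object) {
  msg <- NULL
  if (length(object@weights) != 3L ||
      abs(sum(object@weights) - 1) > 1e-9 || any(object@weights < 0))
    msg <- c(msg, "weights must be nonnegative and sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' PpoConfig: proximal-policy-optimisation hyperparameters
#'
#' @slot clip surrogate clipping threshold epsilon, in (0, 1)
#' @slot gamma discount, in (0, 1]
#' @slot gaeLambda generalised-advantage-estimation lambda
#' @slot lr Adam learning rate
#' @slot epochs gradient epochs per policy update
#' @slot smoothness prescription-change penalty weight lambda, >= 0
#' @slot entropy entropy-bonus coefficient
#' @exportClass PpoConfig
setClass("PpoConfig", representation(
  clip = "numeric", gamma = "numeric", gaeLambda = "numeric",
  lr = "numeric", epochs = "numeric", smoothness = "numeric",
  entropy = "numeric"))

setValidity("PpoConfig", function(object) {
  msg <- NULL
  if (object@clip <= 0 || object@clip >= 1)
    msg <- c(msg, "clip must lie in (0, 1)")
  if (object@gamma <= 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in (0, 1]")
  if (object@smoothness < 0) msg <- c(msg, "smoothness must be >= 0")
  if (is.null(msg)) TRUE else msg
})
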