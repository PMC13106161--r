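#' @name accessors
#' @title Accessors for wearHAR S4 containers
#' @description Accessor generics and methods for the package's central
#'   containers: slot access goes through these, never through \code{@}.
#' @param x an object
#' @param object an object (for show methods)
#' @return the accessed component
NULL

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "SensorStream",
          function(x) assay(x, "signal"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setMethod("missingMask", "SensorStream",
          function(x) assay(x, "missing"))

#' @rdname accessors
#' @export
setGeneric("streamTimes", function(x) standardGeneric("streamTimes"))
#' @rdname accessors
#' @export
setMethod("streamTimes", "SensorStream",
          function(x) colData(x)$time)

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setMethod("sampleLabels", "SensorStream",
          function(x) colData(x)$label)

#' @rdname accessors
#' @export
setGeneric("nominalRate", function(x) standardGeneric("nominalRate"))
#' @rdname accessors
#' @export
setMethod("nominalRate", "SensorStream",
          function(x) metadata(x)$nominal_rate)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "SensorStream",
          function(x) as.character(rowData(x)$channel))
#' @rdname accessors
#' @export
setMethod("channelNames", "FeatureWindows", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setMethod("placements", "SensorStream",
          function(x) as.character(rowData(x)$placement))

#' @rdname accessors
#' @export
setGeneric("scriptSegments", function(x) standardGeneric("scriptSegments"))
#' @rdname accessors
#' @export
setMethod("scriptSegments", "ActionScript", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("windowArray", function(x) standardGeneric("windowArray"))
#' @rdname accessors
#' @export
setMethod("windowArray", "FeatureWindows", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setMethod("windowLabels", "FeatureWindows", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("windowSubjects", function(x) standardGeneric("windowSubjects"))
#' @rdname accessors
#' @export
setMethod("windowSubjects", "FeatureWindows", function(x) x@subject)

#' @rdname accessors
#' @export
setGeneric("normStats", function(x) standardGeneric("normStats"))
#' @rdname accessors
#' @export
setMethod("normStats", "FeatureWindows",
          function(x) list(center = x@normCenter, scale = x@normScale))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setMethod("nWindows", "FeatureWindows", function(x) dim(x@windows)[3])

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setMethod("graphNodes", "SkeletonGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "SkeletonGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("alignmentPath", function(x) standardGeneric("alignmentPath"))
#' @rdname accessors
#' @export
setMethod("alignmentPath", "DtwAlignment", function(x) x@path)

#' @rdname accessors
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
#' @rdname accessors
#' @export
setMethod("totalCost", "DtwAlignment", function(x) x@totalCost)

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
#' @rdname accessors
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))
#' @rdname accessors
#' @export
setMethod("overallAccuracy", "EvalReport", function(x) x@accuracy)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("goalWeights", function(x) standardGeneric("goalWeights"))
#' @rdname accessors
#' @export
setMethod("goalWeights", "VirtualSubject", function(x) x@goalWeights)
#' @rdname accessors
#' @export
setMethod("goalWeights", "GoalSpec", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("intensityOf", function(x) standardGeneric("intensityOf"))
#' @rdname accessors
#' @export
setMethod("intensityOf", "Prescription", function(x) x@intensity)

#' @rdname accessors
#' @export
setGeneric("restIntervalOf", function(x) standardGeneric("restIntervalOf"))
#' @rdname accessors
#' @export
setMethod("restIntervalOf", "Prescription", function(x) x@restInterval)

#' @rdname accessors
#' @export
setGeneric("updateDelta", function(x) standardGeneric("updateDelta"))
#' @rdname accessors
#' @export
setMethod("updateDelta", "ClientUpdate", function(x) x@delta)

#' @rdname accessors
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))
#' @rdname accessors
#' @export
setMethod("sampleCount", "ClientUpdate", function(x) x@nSamples)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "HarModel", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setMethod("modelConfig", "HarModel", function(x) x@config)

## -- show methods ------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("show", "SensorStream", function(object) {
  tt <- streamTimes(object)
  cat(sprintf("SensorStream: %d channels x %d samples, %.1f s @ %g Hz\n",
              nrow(object), ncol(object),
              if (length(tt)) diff(range(tt)) else 0,
              nominalRate(object)))
  cat("  channels:", paste(utils::head(channelNames(object), 6),
                           collapse = ", "),
      if (nrow(object) > 6) "..." else "", "\n")
  mis <- mean(missingMask(object))
  if (mis > 0) cat(sprintf("  missing: %.1f%% of samples\n", 100 * mis))
  lab <- sampleLabels(object)
  if (!is.null(lab))
    cat("  labels:", paste(unique(lab), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "ActionScript", function(object) {
  seg <- object@segments
  cat(sprintf("ActionScript: %d segments, %.1f s total\n",
              nrow(seg), sum(seg$duration)))
  for (i in seq_len(min(nrow(seg), 8)))
    cat(sprintf("  %-11s %6.1f s  intensity %.2f\n",
                seg$label[i], seg$duration[i], seg$intensity[i]))
  if (nrow(seg) > 8) cat("  ...\n")
})

#' @rdname accessors
#' @export
setMethod("show", "VirtualSubject", function(object) {
  cat(sprintf(
    "VirtualSubject: age %g, VO2max %.1f mL/kg/min, %g reps, rest HR %g bpm\n",
    object@age, object@vo2max, object@enduranceReps, object@restingHr))
  cat(sprintf("  fatigue %.2f, goal weights (%.2f, %.2f, %.2f), target HR %g\n",
              object@fatigue, object@goalWeights[1], object@goalWeights[2],
              object@goalWeights[3], object@targetHr))
})

#' @rdname accessors
#' @export
setMethod("show", "FeatureWindows", function(object) {
  d <- dim(object@windows)
  cat(sprintf("FeatureWindows: %d windows of %d x %d (T x D) @ %g Hz\n",
              d[3], d[1], d[2], object@rate))
  cat("  classes:", paste(levels(object@labels), collapse = ", "), "\n")
  cat("  subjects:", length(unique(object@subject)),
      if (length(object@normCenter)) " (Z-scored)" else "", "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes (%s), %d edges + self-loops\n",
              length(object@nodes), paste(object@nodes, collapse = ", "),
              (sum(object@adjacency != 0) - length(object@nodes)) / 2))
})

#' @rdname accessors
#' @export
setMethod("show", "DtwAlignment", function(object) {
  cat(sprintf("DtwAlignment: %d x %d, path length %d, total cost %.4g\n",
              nrow(object@costMatrix), ncol(object@costMatrix),
              nrow(object@path), object@totalCost))
})

#' @rdname accessors
#' @export
setMethod("show", "HarModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "HarModel: Transformer-GCN, d_model %d, %d heads, %d encoder layer(s)\n",
    cfg$dModel, cfg$nHeads, cfg$nLayers))
  cat(sprintf("  %d classes (%s); %s\n", length(object@classes),
              paste(object@classes, collapse = ", "),
              if (object@trained) "trained" else "untrained"))
})

#' @rdname accessors
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: overall accuracy %.2f%%\n", object@accuracy))
  print(object@perClass, row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("show", "Prescription", function(object) {
  cat(sprintf(
    "Prescription: %s, %.0f min @ intensity %.2f, rest %.0f s\n",
    object@exerciseType, object@duration, object@intensity,
    object@restInterval))
})

#' @rdname accessors
#' @export
setMethod("show", "UserState", function(object) {
  cat(sprintf(
    "UserState: HR %.0f bpm, HRV %.0f ms, GSR %.2f uS, fatigue %.2f\n",
    object@heartRate, object@hrv, object@gsr, object@fatigueIndex))
})

#' @rdname accessors
#' @export
setMethod("show", "ClientUpdate", function(object) {
  cat(sprintf("ClientUpdate: client %s, round %d, %d params, n = %d\n",
              object@clientId, as.integer(object@round),
              length(object@delta), as.integer(object@nSamples)))
})
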