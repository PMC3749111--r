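#' Accessors
#'
#' Small accessor generics for the package's S4 containers; slots are never
#' meant to be reached with `@` from user code.
#'
#' @param object an ecogtraj S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("markerMatrix", function(object) standardGeneric("markerMatrix"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("envelopeMatrix", function(object) standardGeneric("envelopeMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureChannels", function(object) standardGeneric("featureChannels"))
#' @rdname accessors
#' @export
setGeneric("featureBands", function(object) standardGeneric("featureBands"))
#' @rdname accessors
#' @export
setGeneric("normalizationStats", function(object) standardGeneric("normalizationStats"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("modelBias", function(object) standardGeneric("modelBias"))
#' @rdname accessors
#' @export
setGeneric("activeColumns", function(object) standardGeneric("activeColumns"))
#' @rdname accessors
#' @export
setGeneric("trialIntervals", function(object) standardGeneric("trialIntervals"))
#' @rdname accessors
#' @export
setGeneric("excludedTrials", function(object) standardGeneric("excludedTrials"))
#' @rdname accessors
#' @export
setGeneric("perTrialScores", function(object) standardGeneric("perTrialScores"))
#' @rdname accessors
#' @export
setGeneric("aggregateScores", function(object) standardGeneric("aggregateScores"))
#' @rdname accessors
#' @export
setGeneric("jointAngles", function(object) standardGeneric("jointAngles"))

#' @rdname accessors
#' @export
setMethod("signalMatrix", "RawSession", function(object) object@signal)
#' @rdname accessors
#' @export
setMethod("markerMatrix", "RawSession", function(object) object@markers)
#' @rdname accessors
#' @export
setMethod("channelLabels", "RawSession", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "RawSession", function(object) object@fsSignal)
#' @rdname accessors
#' @export
setMethod("samplingRate", "FeatureSeries", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "JointAngleSeries", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("envelopeMatrix", "FeatureSeries", function(object) object@envelopes)
#' @rdname accessors
#' @export
setMethod("featureChannels", "FeatureSeries", function(object) object@channelOfFeature)
#' @rdname accessors
#' @export
setMethod("featureBands", "FeatureSeries", function(object) object@bandOfFeature)
#' @rdname accessors
#' @export
setMethod("channelLabels", "FeatureSeries", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("normalizationStats", "FeatureSeries", function(object)
  list(mu = object@mu, sigma = object@sigma, statsWindow = object@statsWindow))
#' @rdname accessors
#' @export
setMethod("modelWeights", "DecoderModel", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("modelBias", "DecoderModel", function(object) object@w0)
#' @rdname accessors
#' @export
setMethod("activeColumns", "DecoderModel", function(object) object@activeSet)
#' @rdname accessors
#' @export
setMethod("trialIntervals", "TrialSet", function(object) object@intervals)
#' @rdname accessors
#' @export
setMethod("excludedTrials", "TrialSet", function(object) object@excluded)
#' @rdname accessors
#' @export
setMethod("perTrialScores", "EvaluationReport", function(object) object@perTrial)
#' @rdname accessors
#' @export
setMethod("aggregateScores", "EvaluationReport", function(object) object@aggregate)
#' @rdname accessors
#' @export
setMethod("jointAngles", "JointAngleSeries", function(object) object@angles)

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  %d bands: %s\n", nrow(object@bandEdges),
              paste(sprintf("%s %g-%g Hz", object@bandNames,
                            object@bandEdges[, 1], object@bandEdges[, 2]),
                    collapse = ", ")))
  cat(sprintf("  bandpass order %d (%s), envelope LP %g Hz order %d, fsOut %g Hz\n",
              object@bpOrder, object@filterMode, object@lpCutoff,
              object@lpOrder, object@fsOut))
  cat(sprintf("  decoder: m = %d lags, dt = %g s; normalization %s; stride %d\n",
              object@nLags, object@lagStep, object@normalization,
              object@designStride))
  cat(sprintf("  segmentation: %g%% of max speed, minGap %g s, minDuration %g s\n",
              100 * object@velocityThresholdFraction, object@minGap,
              object@minDuration))
  invisible(object)
})

setMethod("show", "RawSession", function(object) {
  cat(sprintf("RawSession: %d channels x %d samples at %g Hz (%.1f s)\n",
              ncol(object@signal), nrow(object@signal), object@fsSignal,
              nrow(object@signal) / object@fsSignal))
  if (is.null(object@markers)) {
    cat("  markers: none\n")
  } else {
    cat(sprintf("  markers: %d samples at %g Hz (shoulder/elbow/wrist xyz)\n",
                nrow(object@markers), object@fsMarkers))
  }
  invisible(object)
})

setMethod("show", "FeatureSeries", function(object) {
  cat(sprintf("FeatureSeries: %d samples x %d features at %g Hz\n",
              nrow(object@envelopes), ncol(object@envelopes), object@fs))
  cat(sprintf("  %d channels x %d bands; stats window %d samples",
              length(object@channelLabels), length(object@bandNames),
              length(object@statsWindow)))
  if (length(object@droppedFeatures))
    cat(sprintf("; %d zero-variance features dropped", length(object@droppedFeatures)))
  cat("\n")
  invisible(object)
})

setMethod("show", "DecoderModel", function(object) {
  cat(sprintf("DecoderModel '%s': %d/%d active columns, w0 = %.4g\n",
              if (length(object@target)) object@target else "?",
              length(object@activeSet), length(object@weights), object@w0))
  cat(sprintf("  %d iterations, stop: %s, beta = %.4g\n",
              object@nItersRun, object@earlyStopReason, object@beta))
  invisible(object)
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trials at %g Hz", nrow(object@intervals), object@fs))
  if (nrow(object@intervals)) {
    dur <- (object@intervals[, 2] - object@intervals[, 1]) / object@fs
    cat(sprintf(", durations %.1f-%.1f s", min(dur), max(dur)))
  }
  if (nrow(object@excluded)) cat(sprintf("; %d excluded", nrow(object@excluded)))
  cat("\n")
  invisible(object)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (band: %s)\n", object@bandCondition))
  print(object@aggregate, digits = 3)
  invisible(object)
})
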