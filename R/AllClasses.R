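#' @import methods
#' @importFrom stats approx cor fft filter median quantile rnorm runif sd var
#' @importFrom utils modifyList read.csv write.csv head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## Canonical sensorimotor-rhythm band edges (Hz).  The delta band needs an
## explicit lower edge for a bandpass design; 0.5 Hz removes drift while
## keeping movement-locked slow potentials.
.defaultBandEdges <- function() {
  m <- matrix(c(0.5, 4,
                4,   8,
                8,  14,
                14, 20,
                20, 30,
                30, 50,
                50, 90), ncol = 2, byrow = TRUE)
  dimnames(m) <- list(c("delta", "theta", "alpha", "beta1", "beta2",
                        "gamma1", "gamma2"),
                      c("low", "high"))
  m
}

#' Pipeline configuration
#'
#' Holds every numeric constant of the preprocessing and decoding chain.  The
#' defaults reproduce the published analysis: seven sensorimotor-rhythm bands
#' (delta 0.5--4 Hz through gamma2 50--90 Hz), 4th-order Butterworth bandpass
#' filters, rectification followed by a 2nd-order 2.2 Hz low-pass smoother,
#' downsampling to 100 Hz, z-scoring, and a lagged linear decoder using the
#' past second of envelopes (`nLags = 100` lags of `lagStep = 0.01` s).
#'
#' @slot bandEdges numeric matrix (bands x 2), low/high edge in Hz.
#' @slot bandNames character, one label per band.
#' @slot bpOrder integer, Butterworth bandpass order.
#' @slot lpCutoff numeric, envelope smoother cutoff (Hz).
#' @slot lpOrder integer, envelope smoother order.
#' @slot fsOut numeric, feature sampling rate after downsampling (Hz).
#' @slot nLags integer, number of past samples per feature in the decoder.
#' @slot lagStep numeric, lag spacing in seconds (must equal `1/fsOut`).
#' @slot velocityThresholdFraction numeric, trial-boundary threshold as a
#'   fraction of maximum tangential velocity.
#' @slot velocitySmoothCutoff numeric, causal low-pass cutoff (Hz) applied to
#'   the speed series before thresholding.
#' @slot minGap numeric, bursts closer than this (s) are merged.
#' @slot minDuration numeric, intervals shorter than this (s) are dropped.
#' @slot filterMode character, `"causal"` (default) or `"zero-phase"`.
#' @slot normalization character, `"foldwise"` (z-score statistics from
#'   training trials only; default) or `"session"` (whole-session statistics).
#' @slot maxIter,pruneThreshold,validationFraction,patience,tolerance sparse
#'   regression options (see [fitSLR()]).
#' @slot designStride integer, keep every `designStride`-th training row of
#'   the lagged design (1 = all rows).
#' @slot seed integer, base seed for stochastic components.
#' @seealso [pipelineConfig()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    bandEdges = "matrix",
    bandNames = "character",
    bpOrder = "integer",
    lpCutoff = "numeric",
    lpOrder = "integer",
    fsOut = "numeric",
    nLags = "integer",
    lagStep = "numeric",
    velocityThresholdFraction = "numeric",
    velocitySmoothCutoff = "numeric",
    minGap = "numeric",
    minDuration = "numeric",
    filterMode = "character",
    normalization = "character",
    maxIter = "integer",
    pruneThreshold = "numeric",
    validationFraction = "numeric",
    patience = "integer",
    tolerance = "numeric",
    designStride = "integer",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (ncol(object@bandEdges) != 2) msgs <- c(msgs, "bandEdges must have two columns")
  if (any(object@bandEdges[, 1] >= object@bandEdges[, 2]))
    msgs <- c(msgs, "each band must have low < high edge")
  if (length(object@bandNames) != nrow(object@bandEdges))
    msgs <- c(msgs, "bandNames length must match bandEdges rows")
  if (object@bpOrder < 1L) msgs <- c(msgs, "bpOrder must be >= 1")
  if (object@lpCutoff <= 0) msgs <- c(msgs, "lpCutoff must be positive")
  if (object@fsOut <= 0) msgs <- c(msgs, "fsOut must be positive")
  if (object@nLags < 1L) msgs <- c(msgs, "nLags must be >= 1")
  if (abs(object@lagStep - 1 / object@fsOut) > 1e-9)
    msgs <- c(msgs, "lagStep must equal the feature sampling interval 1/fsOut")
  if (object@velocityThresholdFraction <= 0 || object@velocityThresholdFraction >= 1)
    msgs <- c(msgs, "velocityThresholdFraction must lie in (0, 1)")
  if (!object@filterMode %in% c("causal", "zero-phase"))
    msgs <- c(msgs, "filterMode must be 'causal' or 'zero-phase'")
  if (!object@normalization %in% c("foldwise", "session"))
    msgs <- c(msgs, "normalization must be 'foldwise' or 'session'")
  if (object@validationFraction < 0 || object@validationFraction >= 0.5)
    msgs <- c(msgs, "validationFraction must lie in [0, 0.5)")
  if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
  if (object@designStride < 1L) msgs <- c(msgs, "designStride must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a pipeline configuration
#'
#' @param bandEdges bands x 2 numeric matrix of band edges in Hz; rownames are
#'   used as band labels when `bandNames` is missing.
#' @param bandNames character vector of band labels.
#' @param bpOrder Butterworth bandpass order (default 4).
#' @param lpCutoff envelope smoother cutoff in Hz (default 2.2).
#' @param lpOrder envelope smoother order (default 2).
#' @param fsOut output feature rate in Hz (default 100).
#' @param nLags number of decoder lags m (default 100).
#' @param lagStep lag spacing in seconds (default 0.01; must equal 1/fsOut).
#' @param velocityThresholdFraction trial boundary threshold (default 0.05).
#' @param velocitySmoothCutoff speed smoother cutoff in Hz (default 5).
#' @param minGap burst merge gap in seconds (default 1).
#' @param minDuration minimum trial duration in seconds (default 2).
#' @param filterMode `"causal"` or `"zero-phase"`.
#' @param normalization `"foldwise"` or `"session"`.
#' @param maxIter,pruneThreshold,validationFraction,patience,tolerance
#'   sparse-regression fitting options (see [fitSLR()]).
#' @param designStride training-row stride for the lagged design (default 1).
#' @param seed integer seed.
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(bandEdges = .defaultBandEdges(),
                           bandNames = rownames(bandEdges),
                           bpOrder = 4L,
                           lpCutoff = 2.2,
                           lpOrder = 2L,
                           fsOut = 100,
                           nLags = 100L,
                           lagStep = 1 / fsOut,
                           velocityThresholdFraction = 0.05,
                           velocitySmoothCutoff = 5,
                           minGap = 1.0,
                           minDuration = 2.0,
                           filterMode = c("causal", "zero-phase"),
                           normalization = c("foldwise", "session"),
                           maxIter = 50L,
                           pruneThreshold = 1e12,
                           validationFraction = 0.1,
                           patience = 3L,
                           tolerance = 1e-6,
                           designStride = 1L,
                           seed = 1L) {
  bandEdges <- as.matrix(bandEdges)
  if (is.null(bandNames)) bandNames <- paste0("band", seq_len(nrow(bandEdges)))
  new("PipelineConfig",
      bandEdges = bandEdges,
      bandNames = as.character(bandNames),
      bpOrder = as.integer(bpOrder),
      lpCutoff = lpCutoff,
      lpOrder = as.integer(lpOrder),
      fsOut = fsOut,
      nLags = as.integer(nLags),
      lagStep = lagStep,
      velocityThresholdFraction = velocityThresholdFraction,
      velocitySmoothCutoff = velocitySmoothCutoff,
      minGap = minGap,
      minDuration = minDuration,
      filterMode = match.arg(filterMode),
      normalization = match.arg(normalization),
      maxIter = as.integer(maxIter),
      pruneThreshold = pruneThreshold,
      validationFraction = validationFraction,
      patience = as.integer(patience),
      tolerance = tolerance,
      designStride = as.integer(designStride),
      seed = as.integer(seed))
}

#' Raw recording session
#'
#' A synchronized pair of streams: the multichannel neural signal at
#' acquisition rate and (optionally) 3D motion-capture markers for the
#' shoulder, elbow and wrist.  Both streams start at the common cue
#' (sample-0 time lock); no cross-correlation alignment is attempted.
#'
#' @slot signal numeric matrix, time x channels.
#' @slot fsSignal numeric, signal sampling rate in Hz.
#' @slot markers numeric matrix time x 9 (shoulder xyz, elbow xyz, wrist xyz,
#'   meters) or `NULL`.
#' @slot fsMarkers numeric, marker sampling rate in Hz.
#' @slot channelLabels character, one per channel.
#' @slot t0Aligned logical, both streams start at the common cue.
#' @exportClass RawSession
setClass("RawSession",
  representation(
    signal = "matrix",
    fsSignal = "numeric",
    markers = "matrixOrNULL",
    fsMarkers = "numeric",
    channelLabels = "character",
    t0Aligned = "logical"
  ),
  prototype(markers = NULL, fsMarkers = 100, t0Aligned = TRUE)
)

setValidity("RawSession", function(object) {
  msgs <- character()
  if (anyNA(object@signal)) msgs <- c(msgs, "signal contains NA/NaN")
  if (object@fsSignal <= 0) msgs <- c(msgs, "fsSignal must be positive")
  if (length(object@channelLabels) != ncol(object@signal))
    msgs <- c(msgs, "channelLabels length must equal number of signal columns")
  if (!is.null(object@markers)) {
    if (ncol(object@markers) != 9)
      msgs <- c(msgs, "markers must have 9 columns (shoulder/elbow/wrist xyz)")
    if (object@fsMarkers <= 0) msgs <- c(msgs, "fsMarkers must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a raw session
#'
#' @param signal time x channels numeric matrix.
#' @param fsSignal sampling rate of `signal` in Hz.
#' @param markers time x 9 marker matrix (meters) or `NULL`.
#' @param fsMarkers marker sampling rate in Hz (default 100).
#' @param channelLabels channel names (default `ch1`, `ch2`, ...).
#' @param t0Aligned logical; both streams start at the common cue.
#' @return A [RawSession-class] object.
#' @export
rawSession <- function(signal, fsSignal, markers = NULL, fsMarkers = 100,
                       channelLabels = NULL, t0Aligned = TRUE) {
  signal <- as.matrix(signal)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(ncol(signal)))
  if (!is.null(markers)) markers <- as.matrix(markers)
  new("RawSession", signal = signal, fsSignal = fsSignal, markers = markers,
      fsMarkers = fsMarkers, channelLabels = as.character(channelLabels),
      t0Aligned = t0Aligned)
}

#' Z-scored band-envelope features
#'
#' The decoder's input representation: per-channel, per-band amplitude
#' envelopes at 100 Hz, z-scored with mean/sd taken over `statsWindow`
#' samples (population form, 1/N).
#'
#' @slot envelopes numeric matrix, time x features.
#' @slot fs numeric, sampling rate in Hz.
#' @slot channelOfFeature,bandOfFeature integer maps feature -> channel/band.
#' @slot bandNames,channelLabels labels used by the maps.
#' @slot mu,sigma per-feature normalization constants.
#' @slot statsWindow integer sample indices the constants were computed on.
#' @slot droppedFeatures integer indices (in the pre-drop layout) of
#'   zero-variance features removed with a warning.
#' @exportClass FeatureSeries
setClass("FeatureSeries",
  representation(
    envelopes = "matrix",
    fs = "numeric",
    channelOfFeature = "integer",
    bandOfFeature = "integer",
    bandNames = "character",
    channelLabels = "character",
    mu = "numeric",
    sigma = "numeric",
    statsWindow = "integer",
    droppedFeatures = "integer"
  )
)

setValidity("FeatureSeries", function(object) {
  F <- ncol(object@envelopes)
  msgs <- character()
  if (length(object@channelOfFeature) != F || length(object@bandOfFeature) != F)
    msgs <- c(msgs, "feature index maps must match envelope columns")
  if (length(object@mu) != F || length(object@sigma) != F)
    msgs <- c(msgs, "mu/sigma must match envelope columns")
  if (any(object@sigma <= 0)) msgs <- c(msgs, "sigma must be positive for retained features")
  if (length(msgs)) msgs else TRUE
})

#' Lagged regression design
#'
#' Design matrix pairing each target sample with the past `nLags` samples of
#' every feature.  The first column is a constant-1 bias column; column
#' `1 + (i-1)*nLags + j` holds feature `i` at lag `j` (strictly past samples,
#' `j = 1..nLags`).  Rows exist only for target times whose full lag history
#' lies inside the valid mask.
#'
#' @slot X numeric matrix, rows x (nFeatures*nLags + 1).
#' @slot y numeric target vector.
#' @slot sampleTimes integer, target sample index of each row.
#' @slot nFeatures,nLags integer layout constants.
#' @slot featureOfColumn,lagOfColumn integer maps, 0 for the bias column.
#' @slot channelOfFeature,bandOfFeature optional feature metadata.
#' @slot bandNames,channelLabels optional labels.
#' @slot stride integer, training-row stride used.
#' @exportClass LaggedDesign
setClass("LaggedDesign",
  representation(
    X = "matrix",
    y = "numeric",
    sampleTimes = "integer",
    nFeatures = "integer",
    nLags = "integer",
    featureOfColumn = "integer",
    lagOfColumn = "integer",
    channelOfFeature = "integer",
    bandOfFeature = "integer",
    bandNames = "character",
    channelLabels = "character",
    stride = "integer"
  )
)

#' Fitted sparse linear decoder
#'
#' Weights of the lagged linear model fitted by automatic relevance
#' determination.  Pruned columns carry exactly zero weight and never enter a
#' prediction.
#'
#' @slot w0 numeric bias.
#' @slot weights numeric, length nFeatures*nLags; zero outside `activeSet`.
#' @slot alpha numeric relevance precisions (`Inf` for pruned columns).
#' @slot beta numeric noise precision.
#' @slot activeSet integer retained column indices (into `weights`).
#' @slot nItersRun integer.
#' @slot earlyStopReason character, one of `"validation_rise"`, `"max_iter"`,
#'   `"converged"`.
#' @slot nFeatures,nLags layout constants.
#' @slot channelOfFeature,bandOfFeature,bandNames,channelLabels feature
#'   metadata for sparsity reporting (may be empty).
#' @slot target character, name of the decoded variable.
#' @slot config list, snapshot of the preprocessing configuration the model
#'   was trained under (prediction refuses mismatched preprocessing).
#' @slot trace data.frame per-iteration fitting trace (`iter`, `train_mse`,
#'   `val_mse`, `active`, `evidence`).
#' @exportClass DecoderModel
setClass("DecoderModel",
  representation(
    trace = "data.frame",
    w0 = "numeric",
    weights = "numeric",
    alpha = "numeric",
    beta = "numeric",
    activeSet = "integer",
    nItersRun = "integer",
    earlyStopReason = "character",
    nFeatures = "integer",
    nLags = "integer",
    channelOfFeature = "integer",
    bandOfFeature = "integer",
    bandNames = "character",
    channelLabels = "character",
    target = "character",
    config = "list"
  )
)

setValidity("DecoderModel", function(object) {
  msgs <- character()
  if (length(object@weights) != object@nFeatures * object@nLags)
    msgs <- c(msgs, "weights length must equal nFeatures*nLags")
  inactive <- setdiff(seq_along(object@weights), object@activeSet)
  if (length(inactive) && any(object@weights[inactive] != 0))
    msgs <- c(msgs, "pruned columns must have weight exactly 0")
  if (object@beta <= 0) msgs <- c(msgs, "noise precision beta must be positive")
  if (any(object@alpha[object@activeSet] <= 0))
    msgs <- c(msgs, "alpha must be positive on the active set")
  if (length(msgs)) msgs else TRUE
})

#' Trial segmentation result
#'
#' Intervals `[start, end)` on the 100 Hz grid delimited by the
#' 5%-of-maximum tangential-velocity rule, plus excluded intervals with
#' reasons.
#'
#' @slot intervals integer matrix n x 2 (`start`, `end`), 1-based, end
#'   exclusive, sorted and disjoint.
#' @slot excluded data.frame with columns `start`, `end`, `reason`.
#' @slot fs numeric grid rate in Hz.
#' @slot sourceSpeed numeric, the speed series segmentation ran on.
#' @slot thresholdFraction numeric.
#' @exportClass TrialSet
setClass("TrialSet",
  representation(
    intervals = "matrix",
    excluded = "data.frame",
    fs = "numeric",
    sourceSpeed = "numeric",
    thresholdFraction = "numeric"
  )
)

setValidity("TrialSet", function(object) {
  iv <- object@intervals
  msgs <- character()
  if (ncol(iv) != 2) msgs <- c(msgs, "intervals must have two columns")
  if (nrow(iv) > 1) {
    if (is.unsorted(iv[, 1])) msgs <- c(msgs, "intervals must be sorted")
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) msgs <- c(msgs, "intervals must be disjoint")
  }
  if (nrow(iv) && any(iv[, 2] <= iv[, 1])) msgs <- c(msgs, "intervals must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validated evaluation report
#'
#' @slot perTrial data.frame: `trial`, `variable`, `cc`, `nrmse`,
#'   `duration_s`, `n_scored`.
#' @slot aggregate data.frame: per-variable `mean_cc`, `sem_cc`,
#'   `mean_nrmse`, `sem_nrmse`, `n_trials`.
#' @slot bandCondition character, band label when the design was restricted
#'   to a single band, else `"all"`.
#' @slot config list snapshot.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    perTrial = "data.frame",
    aggregate = "data.frame",
    bandCondition = "character",
    config = "list"
  )
)

#' Arm geometry
#'
#' @slot lUpper numeric, shoulder-elbow segment length (m).
#' @slot lFore numeric, elbow-wrist segment length (m).
#' @exportClass ArmGeometry
setClass("ArmGeometry", representation(lUpper = "numeric", lFore = "numeric"))

setValidity("ArmGeometry", function(object) {
  if (object@lUpper <= 0 || object@lFore <= 0) "segment lengths must be positive" else TRUE
})

#' Construct an arm geometry
#' @param lUpper shoulder-elbow length in meters.
#' @param lFore elbow-wrist length in meters.
#' @return An [ArmGeometry-class] object.
#' @export
armGeometry <- function(lUpper = 0.30, lFore = 0.25) {
  new("ArmGeometry", lUpper = lUpper, lFore = lFore)
}

#' Joint-angle time series
#'
#' Angles of the 4-DOF shoulder-elbow model: q1 shoulder
#' abduction/adduction, q2 shoulder flexion/extension, q3 shoulder
#' external/internal rotation, q4 elbow flexion/extension (q4 = pi at full
#' extension).  Radians.
#'
#' @slot angles numeric matrix time x 4, columns `q1`..`q4`.
#' @slot fs numeric sampling rate in Hz.
#' @exportClass JointAngleSeries
setClass("JointAngleSeries", representation(angles = "matrix", fs = "numeric"))

setValidity("JointAngleSeries", function(object) {
  msgs <- character()
  if (ncol(object@angles) != 4) msgs <- c(msgs, "angles must have 4 columns (q1..q4)")
  q4 <- object@angles[, 4]
  if (any(is.finite(q4) & (q4 <= 0 | q4 > pi + 1e-9)))
    msgs <- c(msgs, "q4 must lie in (0, pi]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a joint-angle series
#' @param angles time x 4 matrix (q1..q4, radians) .
#' @param fs sampling rate in Hz.
#' @return A [JointAngleSeries-class] object.
#' @export
jointAngleSeries <- function(angles, fs = 100) {
  angles <- as.matrix(angles)
  colnames(angles) <- c("q1", "q2", "q3", "q4")
  new("JointAngleSeries", angles = angles, fs = fs)
}

#' Synthetic-session specification
#'
#' Conditions of the emulated block-transport experiment: repeated
#' reach-and-transport cycles of three blocks around the corners of a
#' 25 cm x 25 cm square at a self-paced ~17 s per cycle, recorded as
#' multichannel 1000 Hz signals whose within-band amplitude envelopes carry a
#' lagged linear relationship to the arm kinematics plus noise.
#'
#' @slot nChannels integer (60 for the large grid, 15 for the small montage).
#' @slot nTrials integer number of transport cycles.
#' @slot trialDuration numeric, seconds per cycle.
#' @slot restDuration numeric, near-zero-velocity seconds between cycles.
#' @slot squareSide numeric, task square side (m).
#' @slot liftHeight numeric, block lift height (m).
#' @slot informativeFraction numeric fraction of (channel, band) pairs whose
#'   envelope encodes kinematics.
#' @slot trueLag numeric seconds by which the envelope leads the kinematics.
#' @slot envelopeSnr numeric, signal/noise variance ratio in the envelope
#'   domain (0 = no kinematic signal).
#' @slot modulationDepth numeric relative envelope modulation depth.
#' @slot carrierType character, `"band_noise"` or `"sinusoid"`.
#' @slot pinkAmplitude numeric, broadband 1/f noise RMS relative to one
#'   carrier's RMS.
#' @slot fsSignal,fsMarkers numeric rates (Hz).
#' @slot lUpper,lFore numeric arm-segment lengths (m).
#' @slot seed integer.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    nChannels = "integer",
    nTrials = "integer",
    trialDuration = "numeric",
    restDuration = "numeric",
    squareSide = "numeric",
    liftHeight = "numeric",
    informativeFraction = "numeric",
    trueLag = "numeric",
    envelopeSnr = "numeric",
    modulationDepth = "numeric",
    carrierType = "character",
    pinkAmplitude = "numeric",
    fsSignal = "numeric",
    fsMarkers = "numeric",
    lUpper = "numeric",
    lFore = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msgs <- character()
  if (object@nChannels < 2L) msgs <- c(msgs, "need at least 2 channels")
  if (object@nTrials < 1L) msgs <- c(msgs, "need at least 1 trial")
  if (object@trialDuration <= 0 || object@restDuration < 0)
    msgs <- c(msgs, "durations must be positive")
  if (object@informativeFraction < 0 || object@informativeFraction > 1)
    msgs <- c(msgs, "informativeFraction must lie in [0, 1]")
  if (object@envelopeSnr < 0) msgs <- c(msgs, "envelopeSnr must be >= 0")
  if (!object@carrierType %in% c("band_noise", "sinusoid"))
    msgs <- c(msgs, "carrierType must be 'band_noise' or 'sinusoid'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation specification
#'
#' Defaults emulate the published study conditions: 60 channels at 1000 Hz,
#' nine ~17 s transport cycles around a 0.25 m square, markers at 100 Hz.
#'
#' @param nChannels,nTrials,trialDuration,restDuration,squareSide,liftHeight
#'   task geometry and session layout; see [SimulationSpec-class].
#' @param informativeFraction,trueLag,envelopeSnr,modulationDepth,carrierType,pinkAmplitude
#'   envelope coupling model; see [SimulationSpec-class].
#' @param fsSignal,fsMarkers sampling rates in Hz.
#' @param lUpper,lFore arm-segment lengths in meters.
#' @param seed integer seed; fixed seed gives bit-identical sessions.
#' @return A [SimulationSpec-class] object.
#' @export
simulationSpec <- function(nChannels = 60L, nTrials = 9L,
                           trialDuration = 17, restDuration = 5,
                           squareSide = 0.25, liftHeight = 0.10,
                           informativeFraction = 0.2, trueLag = 0.15,
                           envelopeSnr = 10, modulationDepth = 0.4,
                           carrierType = c("band_noise", "sinusoid"),
                           pinkAmplitude = 0.1,
                           fsSignal = 1000, fsMarkers = 100,
                           lUpper = 0.30, lFore = 0.25, seed = 1L) {
  new("SimulationSpec",
      nChannels = as.integer(nChannels), nTrials = as.integer(nTrials),
      trialDuration = trialDuration, restDuration = restDuration,
      squareSide = squareSide, liftHeight = liftHeight,
      informativeFraction = informativeFraction, trueLag = trueLag,
      envelopeSnr = envelopeSnr, modulationDepth = modulationDepth,
      carrierType = match.arg(carrierType), pinkAmplitude = pinkAmplitude,
      fsSignal = fsSignal, fsMarkers = fsMarkers,
      lUpper = lUpper, lFore = lFore, seed = as.integer(seed))
}

#' Ground truth of a synthetic session
#'
#' @slot angles [JointAngleSeries-class] driving the simulation.
#' @slot informative data.frame: `channel`, `band`, one row per informative
#'   (channel, band) pair.
#' @slot couplings list of per-pair coupling descriptions (kinematic variable
#'   indices, weights, lag).
#' @slot cleanEnvelopes numeric matrix time x (channels*bands) at the marker
#'   rate, the noise-free envelopes before modulation noise.
#' @slot trueLag numeric seconds.
#' @slot clippedCount integer, samples clipped to keep envelopes nonnegative.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    angles = "JointAngleSeries",
    informative = "data.frame",
    couplings = "list",
    cleanEnvelopes = "matrix",
    trueLag = "numeric",
    clippedCount = "integer"
  )
)
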