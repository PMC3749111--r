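## Leave-one-out cross-validation over trials with Pearson correlation and
## normalized RMSE scoring.  One independent decoder per target variable per
## fold; normalization statistics and the early-stopping holdout are drawn
## from training trials only, so nothing about the held-out trial can touch
## a training fit.

#' Pearson correlation coefficient
#'
#' @param pred,actual equal-length numeric series (NA pairs dropped).
#' @return scalar in `[-1, 1]`; `NA` (flagged undefined) when either series
#'   is constant or fewer than 2 pairs remain.
#' @export
pearsonCC <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("series lengths differ")
  ok <- !is.na(pred) & !is.na(actual)
  if (sum(ok) < 2) return(NA_real_)
  p <- pred[ok]; a <- actual[ok]
  if (sd(p) == 0 || sd(a) == 0) return(NA_real_)
  cor(p, a)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the spread of the actual series: its range (max - min,
#' default — the common convention in trajectory decoding) or its standard
#' deviation.
#'
#' @param pred,actual equal-length numeric series (NA pairs dropped).
#' @param normalization `"range"` or `"sd"`.
#' @return nonnegative scalar; `NA` when the actual series is constant.
#' @export
nrmse <- function(pred, actual, normalization = c("range", "sd")) {
  normalization <- match.arg(normalization)
  if (length(pred) != length(actual)) stop("series lengths differ")
  ok <- !is.na(pred) & !is.na(actual)
  if (sum(ok) < 2) return(NA_real_)
  p <- pred[ok]; a <- actual[ok]
  denom <- if (normalization == "range") max(a) - min(a) else sd(a)
  if (denom == 0) return(NA_real_)
  sqrt(mean((p - a)^2)) / denom
}

.configSnapshot <- function(config) {
  list(bandEdges = unname(config@bandEdges), bandNames = config@bandNames,
       bpOrder = config@bpOrder, lpCutoff = config@lpCutoff,
       lpOrder = config@lpOrder, fsOut = config@fsOut,
       nLags = config@nLags, lagStep = config@lagStep,
       filterMode = config@filterMode, normalization = config@normalization,
       designStride = config@designStride)
}

#' Standard decoding targets of a session
#'
#' The ten decoded variables: joint angles q1..q4 (from inverse kinematics
#' of the markers) and the elbow/wrist xyz coordinates, all at the marker
#' rate.
#'
#' @param session a [RawSession-class] with markers.
#' @param geom an [ArmGeometry-class]; estimated from the markers when
#'   omitted.
#' @return time x 10 matrix with columns `q1..q4`, `elbow_x..z`,
#'   `wrist_x..z`.
#' @export
decodingTargets <- function(session, geom = NULL) {
  m <- markerMatrix(session)
  if (is.null(m)) stop("session has no markers")
  if (is.null(geom)) geom <- estimateArmGeometry(m)
  q <- inverseKinematics(m[, 1:3], m[, 4:6], m[, 7:9], geom,
                         fs = session@fsMarkers)
  out <- cbind(jointAngles(q), m[, 4:6], m[, 7:9])
  colnames(out) <- c("q1", "q2", "q3", "q4",
                     "elbow_x", "elbow_y", "elbow_z",
                     "wrist_x", "wrist_y", "wrist_z")
  out
}

.restrictBand <- function(raw, band) {
  bi <- match(band, raw$bandNames)
  if (is.na(bi)) stop("unknown band label '", band, "'; configured bands: ",
                      paste(raw$bandNames, collapse = ", "))
  keep <- raw$bandOfFeature == bi
  raw$env <- raw$env[, keep, drop = FALSE]
  raw$channelOfFeature <- raw$channelOfFeature[keep]
  raw$bandOfFeature <- raw$bandOfFeature[keep]
  raw
}

#' Leave-one-out cross-validation on precomputed envelopes
#'
#' The fold engine behind [looCrossValidate()], operating on the
#' un-normalized envelope matrix so the target-independent filtering work is
#' shared across folds.  For each held-out trial: z-score statistics are
#' computed on training-trial samples ("foldwise", default) or the whole
#' session; one decoder per target is fit on training-trial rows; the
#' held-out trial is predicted and scored with [pearsonCC()] and [nrmse()].
#'
#' @param raw list from [rawEnvelopes()].
#' @param targets time x variables matrix of decoding targets on the same
#'   grid (see [decodingTargets()]).
#' @param trials a [TrialSet-class] on the same grid.
#' @param config a [PipelineConfig-class].
#' @param band optional band label restricting the design to that band's
#'   features.
#' @param returnModels also return the fitted per-fold models.
#' @return An [EvaluationReport-class]; with `returnModels = TRUE`, a list
#'   `report`, `models` (models indexed `[[fold]][[target]]`).
#' @export
looDecodeEnvelopes <- function(raw, targets, trials, config = pipelineConfig(),
                               band = NULL, returnModels = FALSE) {
  targets <- as.matrix(targets)
  if (is.null(colnames(targets)))
    colnames(targets) <- paste0("target", seq_len(ncol(targets)))
  if (!is.null(band)) raw <- .restrictBand(raw, band)
  iv <- trialIntervals(trials)
  k <- nrow(iv)
  if (k < 2) stop("leave-one-out needs at least 2 retained trials")
  n <- nrow(raw$env)
  if (nrow(targets) != n) stop("targets and envelopes have different lengths")
  m <- config@nLags
  vars <- colnames(targets)
  rows <- list()
  models <- vector("list", k)
  for (fold in seq_len(k)) {
    trainMask <- trialMask(trials, n, setdiff(seq_len(k), fold))
    testMask <- trialMask(trials, n, fold)
    statsWindow <- if (config@normalization == "foldwise")
      which(trainMask) else seq_len(n)
    fs <- zscoreNormalize(raw$env, statsWindow,
                          channelOfFeature = raw$channelOfFeature,
                          bandOfFeature = raw$bandOfFeature,
                          bandNames = raw$bandNames,
                          channelLabels = raw$channelLabels,
                          fs = raw$fs)
    testTimes <- .validRowTimes(testMask, m)
    if (!length(testTimes)) {
      warning("trial ", fold, " too short for the ", m,
              "-sample lag history; skipped")
      next
    }
    models[[fold]] <- vector("list", length(vars))
    names(models[[fold]]) <- vars
    for (v in seq_along(vars)) {
      design <- buildDesign(fs, targets[, v], trainMask, m,
                            stride = config@designStride)
      model <- fitSLR(design,
                      maxIter = config@maxIter,
                      pruneThreshold = config@pruneThreshold,
                      validationFraction = config@validationFraction,
                      patience = config@patience,
                      tolerance = config@tolerance,
                      target = vars[v],
                      config = .configSnapshot(config))
      models[[fold]][[v]] <- model
      pred <- predictSeries(model, fs, testMask)
      act <- targets[, v]
      scored <- !is.na(pred) & testMask
      rows[[length(rows) + 1L]] <- data.frame(
        trial = fold, variable = vars[v],
        cc = pearsonCC(pred[scored], act[scored]),
        nrmse = nrmse(pred[scored], act[scored]),
        duration_s = (iv[fold, 2] - iv[fold, 1]) / raw$fs,
        n_scored = sum(scored),
        stringsAsFactors = FALSE)
    }
  }
  perTrial <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(0), variable = character(0), cc = numeric(0),
               nrmse = numeric(0), duration_s = numeric(0),
               n_scored = integer(0))
  agg <- do.call(rbind, lapply(split(perTrial, perTrial$variable), function(d) {
    ccOk <- d$cc[!is.na(d$cc)]
    nrOk <- d$nrmse[!is.na(d$nrmse)]
    data.frame(variable = d$variable[1],
               mean_cc = if (length(ccOk)) mean(ccOk) else NA_real_,
               sem_cc = if (length(ccOk) > 1) sd(ccOk) / sqrt(length(ccOk)) else NA_real_,
               mean_nrmse = if (length(nrOk)) mean(nrOk) else NA_real_,
               sem_nrmse = if (length(nrOk) > 1) sd(nrOk) / sqrt(length(nrOk)) else NA_real_,
               n_trials = nrow(d),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(agg)) {
    agg <- agg[match(intersect(vars, agg$variable), agg$variable), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(variable = character(0), mean_cc = numeric(0),
                      sem_cc = numeric(0), mean_nrmse = numeric(0),
                      sem_nrmse = numeric(0), n_trials = integer(0))
  }
  report <- new("EvaluationReport", perTrial = perTrial, aggregate = agg,
                bandCondition = if (is.null(band)) "all" else band,
                config = .configSnapshot(config))
  if (returnModels) list(report = report, models = models) else report
}

#' Leave-one-out cross-validated decoding of a session
#'
#' For each held-out trial, fits one sparse lagged decoder per target
#' variable on all other trials' samples, predicts the held-out trial, and
#' scores Pearson CC and nRMSE; scores are aggregated across trials as
#' mean and SEM (sample sd / sqrt(n)).
#'
#' @param session a [RawSession-class] with markers.
#' @param trials a [TrialSet-class] on the feature grid.
#' @param targets time x variables target matrix (default:
#'   [decodingTargets()] of the session).
#' @param config a [PipelineConfig-class].
#' @param band optional band label to restrict the design to one band.
#' @param returnModels also return fitted models.
#' @return An [EvaluationReport-class] (or list with models).
#' @export
looCrossValidate <- function(session, trials, targets = NULL,
                             config = pipelineConfig(), band = NULL,
                             returnModels = FALSE) {
  if (is.null(targets)) targets <- decodingTargets(session)
  raw <- rawEnvelopes(session, config)
  n <- min(nrow(raw$env), nrow(targets))
  raw$env <- raw$env[seq_len(n), , drop = FALSE]
  targets <- as.matrix(targets)[seq_len(n), , drop = FALSE]
  looDecodeEnvelopes(raw, targets, trials, config, band = band,
                     returnModels = returnModels)
}

#' Per-band cross-validated decoding
#'
#' Repeats the leave-one-out evaluation with the design restricted to a
#' single sensorimotor rhythm, quantifying each band's individual
#' contribution.
#'
#' @param session,trials,targets,config as in [looCrossValidate()].
#' @param bands character vector of band labels (default: all configured
#'   bands).
#' @return named list of [EvaluationReport-class], one per band.
#' @export
perBandCV <- function(session, trials, targets = NULL,
                      config = pipelineConfig(),
                      bands = config@bandNames) {
  out <- lapply(bands, function(b)
    looCrossValidate(session, trials, targets, config, band = b))
  names(out) <- bands
  out
}
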