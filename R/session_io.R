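## Session, model and report I/O.  Signals travel as headered CSV/TSV or
## standard EDF (European Data Format, 16-bit); markers as headered CSV/TSV
## with columns time_s, sx..sz, ex..ez, wx..wz in meters (readers accept
## mm/cm and convert).  Models are single-file JSON with base64-encoded
## IEEE-754 weight blocks so round-trips are exact.

.MODEL_FORMAT_VERSION <- "1"

.markerCols <- c("sx", "sy", "sz", "ex", "ey", "ez", "wx", "wy", "wz")

.sepOf <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Write a session to disk
#'
#' @param session a [RawSession-class].
#' @param signalPath output path for the signal (`.csv`/`.tsv` headered
#'   table with a `time_s` column, or `.edf`).
#' @param markersPath optional output path for the markers (CSV/TSV).
#' @return invisibly, the paths written.
#' @export
writeSession <- function(session, signalPath, markersPath = NULL) {
  stopifnot(is(session, "RawSession"))
  if (grepl("\\.edf$", signalPath, ignore.case = TRUE)) {
    writeEdf(signalMatrix(session), session@fsSignal,
             channelLabels(session), signalPath)
  } else {
    d <- data.frame(time_s = (seq_len(nrow(session@signal)) - 1) / session@fsSignal,
                    session@signal)
    names(d) <- c("time_s", channelLabels(session))
    write.csv(d, signalPath, row.names = FALSE)
  }
  if (!is.null(markersPath) && !is.null(session@markers)) {
    d <- data.frame(time_s = (seq_len(nrow(session@markers)) - 1) / session@fsMarkers,
                    session@markers)
    names(d) <- c("time_s", .markerCols)
    write.csv(d, markersPath, row.names = FALSE)
  }
  invisible(c(signalPath, markersPath))
}

#' Read a session from disk
#'
#' @param signalPath EDF or headered CSV/TSV signal file (CSV must carry a
#'   `time_s` column, from which the rate is inferred unless `fsSignal` is
#'   given).
#' @param markersPath optional headered CSV/TSV marker file with columns
#'   `time_s`, `sx..sz`, `ex..ez`, `wx..wz`.
#' @param fsSignal,fsMarkers override the inferred sampling rates (Hz).
#' @param markerUnits units of the marker file (`"m"`, `"cm"`, `"mm"`);
#'   converted to meters on load.
#' @param durationTol maximum allowed difference between signal and marker
#'   stream durations, in seconds (default 0.5).
#' @return A [RawSession-class].
#' @export
readSession <- function(signalPath, markersPath = NULL, fsSignal = NULL,
                        fsMarkers = NULL, markerUnits = c("m", "cm", "mm"),
                        durationTol = 0.5) {
  markerUnits <- match.arg(markerUnits)
  if (grepl("\\.edf$", signalPath, ignore.case = TRUE)) {
    e <- readEdf(signalPath)
    signal <- e$signal
    fsS <- if (is.null(fsSignal)) e$fs else fsSignal
    labels <- e$labels
  } else {
    d <- read.csv(signalPath, sep = .sepOf(signalPath), check.names = FALSE)
    if (!"time_s" %in% names(d))
      stop("schema error: signal table lacks a 'time_s' column")
    if (!all(vapply(d, is.numeric, logical(1))))
      stop("parse error: non-numeric cells in signal table")
    tcol <- d[["time_s"]]
    fsS <- if (is.null(fsSignal)) {
      if (length(tcol) < 2) stop("cannot infer sampling rate from one sample")
      1 / median(diff(tcol))
    } else fsSignal
    labels <- setdiff(names(d), "time_s")
    signal <- as.matrix(d[labels])
  }
  markers <- NULL
  fsM <- 100
  if (!is.null(markersPath)) {
    dm <- read.csv(markersPath, sep = .sepOf(markersPath), check.names = FALSE)
    missing <- setdiff(c("time_s", .markerCols), names(dm))
    if (length(missing))
      stop("schema error: marker table lacks column(s) ",
           paste(missing, collapse = ", "))
    if (!all(vapply(dm[c("time_s", .markerCols)], is.numeric, logical(1))))
      stop("parse error: non-numeric cells in marker table")
    fsM <- if (is.null(fsMarkers)) 1 / median(diff(dm$time_s)) else fsMarkers
    scale <- c(m = 1, cm = 0.01, mm = 0.001)[[markerUnits]]
    markers <- as.matrix(dm[.markerCols]) * scale
    durS <- nrow(signal) / fsS
    durM <- nrow(markers) / fsM
    if (abs(durS - durM) > durationTol)
      stop("alignment error: signal lasts ", round(durS, 3),
           " s but markers last ", round(durM, 3), " s")
  }
  rawSession(signal, fsS, markers, fsM, channelLabels = labels)
}

## ---- EDF (European Data Format), 16-bit standard subset ----------------
## One-second data records; the signal is truncated to whole records.

.padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = "-")
}

## render a number into <= 8 ASCII chars (EDF physical-range fields)
.num8 <- function(x) {
  for (d in 7:1) {
    s <- sprintf(paste0("%.", d, "g"), x)
    if (nchar(s) <= 8) return(s)
  }
  substr(s, 1, 8)
}

#' Write a multichannel signal as standard EDF
#'
#' Minimal standard-EDF writer (16-bit integers, one-second data records).
#' The signal is truncated to a whole number of records; per-channel
#' physical ranges are taken from the data.
#'
#' @param signal time x channels matrix.
#' @param fs sampling rate in Hz (integer samples per record).
#' @param labels channel labels.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEdf <- function(signal, fs, labels, path) {
  signal <- as.matrix(signal)
  ns <- ncol(signal)
  spr <- as.integer(round(fs))
  nrec <- floor(nrow(signal) / spr)
  if (nrec < 1) stop("signal shorter than one EDF data record (1 s)")
  physMin <- apply(signal, 2, min)
  physMax <- apply(signal, 2, max)
  flat <- physMax - physMin < .Machine$double.eps
  physMax[flat] <- physMin[flat] + 1
  ## the header stores the ranges as 8-char ASCII; quantize against the
  ## stored (rendered) values so writer and reader agree exactly
  physMinS <- vapply(physMin, .num8, "")
  physMaxS <- vapply(physMax, .num8, "")
  physMin <- as.numeric(physMinS)
  physMax <- as.numeric(physMaxS)
  bad <- physMax <= physMin
  if (any(bad)) { physMax[bad] <- physMin[bad] + 1; physMaxS[bad] <- vapply(physMax[bad], .num8, "") }
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8),
    .padField("synthetic", 80),
    .padField("ecogtraj session", 80),
    .padField("01.01.26", 8), .padField("00.00.00", 8),
    .padField(256 * (1 + ns), 8),
    .padField("", 44),
    .padField(nrec, 8),
    .padField("1", 8),
    .padField(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- c(
    vapply(labels, .padField, "", width = 16),
    rep(.padField("", 80), ns),
    rep(.padField("uV", 8), ns),
    vapply(physMinS, .padField, "", width = 8),
    vapply(physMaxS, .padField, "", width = 8),
    rep(.padField(digMin, 8), ns),
    rep(.padField(digMax, 8), ns),
    rep(.padField("", 80), ns),
    rep(.padField(spr, 8), ns),
    rep(.padField("", 32), ns))
  writeChar(paste(fields, collapse = ""), con,
            nchars = 256 * ns, eos = NULL)
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((signal[idx, ch] - physMin[ch]) * gain[ch]) + digMin
      dig <- pmax(digMin, pmin(digMax, dig))
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a standard EDF file
#'
#' Counterpart of [writeEdf()]: standard EDF, 16-bit samples.  All channels
#' must share one sampling rate.
#'
#' @param path EDF file path.
#' @return list with `signal` (time x channels), `fs`, `labels`.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: bad signal count")
  if (hdrBytes != 256 * (1 + ns)) stop("corrupt EDF header: size mismatch")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1)
    stop("unsupported EDF: channels with differing sampling rates")
  fs <- spr[1] / recDur
  total <- nrec * spr[1]
  signal <- matrix(NA_real_, total, ns)
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(dig) < spr[ch]) stop("truncated EDF: record ", r, " incomplete")
      idx <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      signal[idx, ch] <- physMin[ch] + (dig - digMin[ch]) * gain[ch]
    }
  }
  list(signal = signal, fs = fs, labels = labels)
}

## ---- model serialization ------------------------------------------------

.encodeDoubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
.decodeDoubles <- function(s) readBin(jsonlite::base64_dec(s), "numeric", n = 1e8, size = 8, endian = "little")

#' Save a fitted decoder model
#'
#' Single-file JSON with the configuration snapshot and base64-encoded
#' IEEE-754 weight blocks, so reloading reproduces predictions exactly.
#'
#' @param model a [DecoderModel-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "DecoderModel"))
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    target = model@target,
    n_features = model@nFeatures,
    n_lags = model@nLags,
    w0 = .encodeDoubles(model@w0),
    beta = .encodeDoubles(model@beta),
    active_set = model@activeSet,
    weights_active = .encodeDoubles(model@weights[model@activeSet]),
    alpha_active = .encodeDoubles(model@alpha[model@activeSet]),
    channel_of_feature = model@channelOfFeature,
    band_of_feature = model@bandOfFeature,
    band_names = model@bandNames,
    channel_labels = model@channelLabels,
    n_iters_run = model@nItersRun,
    early_stop_reason = model@earlyStopReason,
    config = model@config)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Load a decoder model
#'
#' @param path JSON file written by [saveModel()].
#' @return A [DecoderModel-class].
#' @export
loadModel <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("corrupt model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$format_version))
    stop("corrupt model file: missing format_version")
  if (!identical(as.character(obj$format_version), .MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has '", obj$format_version,
         "', this package reads '", .MODEL_FORMAT_VERSION, "'")
  K <- obj$n_features * obj$n_lags
  act <- as.integer(obj$active_set)
  w <- rep(0, K)
  w[act] <- .decodeDoubles(obj$weights_active)
  alpha <- rep(Inf, K)
  alpha[act] <- .decodeDoubles(obj$alpha_active)
  cfg <- as.list(obj$config)
  if (!is.null(cfg$bandEdges)) cfg$bandEdges <- as.matrix(cfg$bandEdges)
  new("DecoderModel",
      w0 = .decodeDoubles(obj$w0), weights = w, alpha = alpha,
      beta = .decodeDoubles(obj$beta), activeSet = act,
      nItersRun = as.integer(obj$n_iters_run),
      earlyStopReason = as.character(obj$early_stop_reason),
      nFeatures = as.integer(obj$n_features), nLags = as.integer(obj$n_lags),
      channelOfFeature = as.integer(obj$channel_of_feature),
      bandOfFeature = as.integer(obj$band_of_feature),
      bandNames = as.character(obj$band_names),
      channelLabels = as.character(obj$channel_labels),
      target = as.character(obj$target), config = cfg,
      trace = data.frame())
}

## ---- feature / trial / report exports ----------------------------------

#' Export z-scored features as CSV with a JSON sidecar
#'
#' @param features a [FeatureSeries-class].
#' @param csvPath output CSV path (time x features).
#' @param sidecarPath output JSON path for mu/sigma and the feature
#'   indexing; default `csvPath` with `.json` appended.
#' @return invisibly, the paths.
#' @export
exportFeatureSeries <- function(features, csvPath,
                                sidecarPath = paste0(csvPath, ".json")) {
  stopifnot(is(features, "FeatureSeries"))
  z <- features@envelopes
  nm <- paste0(features@channelLabels[features@channelOfFeature], "_",
               features@bandNames[features@bandOfFeature])
  d <- data.frame(time_s = (seq_len(nrow(z)) - 1) / features@fs, z)
  names(d) <- c("time_s", nm)
  write.csv(d, csvPath, row.names = FALSE)
  side <- list(fs = features@fs, mu = features@mu, sigma = features@sigma,
               channel_of_feature = features@channelOfFeature,
               band_of_feature = features@bandOfFeature,
               band_names = features@bandNames,
               channel_labels = features@channelLabels,
               stats_window = range(features@statsWindow),
               dropped_features = features@droppedFeatures)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA), sidecarPath)
  invisible(c(csvPath, sidecarPath))
}

#' Export a trial set as CSV
#'
#' Columns `start_s`, `end_s`, `status`, `reason`.
#'
#' @param trials a [TrialSet-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
exportTrialSet <- function(trials, path) {
  stopifnot(is(trials, "TrialSet"))
  iv <- trials@intervals
  d <- data.frame(start_s = (iv[, 1] - 1) / trials@fs,
                  end_s = (iv[, 2] - 1) / trials@fs,
                  status = rep("retained", nrow(iv)),
                  reason = rep("", nrow(iv)))
  ex <- trials@excluded
  if (nrow(ex)) {
    d <- rbind(d, data.frame(start_s = (ex$start - 1) / trials@fs,
                             end_s = (ex$end - 1) / trials@fs,
                             status = "excluded", reason = ex$reason))
  }
  write.csv(d[order(d$start_s), ], path, row.names = FALSE)
  invisible(path)
}

#' Export an evaluation report
#'
#' Per-trial scores as CSV; aggregates and the configuration snapshot as
#' JSON.
#'
#' @param report an [EvaluationReport-class].
#' @param csvPath per-trial CSV output path.
#' @param jsonPath aggregate JSON output path.
#' @return invisibly, the paths.
#' @export
exportReport <- function(report, csvPath, jsonPath) {
  stopifnot(is(report, "EvaluationReport"))
  write.csv(perTrialScores(report), csvPath, row.names = FALSE)
  obj <- list(band_condition = report@bandCondition,
              aggregate = aggregateScores(report),
              config = report@config)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                              dataframe = "rows"), jsonPath)
  invisible(c(csvPath, jsonPath))
}
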