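## Band-envelope preprocessing: CAR -> Butterworth filter bank -> rectify ->
## low-pass smooth -> downsample -> z-score.  All filters are causal
## (forward-only) by default so the feature at time t depends on samples <= t;
## a zero-phase mode (filtfilt) exists for offline exploration.

## direct-form IIR filtering: convolution (MA) pass then recursive (AR)
## pass via stats::filter, equivalent to signal::filter but without its
## per-call overhead
.causalFilter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- v[nb:length(v)]
  if (length(a) > 1)
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  else as.numeric(v)
}

.applyFilter <- function(filt, x, mode = "causal") {
  if (mode == "zero-phase") {
    as.numeric(signal::filtfilt(filt, x))
  } else {
    .causalFilter(filt$b, filt$a, x)
  }
}

## ---- Butterworth bandpass as cascaded biquads --------------------------
## A 2n-pole narrowband bandpass in single transfer-function form is
## numerically unstable in double precision at 1000 Hz (the delta band's
## poles round onto/outside the unit circle), so the filter is designed as
## n second-order sections: analog Butterworth prototype -> lowpass-to-
## bandpass transform -> bilinear transform per pole pair.  Each section is
## normalized to unit gain at the (prewarped geometric) center frequency.

.butterBandpassSos <- function(n, f1, f2, fs) {
  stopifnot(n >= 1, f1 > 0, f2 > f1, f2 < fs / 2)
  c2 <- 2 * fs
  w1 <- c2 * tan(pi * f1 / fs)
  w2 <- c2 * tan(pi * f2 / fs)
  w0 <- sqrt(w1 * w2)
  B <- w2 - w1
  ## analog prototype poles (left half-plane, unit cutoff)
  k <- seq_len(n)
  pproto <- exp(1i * pi * (2 * k - 1 + n) / (2 * n))
  ## bandpass transform: each prototype pole -> two analog poles
  pa <- c()
  for (p in pproto) {
    bp <- B * p / 2
    rt <- sqrt(bp^2 - w0^2)
    pa <- c(pa, bp + rt, bp - rt)
  }
  ## bilinear transform
  pd <- (c2 + pa) / (c2 - pa)
  ## pair into conjugate biquads (one zero at +1 and one at -1 per section)
  pd <- pd[order(-Im(pd))]
  used <- rep(FALSE, length(pd))
  sections <- list()
  wc <- 2 * pi * (atan(w0 / c2) / pi) # normalized digital center (rad/sample)
  zc <- exp(1i * wc)
  for (i in seq_along(pd)) {
    if (used[i]) next
    used[i] <- TRUE
    cand <- which(!used)
    j <- cand[which.min(abs(pd[cand] - Conj(pd[i])))]
    used[j] <- TRUE
    a <- c(1, -2 * Re(pd[i]), Re(pd[i] * pd[j]))
    b <- c(1, 0, -1)
    ## unit gain at the center frequency
    H <- sum(b * zc^(0:-2)) / sum(a * zc^(0:-2))
    sections[[length(sections) + 1L]] <- list(b = b / Mod(H), a = a)
  }
  sections
}

.sosApply <- function(sections, x, mode = "causal") {
  for (s in sections) {
    filt <- signal::Arma(b = s$b, a = s$a)
    x <- .applyFilter(filt, x, mode)
  }
  x
}

## analytic magnitude response of the same design at frequency f (Hz):
## |H(f)|^2 = 1 / (1 + ((W^2 - w0^2) / (B W))^(2n)), W = 2 fs tan(pi f / fs)
.butterBandpassGain <- function(n, f1, f2, fs, f) {
  c2 <- 2 * fs
  w1 <- c2 * tan(pi * f1 / fs)
  w2 <- c2 * tan(pi * f2 / fs)
  w0 <- sqrt(w1 * w2)
  B <- w2 - w1
  W <- c2 * tan(pi * f / fs)
  1 / sqrt(1 + ((W^2 - w0^2) / (B * W))^(2 * n))
}

#' Common average reference
#'
#' Re-references a multichannel signal by subtracting, at every sample, the
#' mean across channels.  Output rows therefore sum to zero exactly.
#'
#' @param signal numeric matrix, time x channels (>= 2 channels).
#' @return matrix of the same shape.
#' @examples
#' commonAverageReference(cbind(c(1, 0), c(3, 2)))
#' @export
commonAverageReference <- function(signal) {
  signal <- as.matrix(signal)
  if (ncol(signal) < 2)
    stop("common average reference needs at least 2 channels")
  signal - rowMeans(signal)
}

#' Butterworth bandpass filter bank
#'
#' Splits each channel into the configured frequency bands with Butterworth
#' bandpass filters (digital, bilinear design).  Filtering is causal by
#' default.
#'
#' @param signal time x channels matrix (or a vector, treated as 1 channel).
#' @param bandEdges bands x 2 matrix of (low, high) edges in Hz.
#' @param order filter order (default 4).
#' @param fs sampling rate in Hz.
#' @param mode `"causal"` or `"zero-phase"`.
#' @return time x (channels * bands) matrix; column `(c-1)*nBands + b` is
#'   channel `c`, band `b`.
#' @export
bandpassFilterbank <- function(signal, bandEdges = .defaultBandEdges(),
                               order = 4L, fs = 1000,
                               mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  signal <- as.matrix(signal)
  bandEdges <- as.matrix(bandEdges)
  if (any(bandEdges >= fs / 2))
    stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  if (any(bandEdges <= 0)) stop("band edges must be positive")
  if (order < 1) stop("filter order must be >= 1")
  nb <- nrow(bandEdges)
  nc <- ncol(signal)
  filts <- lapply(seq_len(nb), function(b)
    .butterBandpassSos(order, bandEdges[b, 1], bandEdges[b, 2], fs))
  out <- matrix(0, nrow(signal), nc * nb)
  for (ch in seq_len(nc)) {
    x <- signal[, ch]
    for (b in seq_len(nb)) {
      out[, (ch - 1L) * nb + b] <- .sosApply(filts[[b]], x, mode)
    }
  }
  out
}

#' Amplitude envelope by rectification and smoothing
#'
#' Full-wave rectifies a band-limited signal (absolute value) and smooths it
#' with a low-order Butterworth low-pass, yielding the slow amplitude
#' envelope.  The smoother has unit DC gain, so a constant input of either
#' sign converges to its magnitude.
#'
#' @param bandSignal numeric vector or time x k matrix of band-limited
#'   series.
#' @param lpCutoff smoother cutoff in Hz (default 2.2).
#' @param lpOrder smoother order (default 2).
#' @param fs sampling rate in Hz.
#' @param mode `"causal"` or `"zero-phase"`.
#' @return envelope series, same shape as the input.
#' @export
smoothedEnvelope <- function(bandSignal, lpCutoff = 2.2, lpOrder = 2L,
                             fs = 1000, mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  if (lpCutoff >= fs / 2) stop("lpCutoff must be below Nyquist")
  filt <- signal::butter(lpOrder, lpCutoff / (fs / 2), type = "low")
  x <- abs(as.matrix(bandSignal))
  out <- apply(x, 2, function(col) .applyFilter(filt, col, mode))
  if (is.null(dim(bandSignal))) as.numeric(out) else out
}

#' Downsample by decimation
#'
#' Keeps every `fsIn/fsOut`-th sample starting at index 1 (time 0).  The
#' ratio must be an integer.  No extra anti-alias filter is applied: the
#' intended use is after the 2.2 Hz envelope smoother, which already
#' suppresses content near the output Nyquist.
#'
#' @param series numeric vector or time x k matrix.
#' @param fsIn input rate (Hz).
#' @param fsOut output rate (Hz).
#' @return decimated series of length `floor(n / (fsIn/fsOut))`.
#' @export
downsampleSeries <- function(series, fsIn, fsOut) {
  k <- fsIn / fsOut
  if (abs(k - round(k)) > 1e-9)
    stop("fsIn must be an integer multiple of fsOut (got ratio ", k, ")")
  k <- as.integer(round(k))
  x <- as.matrix(series)
  n <- floor(nrow(x) / k)
  idx <- seq.int(1L, by = k, length.out = n)
  out <- x[idx, , drop = FALSE]
  if (is.null(dim(series))) as.numeric(out) else out
}

#' Z-score normalization of envelope features
#'
#' Normalizes each feature to zero mean, unit standard deviation, with mean
#' and (population, 1/N) standard deviation computed over `statsWindow`
#' samples only.  The constants are stored so held-out data can be
#' normalized with training statistics.  Zero-variance features are dropped
#' with a warning (or an error in strict mode).
#'
#' @param env time x features envelope matrix (pre-normalization).
#' @param statsWindow integer sample indices used for mu/sigma (default all).
#' @param channelOfFeature,bandOfFeature integer maps feature -> channel/band.
#' @param bandNames,channelLabels labels.
#' @param fs sampling rate (Hz).
#' @param strict error instead of dropping zero-variance features.
#' @return A [FeatureSeries-class] object.
#' @export
zscoreNormalize <- function(env, statsWindow = seq_len(nrow(env)),
                            channelOfFeature = rep(1L, ncol(env)),
                            bandOfFeature = seq_len(ncol(env)),
                            bandNames = paste0("band", seq_len(max(bandOfFeature))),
                            channelLabels = paste0("ch", seq_len(max(channelOfFeature))),
                            fs = 100, strict = FALSE) {
  env <- as.matrix(env)
  statsWindow <- as.integer(statsWindow)
  if (!length(statsWindow)) stop("statsWindow must be non-empty")
  sub <- env[statsWindow, , drop = FALSE]
  n <- nrow(sub)
  mu <- colMeans(sub)
  ## population (1/N) standard deviation
  sigma <- sqrt(colMeans(sub^2) - mu^2)
  sigma[sigma < 0] <- 0
  bad <- which(sigma <= .Machine$double.eps^0.5 * pmax(abs(mu), 1))
  if (length(bad)) {
    if (strict) stop("zero-variance feature(s): ", paste(bad, collapse = ", "))
    warning(length(bad), " zero-variance feature(s) dropped: ",
            paste(head(bad, 10), collapse = ", "))
    keep <- setdiff(seq_len(ncol(env)), bad)
  } else {
    keep <- seq_len(ncol(env))
  }
  if (!length(keep)) stop("no features left after dropping zero-variance columns")
  z <- sweep(sweep(env[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep], "/")
  new("FeatureSeries",
      envelopes = z, fs = fs,
      channelOfFeature = as.integer(channelOfFeature[keep]),
      bandOfFeature = as.integer(bandOfFeature[keep]),
      bandNames = as.character(bandNames),
      channelLabels = as.character(channelLabels),
      mu = as.numeric(mu[keep]), sigma = as.numeric(sigma[keep]),
      statsWindow = statsWindow,
      droppedFeatures = as.integer(bad))
}

#' Raw band envelopes of a session
#'
#' Runs the target-independent part of the preprocessing chain (CAR ->
#' filter bank -> rectification -> low-pass smoothing -> downsampling) and
#' returns the un-normalized envelopes at `fsOut` together with the feature
#' index maps.  [preprocessSession()] composes this with [zscoreNormalize()];
#' cross-validation reuses the raw envelopes across folds and re-normalizes
#' per fold.
#'
#' @param session a [RawSession-class].
#' @param config a [PipelineConfig-class].
#' @return list with `env` (time x features), `channelOfFeature`,
#'   `bandOfFeature`, `bandNames`, `channelLabels`, `fs`.
#' @export
rawEnvelopes <- function(session, config = pipelineConfig()) {
  stopifnot(is(session, "RawSession"), is(config, "PipelineConfig"))
  fs <- session@fsSignal
  if (fs <= 2 * max(config@bandEdges))
    stop("signal rate ", fs, " Hz must exceed twice the highest band edge")
  x <- commonAverageReference(session@signal)
  nb <- nrow(config@bandEdges)
  nc <- ncol(x)
  banded <- bandpassFilterbank(x, config@bandEdges, config@bpOrder, fs,
                               mode = config@filterMode)
  env <- smoothedEnvelope(banded, config@lpCutoff, config@lpOrder, fs,
                          mode = config@filterMode)
  env <- downsampleSeries(env, fs, config@fsOut)
  list(env = env,
       channelOfFeature = rep(seq_len(nc), each = nb),
       bandOfFeature = rep(seq_len(nb), times = nc),
       bandNames = config@bandNames,
       channelLabels = session@channelLabels,
       fs = config@fsOut)
}

#' Preprocess a session into z-scored band envelopes
#'
#' The full feature chain, in order: common average reference, Butterworth
#' band-pass filter bank, full-wave rectification, 2.2 Hz low-pass
#' smoothing, decimation to 100 Hz, and z-scoring over `statsWindow`.
#'
#' @param session a [RawSession-class].
#' @param config a [PipelineConfig-class].
#' @param statsWindow sample indices (on the output grid) over which the
#'   normalization constants are computed; default: all samples
#'   (whole-session statistics).
#' @return A [FeatureSeries-class] with `nChannels * nBands` features.
#' @examples
#' ses <- rawSession(matrix(rnorm(4000), ncol = 2), fsSignal = 1000)
#' fs <- preprocessSession(ses, pipelineConfig())
#' dim(envelopeMatrix(fs))  # 400 samples x 14 features
#' @export
preprocessSession <- function(session, config = pipelineConfig(),
                              statsWindow = NULL) {
  raw <- rawEnvelopes(session, config)
  if (is.null(statsWindow)) statsWindow <- seq_len(nrow(raw$env))
  zscoreNormalize(raw$env, statsWindow,
                  channelOfFeature = raw$channelOfFeature,
                  bandOfFeature = raw$bandOfFeature,
                  bandNames = raw$bandNames,
                  channelLabels = raw$channelLabels,
                  fs = raw$fs)
}
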