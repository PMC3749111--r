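## Lagged design construction.  The decoder predicts a kinematic variable at
## time t from the past second of every envelope feature: lags j = 1..m of
## dt = one feature sample, strictly past (the current sample is excluded).
## Rows exist only where the whole lag history lies inside the valid mask,
## so histories never straddle trial boundaries.

.validRowTimes <- function(validMask, m) {
  ## t is a row time iff validMask[t - m .. t] are all TRUE
  n <- length(validMask)
  if (m >= n) return(integer(0))
  run <- cumsum(as.integer(validMask))
  t <- (m + 1L):n
  ok <- (run[t] - c(0L, run)[t - m]) == (m + 1L)
  t[ok]
}

#' Build a lagged regression design
#'
#' Pairs each valid target sample with the `m` strictly-past samples of
#' every feature.  Column layout: column 1 is the constant-1 bias; column
#' `1 + (i-1)*m + j` is feature `i` at lag `j` (i.e. `z_i(t - j*dt)`).
#'
#' @param features a [FeatureSeries-class] (or a plain time x features
#'   matrix).
#' @param target numeric target series on the same grid.
#' @param validMask logical series; a row is emitted for time `t` only if
#'   `t` and its `m` preceding samples are all valid.  Default: all valid.
#' @param m number of lags (default 100).
#' @param stride keep every `stride`-th valid row (default 1 = all rows).
#'   Envelopes are smooth at 100 Hz, so moderate strides thin the training
#'   rows with little information loss.
#' @return A [LaggedDesign-class].
#' @examples
#' d <- buildDesign(matrix(c(10, 20, 30, 40)), c(1, 2, 3, 4), m = 2)
#' d@X  # rows for t = 3, 4: [1, 20, 10], [1, 30, 20]
#' @export
buildDesign <- function(features, target, validMask = NULL, m = 100L,
                        stride = 1L) {
  if (is(features, "FeatureSeries")) {
    env <- features@envelopes
    chOf <- features@channelOfFeature
    bdOf <- features@bandOfFeature
    bn <- features@bandNames
    cl <- features@channelLabels
  } else {
    env <- as.matrix(features)
    chOf <- integer(0); bdOf <- integer(0)
    bn <- character(0); cl <- character(0)
  }
  m <- as.integer(m)
  stride <- as.integer(stride)
  n <- nrow(env)
  F <- ncol(env)
  if (length(target) != n) stop("target length must match feature series length")
  if (is.null(validMask)) validMask <- rep(TRUE, n)
  if (length(validMask) != n) stop("validMask length must match series length")
  validMask <- validMask & !is.na(target)
  times <- .validRowTimes(validMask, m)
  if (stride > 1L && length(times)) times <- times[seq(1L, length(times), by = stride)]
  if (!length(times))
    stop("empty design: no sample has a full ", m, "-lag history in the valid mask")
  X <- matrix(0, length(times), F * m + 1L)
  X[, 1L] <- 1
  for (j in seq_len(m)) {
    ## columns of lag j across all features: 1 + (i-1)*m + j
    X[, 1L + (seq_len(F) - 1L) * m + j] <- env[times - j, , drop = FALSE]
  }
  new("LaggedDesign",
      X = X, y = as.numeric(target[times]), sampleTimes = as.integer(times),
      nFeatures = F, nLags = m,
      featureOfColumn = c(0L, rep(seq_len(F), each = m)),
      lagOfColumn = c(0L, rep(seq_len(m), times = F)),
      channelOfFeature = as.integer(chOf), bandOfFeature = as.integer(bdOf),
      bandNames = bn, channelLabels = cl, stride = stride)
}

#' Predict a kinematic series from a fitted decoder
#'
#' Evaluates `Y_p(t) = w0 + sum_i sum_j w_ij z_i(t - j*dt)` over the active
#' weights only.  Samples whose lag history is not fully inside the valid
#' mask are returned as `NA` (flagged undefined, never zero-filled).
#'
#' @param model a [DecoderModel-class].
#' @param features a [FeatureSeries-class] (or plain matrix) with the same
#'   feature layout the model was trained on.
#' @param validMask logical series restricting both targets and histories
#'   (default: all valid).
#' @param checkConfig refuse prediction if the feature preprocessing
#'   configuration differs from the one stored in the model (default TRUE
#'   when both carry a config snapshot).
#' @return numeric series of length `nrow(features)` with `NA` at undefined
#'   samples.
#' @export
predictSeries <- function(model, features, validMask = NULL,
                          checkConfig = TRUE) {
  stopifnot(is(model, "DecoderModel"))
  if (is(features, "FeatureSeries")) {
    env <- features@envelopes
    if (ncol(env) != model@nFeatures)
      stop("layout mismatch: model expects ", model@nFeatures,
           " features, got ", ncol(env))
    if (checkConfig && length(model@config)) {
      fsCfg <- model@config$fsOut
      if (!is.null(fsCfg) && abs(features@fs - fsCfg) > 1e-9)
        stop("preprocessing mismatch: model trained at fsOut = ", fsCfg,
             " Hz, features are at ", features@fs, " Hz")
    }
  } else {
    env <- as.matrix(features)
    if (ncol(env) != model@nFeatures)
      stop("layout mismatch: model expects ", model@nFeatures,
           " features, got ", ncol(env))
  }
  n <- nrow(env)
  m <- model@nLags
  if (is.null(validMask)) validMask <- rep(TRUE, n)
  times <- .validRowTimes(validMask, m)
  out <- rep(NA_real_, n)
  if (!length(times)) return(out)
  yp <- rep(model@w0, length(times))
  act <- model@activeSet
  if (length(act)) {
    feat <- (act - 1L) %/% m + 1L
    lag <- (act - 1L) %% m + 1L
    w <- model@weights[act]
    for (k in seq_along(act)) {
      yp <- yp + w[k] * env[times - lag[k], feat[k]]
    }
  }
  out[times] <- yp
  out
}
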