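## Velocity-threshold trial segmentation.  The published rule (start/end
## where tangential velocity crosses 5% of the per-trial maximum) is
## circular on its own — the per-trial maximum needs trial boundaries — so a
## two-pass procedure isolates bursts first: candidates from a global
## 5%-of-session-max threshold, merged across gaps shorter than minGap, then
## each burst's boundaries refined against that burst's own maximum.

.runsFromMask <- function(mask) {
  ## [start, end) index pairs of TRUE runs
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values] + 1L)
}

#' Segment a session into movement trials
#'
#' Two-pass velocity-threshold segmentation: candidate bursts where the
#' speed exceeds `thresholdFraction` of the session maximum, bursts merged
#' across gaps shorter than `minGap`, then each burst's `[start, end)`
#' refined to the first/last crossing of `thresholdFraction` of that
#' burst's own maximum.  Intervals shorter than `minDuration` are dropped.
#' Crossings are resolved at sample resolution; the first crossing wins.
#'
#' @param speed nonnegative speed series (m/s).
#' @param fs sampling rate (Hz).
#' @param thresholdFraction fraction of maximum speed (default 0.05).
#' @param minGap bursts closer than this (seconds) are merged (default 1).
#' @param minDuration minimum trial duration in seconds (default 2).
#' @return A [TrialSet-class]; empty (no intervals) for all-zero speed.
#' @export
segmentTrials <- function(speed, fs, thresholdFraction = 0.05,
                          minGap = 1.0, minDuration = 2.0) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  if (any(speed < 0)) stop("speed must be nonnegative")
  n <- length(speed)
  empty <- new("TrialSet",
               intervals = matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end"))),
               excluded = data.frame(start = integer(0), end = integer(0),
                                     reason = character(0)),
               fs = fs, sourceSpeed = as.numeric(speed),
               thresholdFraction = thresholdFraction)
  vmax <- max(speed)
  if (vmax <= 0) return(empty)
  ## pass 1: global candidate bursts
  mask <- speed > thresholdFraction * vmax
  if (!any(mask)) return(empty)
  runs <- .runsFromMask(mask)
  ## merge across short gaps
  gapSamples <- round(minGap * fs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] < gapSamples) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  ## pass 2: refine each burst against its own maximum
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, 1]; e <- merged[i, 2] - 1L
    burstMax <- max(speed[s:e])
    thr <- thresholdFraction * burstMax
    above <- which(speed[s:e] > thr)
    if (!length(above)) next
    out <- rbind(out, c(s + above[1] - 1L, s + above[length(above)] - 1L + 1L))
  }
  keep <- (out[, 2] - out[, 1]) >= round(minDuration * fs)
  iv <- out[keep, , drop = FALSE]
  colnames(iv) <- c("start", "end")
  new("TrialSet", intervals = iv,
      excluded = data.frame(start = integer(0), end = integer(0),
                            reason = character(0)),
      fs = fs, sourceSpeed = as.numeric(speed),
      thresholdFraction = thresholdFraction)
}

#' Exclude trials by within-trial displacement
#'
#' Moves trials whose marker range along one axis exceeds `limit` (e.g.
#' excessive sagittal torso movement, > 0.20 m anterior-posterior) to the
#' excluded list with reason `"displacement"`.
#'
#' @param trials a [TrialSet-class].
#' @param markers time x 3 marker positions on the same grid (meters).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param limit maximum allowed within-trial range (meters).
#' @return A new [TrialSet-class] with offending trials excluded.
#' @export
excludeByDisplacement <- function(trials, markers, axis = c("y", "x", "z"),
                                  limit = 0.20) {
  stopifnot(is(trials, "TrialSet"))
  axis <- match.arg(axis)
  if (limit <= 0) stop("limit must be positive")
  col <- match(axis, c("x", "y", "z"))
  m <- as.matrix(markers)
  iv <- trials@intervals
  if (!nrow(iv) || !is.finite(limit)) return(trials)
  bad <- logical(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    seg <- m[iv[i, 1]:(iv[i, 2] - 1L), col]
    bad[i] <- (max(seg) - min(seg)) > limit
  }
  exc <- trials@excluded
  if (any(bad)) {
    exc <- rbind(exc, data.frame(start = iv[bad, 1], end = iv[bad, 2],
                                 reason = "displacement"))
  }
  new("TrialSet", intervals = iv[!bad, , drop = FALSE], excluded = exc,
      fs = trials@fs, sourceSpeed = trials@sourceSpeed,
      thresholdFraction = trials@thresholdFraction)
}

#' Logical sample mask of a trial set
#'
#' @param trials a [TrialSet-class].
#' @param n series length.
#' @param which interval row indices to include (default all).
#' @return logical vector of length `n`, TRUE inside the chosen intervals.
#' @export
trialMask <- function(trials, n, which = seq_len(nrow(trials@intervals))) {
  mask <- rep(FALSE, n)
  iv <- trials@intervals
  for (i in which) mask[iv[i, 1]:(iv[i, 2] - 1L)] <- TRUE
  mask
}
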