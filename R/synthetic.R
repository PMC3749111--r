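## Synthetic session generator.  Emulates the block-transport task —
## repeated reach/grasp/carry/release cycles of three blocks around the
## corners of a 25 cm square — and multichannel 1000 Hz signals whose
## within-band amplitude envelopes are lagged linear functions of the arm
## kinematics plus noise.  The signal model is multiplicative amplitude
## modulation of band-limited carriers: the generative inverse of
## rectify-and-smooth envelope extraction, so the analysis chain is the
## matched filter for these data.

## minimum-jerk position profile s(tau), tau in [0, 1]
.minJerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

## wrist-target inverse kinematics with the elbow-low swivel convention:
## among the circle of elbow positions compatible with a wrist target, take
## the lowest (most -z) one — the natural relaxed posture at a table.
.postureForWrist <- function(target, geom) {
  d <- sqrt(sum(target^2))
  reach <- geom@lUpper + geom@lFore
  if (d > 0.98 * reach || d < 1.05 * abs(geom@lUpper - geom@lFore))
    stop("wrist target at distance ", round(d, 3),
         " m is outside the arm's comfortable reach")
  what <- target / d
  cEl <- (geom@lUpper^2 + d^2 - geom@lFore^2) / (2 * d)
  r <- sqrt(max(geom@lUpper^2 - cEl^2, 0))
  ## basis of the elbow circle plane; pick the in-plane direction closest
  ## to -z for the lowest elbow
  down <- c(0, 0, -1)
  a <- down - sum(down * what) * what
  na <- sqrt(sum(a^2))
  a <- if (na > 1e-9) a / na else {
    b <- c(1, 0, 0) - what[1] * what
    b / sqrt(sum(b^2))
  }
  elbow <- cEl * what + r * a
  q <- inverseKinematics(c(0, 0, 0), elbow, target, geom, lengthTol = 0.01,
                         fs = 1)
  jointAngles(q)[1, ]
}

## unwrap angle keyframes so interpolation never crosses a branch cut
.unwrapTo <- function(q, ref) q + 2 * pi * round((ref - q) / (2 * pi))

#' Simulate task kinematics
#'
#' Generates joint-angle and marker trajectories of the block-transport
#' task: per cycle, three sequential point-to-point transports among the
#' corners of the task square (reach above the block, lower, grasp, lift,
#' carry, lower, release), minimum-jerk interpolated in joint-angle space
#' between inverse-kinematics key postures, with brief dwell pauses and
#' near-zero-velocity rest epochs between cycles.  Markers come from
#' forward kinematics, so segment lengths hold exactly.
#'
#' @param spec a [SimulationSpec-class].
#' @return list: `angles` ([JointAngleSeries-class]), `markers` (time x 9:
#'   shoulder, elbow, wrist xyz in meters), `corners` (4 x 3 corner
#'   positions), `fs`.
#' @export
simulateKinematics <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  geom <- armGeometry(spec@lUpper, spec@lFore)
  fs <- spec@fsMarkers
  s <- spec@squareSide
  ## task square in a horizontal plane in front of the left shoulder
  ## (x lateral-left, y anterior, z up; shoulder at the origin)
  corners <- rbind(c(0.00, 0.15, -0.20),
                   c(s,    0.15, -0.20),
                   c(s,    0.15 + s, -0.20),
                   c(0.00, 0.15 + s, -0.20))
  rest <- c(0.05, 0.10, -0.35)
  lift <- c(0, 0, spec@liftHeight)
  ## the three blocks differ in shape and height (parallelepiped, cube,
  ## cylinder), so grasp heights differ per transport -- the source of the
  ## task's slow vertical structure
  blockHeight <- c(0.10, 0.04, 0.14)
  ## transports: rotate blocks into the vacant corner (4): 1->4, 2->1, 3->2
  transports <- list(c(1L, 4L), c(2L, 1L), c(3L, 2L))
  ## waypoints of one cycle (positions + dwell flags)
  way <- list(rest)
  dwellAfter <- c(FALSE)
  for (bi in seq_along(transports)) {
    tp <- transports[[bi]]
    top <- c(0, 0, blockHeight[bi])
    src <- corners[tp[1], ] + top; dst <- corners[tp[2], ] + top
    mid <- (src + dst) / 2 + 1.5 * lift   # arced carry clears the other blocks
    seg <- list(src + lift, src, src + lift, mid, dst + lift, dst, dst + lift)
    dw <- c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
    way <- c(way, seg)
    dwellAfter <- c(dwellAfter, dw)
  }
  way <- c(way, list(rest))
  dwellAfter <- c(dwellAfter, FALSE)
  ## joint-space key postures, unwrapped for continuity
  qKey <- matrix(0, length(way), 4)
  qKey[1, ] <- .postureForWrist(way[[1]], geom)
  for (i in 2:length(way)) {
    qi <- .postureForWrist(way[[i]], geom)
    qKey[i, 1] <- .unwrapTo(qi[1], qKey[i - 1, 1])
    qKey[i, 3] <- .unwrapTo(qi[3], qKey[i - 1, 3])
    qKey[i, c(2, 4)] <- qi[c(2, 4)]
  }
  ## segment durations: proportional to Cartesian distance at a comfortable
  ## self-paced speed, plus dwells; scaled to hit trialDuration exactly
  nSeg <- length(way) - 1L
  dist <- vapply(seq_len(nSeg), function(i)
    sqrt(sum((way[[i + 1]] - way[[i]])^2)), numeric(1))
  moveDur <- pmax(0.4, dist / 0.35)
  dwellDur <- ifelse(dwellAfter[-1], 0.3, 0)
  total <- sum(moveDur) + sum(dwellDur)
  k <- spec@trialDuration / total
  moveDur <- moveDur * k
  dwellDur <- dwellDur * k
  ## assemble one cycle on the marker grid
  cycleQ <- qKey[1, , drop = FALSE]
  for (i in seq_len(nSeg)) {
    nS <- max(2L, round(moveDur[i] * fs))
    tau <- .minJerk(seq_len(nS) / nS)
    seg <- outer(tau, qKey[i + 1, ] - qKey[i, ]) +
      matrix(qKey[i, ], nS, 4, byrow = TRUE)
    cycleQ <- rbind(cycleQ, seg)
    nD <- round(dwellDur[i] * fs)
    if (nD > 0) cycleQ <- rbind(cycleQ, matrix(qKey[i + 1, ], nD, 4, byrow = TRUE))
  }
  restQ <- qKey[1, ]
  nRest <- max(1L, round(spec@restDuration * fs))
  restBlock <- matrix(restQ, nRest, 4, byrow = TRUE)
  qAll <- restBlock
  for (tr in seq_len(spec@nTrials)) qAll <- rbind(qAll, cycleQ, restBlock)
  angles <- jointAngleSeries(qAll, fs = fs)
  fk <- forwardKinematics(angles, geom)
  markers <- cbind(matrix(0, nrow(qAll), 3), fk$elbow, fk$wrist)
  colnames(markers) <- c("shoulder_x", "shoulder_y", "shoulder_z",
                         "elbow_x", "elbow_y", "elbow_z",
                         "wrist_x", "wrist_y", "wrist_z")
  list(angles = angles, markers = markers, corners = corners, fs = fs)
}

## 1/f ("pink") noise of length n via spectral shaping, unit variance
.pinkNoise <- function(n) {
  nf <- 2^ceiling(log2(n))
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)   # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / sd(x)
}

#' Simulate the multichannel neural signal of a session
#'
#' For each informative (channel, band) pair, the clean envelope is a
#' positive affine image of a sparse combination of standardized kinematic
#' variables evaluated `trueLag` seconds later (the cortical envelope leads
#' the movement); envelope noise is added at the requested
#' signal-to-noise variance ratio, negative excursions are clipped at zero
#' (counted, warned).  The 1000 Hz channel signal is the sum over bands of
#' unit-variance band-limited carriers (band noise or band-center
#' sinusoids) amplitude-modulated by the envelopes, plus broadband 1/f
#' noise.  Non-informative pairs get envelope noise only.
#'
#' @param kinematics output of [simulateKinematics()].
#' @param spec a [SimulationSpec-class]; `spec@seed` makes the session
#'   bit-reproducible.
#' @return list: `session` ([RawSession-class]), `truth`
#'   ([GroundTruth-class]).
#' @export
simulateEcog <- function(kinematics, spec) {
  stopifnot(is(spec, "SimulationSpec"))
  set.seed(spec@seed)
  fsM <- spec@fsMarkers
  fsS <- spec@fsSignal
  bands <- .defaultBandEdges()
  nb <- nrow(bands)
  nc <- spec@nChannels
  ## kinematic variable matrix, standardized
  kin <- cbind(jointAngles(kinematics$angles),
               kinematics$markers[, 4:9, drop = FALSE])
  colnames(kin) <- c("q1", "q2", "q3", "q4", "elbow_x", "elbow_y", "elbow_z",
                     "wrist_x", "wrist_y", "wrist_z")
  kinStd <- scale(kin)
  kinStd[, attr(kinStd, "scaled:scale") == 0] <- 0
  n100 <- nrow(kin)
  lagS <- round(spec@trueLag * fsM)
  ## envelope leads the kinematics: env(t) ~ kin(t + lag)
  shiftLead <- function(x, L) {
    if (L <= 0) return(x)
    c(x[(L + 1):length(x)], rep(x[length(x)], L))
  }
  nPairs <- nc * nb
  nInf <- if (spec@informativeFraction > 0)
    max(1L, round(spec@informativeFraction * nPairs)) else 0L
  infPairs <- if (nInf) sort(sample.int(nPairs, nInf)) else integer(0)
  depth <- spec@modulationDepth
  noiseSd <- if (spec@envelopeSnr == 0) depth
             else if (is.finite(spec@envelopeSnr)) depth / sqrt(spec@envelopeSnr)
             else 0
  env100 <- matrix(1, n100, nPairs)     # baseline 1
  clean100 <- matrix(1, n100, nPairs)
  couplings <- vector("list", nPairs)
  clipped <- 0L
  for (p in infPairs) {
    nv <- sample(1:3, 1)
    vars <- sample.int(ncol(kin), nv)
    wts <- rnorm(nv)
    s <- as.numeric(kinStd[, vars, drop = FALSE] %*% wts)
    s <- shiftLead(s, lagS)
    sdS <- sd(s)
    if (sdS > 0) s <- (s - mean(s)) / sdS else s <- s * 0
    couplings[[p]] <- list(vars = vars, weights = wts, lag_s = spec@trueLag)
    if (spec@envelopeSnr > 0) clean100[, p] <- 1 + depth * s
  }
  noise <- matrix(rnorm(n100 * nPairs, sd = noiseSd), n100, nPairs)
  ## an amplitude cannot be negative: the emitted clean envelope is the
  ## clipped affine image, and the noisy envelope is clipped again below
  clipped <- sum(clean100 < 0)
  clean100 <- pmax(clean100, 0)
  env100 <- clean100 + noise
  neg <- env100 < 0
  clipped <- clipped + sum(neg)
  if (clipped) {
    env100[neg] <- 0
    warning(clipped, " envelope sample(s) clipped at zero")
  }
  ## upsample envelopes to the signal rate and modulate carriers
  n1000 <- round(n100 * fsS / fsM)
  t100 <- (seq_len(n100) - 1) / fsM
  t1000 <- (seq_len(n1000) - 1) / fsS
  signalM <- matrix(0, n1000, nc)
  filts <- lapply(seq_len(nb), function(b)
    .butterBandpassSos(4, bands[b, 1], bands[b, 2], fsS))
  for (ch in seq_len(nc)) {
    x <- numeric(n1000)
    for (b in seq_len(nb)) {
      p <- (ch - 1L) * nb + b
      envUp <- approx(t100, env100[, p], xout = t1000, rule = 2)$y
      if (spec@carrierType == "band_noise") {
        carrier <- .sosApply(filts[[b]], rnorm(n1000))
        sdc <- sd(carrier)
        if (sdc > 0) carrier <- carrier / sdc
      } else {
        ## place the tone high in the band so its rectification harmonic
        ## (2 fc) clears the envelope smoother's passband even for delta
        fc <- max(sqrt(bands[b, 1] * bands[b, 2]), 0.8 * bands[b, 2])
        carrier <- sqrt(2) * sin(2 * pi * fc * t1000 + runif(1, 0, 2 * pi))
      }
      x <- x + carrier * envUp
    }
    if (spec@pinkAmplitude > 0) x <- x + spec@pinkAmplitude * .pinkNoise(n1000)
    signalM[, ch] <- x
  }
  session <- rawSession(signalM, fsS,
                        markers = kinematics$markers, fsMarkers = fsM,
                        channelLabels = sprintf("ch%02d", seq_len(nc)))
  bandIdx <- rep(seq_len(nb), times = nc)
  chanIdx <- rep(seq_len(nc), each = nb)
  truth <- new("GroundTruth",
               angles = kinematics$angles,
               informative = data.frame(channel = chanIdx[infPairs],
                                        band = bandIdx[infPairs]),
               couplings = couplings,
               cleanEnvelopes = clean100,
               trueLag = spec@trueLag,
               clippedCount = as.integer(clipped))
  list(session = session, truth = truth)
}

#' Simulate a complete session
#'
#' Convenience wrapper: [simulateKinematics()] then [simulateEcog()].
#'
#' @param spec a [SimulationSpec-class].
#' @return list: `session`, `truth`, `kinematics`.
#' @export
simulateSession <- function(spec = simulationSpec()) {
  kin <- simulateKinematics(spec)
  eco <- simulateEcog(kin, spec)
  list(session = eco$session, truth = eco$truth, kinematics = kin)
}

#' Write a grid of benchmark fixture sessions
#'
#' Generates one synthetic session per grid point (envelope SNR x channel
#' count) and writes it in the formats [readSession()] consumes (signal
#' CSV or EDF, marker CSV) plus the ground-truth coupling table as JSON.
#' Includes a 15-channel variant mirroring the small electrode montage.
#'
#' @param dir output directory (created if needed).
#' @param snr named numeric vector of envelope SNR levels
#'   (default `c(high = 10, low = 1)`).
#' @param nChannels integer vector (default `c(60, 15)`).
#' @param nTrials trials per session (default 3).
#' @param trialDuration seconds per trial (default 17).
#' @param signalFormat `"csv"` or `"edf"`.
#' @param baseSeed integer; grid point i uses `baseSeed + i`.
#' @return data.frame manifest (one row per fixture with paths).
#' @export
makeBenchmarkSuite <- function(dir, snr = c(high = 10, low = 1),
                               nChannels = c(60, 15), nTrials = 3L,
                               trialDuration = 17,
                               signalFormat = c("csv", "edf"),
                               baseSeed = 1L) {
  signalFormat <- match.arg(signalFormat)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(snr))) names(snr) <- paste0("snr", seq_along(snr))
  grid <- expand.grid(snr = names(snr), nch = nChannels,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- simulationSpec(nChannels = grid$nch[i], nTrials = nTrials,
                           trialDuration = trialDuration,
                           envelopeSnr = snr[[grid$snr[i]]],
                           seed = baseSeed + i)
    sim <- simulateSession(spec)
    stem <- file.path(dir, sprintf("session_%s_ch%d", grid$snr[i], grid$nch[i]))
    sigPath <- paste0(stem, if (signalFormat == "edf") ".edf" else "_signal.csv")
    mrkPath <- paste0(stem, "_markers.csv")
    truthPath <- paste0(stem, "_truth.json")
    writeSession(sim$session, sigPath, mrkPath)
    truth <- sim$truth
    writeLines(jsonlite::toJSON(list(
      informative = truth@informative,
      true_lag_s = truth@trueLag,
      clipped = truth@clippedCount,
      seed = spec@seed,
      envelope_snr = snr[[grid$snr[i]]]),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"), truthPath)
    rows[[i]] <- data.frame(snr_label = grid$snr[i], envelope_snr = snr[[grid$snr[i]]],
                            n_channels = grid$nch[i], n_trials = nTrials,
                            signal = sigPath, markers = mrkPath,
                            truth = truthPath, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
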