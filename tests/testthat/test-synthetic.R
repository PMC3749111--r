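test_that("simulated wrist paths visit all four task-square corners", {
  spec <- simulationSpec(nChannels = 4L, nTrials = 2L, trialDuration = 12,
                         restDuration = 3, seed = 51)
  kin <- simulateKinematics(spec)
  w <- kin$markers[, 7:9]
  for (i in 1:4) {
    dmin <- min(sqrt(rowSums(sweep(w[, 1:2], 2, kin$corners[i, 1:2])^2)))
    expect_lt(dmin, 0.005)   # within 5 mm in the square's plane
  }
  # markers obey the arm geometry exactly (forward-kinematics property)
  lu <- sqrt(rowSums((kin$markers[, 4:6] - kin$markers[, 1:3])^2))
  lf <- sqrt(rowSums((kin$markers[, 7:9] - kin$markers[, 4:6])^2))
  expect_lt(max(abs(lu - spec@lUpper)), 1e-12)
  expect_lt(max(abs(lf - spec@lFore)), 1e-12)
})

test_that("rest epochs are still and segmentation recovers the trial count", {
  spec <- simulationSpec(nChannels = 4L, nTrials = 3L, trialDuration = 12,
                         restDuration = 4, seed = 52)
  kin <- simulateKinematics(spec)
  speed <- tangentialVelocity(kin$markers[, 4:6], spec@fsMarkers, 5)
  tr <- segmentTrials(speed, spec@fsMarkers)
  expect_equal(nrow(trialIntervals(tr)), 3L)
  # speed in the rest epochs is far below the per-trial maxima
  mask <- trialMask(tr, length(speed))
  # ignore boundary smearing: look well inside the rests
  restIdx <- which(!mask)
  restIdx <- restIdx[restIdx > 50]
  expect_lt(quantile(speed[restIdx], 0.5), 0.01 * max(speed))
})

test_that("a task square beyond arm reach is rejected", {
  spec <- simulationSpec(nChannels = 4L, nTrials = 1L, squareSide = 0.8,
                         seed = 53)
  expect_error(simulateKinematics(spec), "reach")
})

test_that("sessions are bit-identical under a fixed seed", {
  spec <- simulationSpec(nChannels = 3L, nTrials = 1L, trialDuration = 8,
                         restDuration = 2, seed = 54)
  s1 <- simulateSession(spec)
  s2 <- simulateSession(spec)
  expect_identical(signalMatrix(s1$session), signalMatrix(s2$session))
  expect_identical(markerMatrix(s1$session), markerMatrix(s2$session))
  expect_identical(s1$truth@cleanEnvelopes, s2$truth@cleanEnvelopes)
  # a different seed gives different signals
  s3 <- simulateSession(simulationSpec(nChannels = 3L, nTrials = 1L,
                                       trialDuration = 8, restDuration = 2,
                                       seed = 55))
  expect_false(identical(signalMatrix(s1$session), signalMatrix(s3$session)))
})

test_that("preprocessing recovers noiseless sinusoid-carrier envelopes", {
  spec <- simulationSpec(nChannels = 4L, nTrials = 2L, trialDuration = 12,
                         restDuration = 3, envelopeSnr = Inf,
                         carrierType = "sinusoid", pinkAmplitude = 0,
                         informativeFraction = 0.25, seed = 56)
  suppressWarnings(sim <- simulateSession(spec))
  raw <- rawEnvelopes(sim$session, pipelineConfig())
  clean <- sim$truth@cleanEnvelopes
  n <- min(nrow(raw$env), nrow(clean))
  inf <- which(apply(clean, 2, sd) > 0)
  expect_gte(length(inf), 1)
  skip <- 300  # discard the causal-filter transient
  ccs <- vapply(inf, function(p) {
    # align for the smoother's group delay (small, band-dependent)
    max(vapply(0:30, function(L)
      cor(raw$env[(skip + L):n, p], clean[skip:(n - L), p]), numeric(1)))
  }, numeric(1))
  isDelta <- raw$bandOfFeature[inf] == 1L
  # the delta band cannot carry its envelope undistorted: any in-band
  # carrier puts its rectification harmonic (2 fc < 8 Hz) and part of the
  # modulation sidebands inside 0.5-4 Hz itself
  expect_true(all(ccs[!isDelta] >= 0.95))
  expect_true(all(ccs[isDelta] >= 0.90))
})

test_that("measured envelope SNR matches the requested level", {
  spec <- simulationSpec(nChannels = 4L, nTrials = 2L, trialDuration = 12,
                         restDuration = 3, envelopeSnr = 4,
                         informativeFraction = 0.3, seed = 57)
  kin <- simulateKinematics(spec)
  suppressWarnings(eco <- simulateEcog(kin, spec))
  clean <- eco$truth@cleanEnvelopes
  inf <- which(apply(clean, 2, sd) > 0)
  # post-hoc: var(signal) / var(noise) in the envelope domain, pooled
  # (clipping at zero slightly truncates the noise, so allow 10%)
  depthVar <- mean(apply(clean[, inf, drop = FALSE], 2, var))
  noiseVar <- (spec@modulationDepth / sqrt(spec@envelopeSnr))^2
  expect_equal(depthVar / noiseVar, 4, tolerance = 0.4)
})

test_that("decoder weight mass is strongly enriched on informative pairs", {
  spec <- simulationSpec(nChannels = 15L, nTrials = 3L, trialDuration = 12,
                         restDuration = 3, envelopeSnr = 20,
                         informativeFraction = 0.05,
                         carrierType = "sinusoid", seed = 58)
  kin <- simulateKinematics(spec)
  suppressWarnings(eco <- simulateEcog(kin, spec))
  truth <- eco$truth@informative
  infKey <- paste(truth$channel, truth$band)
  cfg <- pipelineConfig(nLags = 50L, designStride = 4L)
  raw <- rawEnvelopes(eco$session, cfg)
  n <- nrow(raw$env)
  speed <- tangentialVelocity(eco$session@markers[, 4:6], 100, 5)
  tr <- segmentTrials(speed[seq_len(n)], 100)
  mask <- trialMask(tr, n)
  fs <- zscoreNormalize(raw$env, which(mask),
                        channelOfFeature = raw$channelOfFeature,
                        bandOfFeature = raw$bandOfFeature,
                        bandNames = raw$bandNames,
                        channelLabels = raw$channelLabels)
  targets <- decodingTargets(eco$session)
  d <- buildDesign(fs, targets[seq_len(n), "wrist_y"], mask, 50L, stride = 4L)
  model <- fitSLR(d, maxIter = 40, validationFraction = 0)
  sr <- sparsityReport(model)
  key <- paste(as.integer(sub("ch", "", sr$channel)),
               match(sr$band, raw$bandNames))
  onInf <- sum(sr$mass[key %in% infKey]) / sum(sr$mass)
  # informative pairs hold a small share of columns (5%) but a dominant
  # share of weight mass, and the top-mass cells are all truly informative
  expect_gt(onInf, 5 * 0.05)
  expect_true(all(key[1:3] %in% infKey))
})

test_that("the benchmark suite writes a readable fixture grid", {
  dir <- tempfile()
  manifest <- makeBenchmarkSuite(dir, snr = c(high = 10, low = 1),
                                 nChannels = c(4, 3), nTrials = 1L,
                                 trialDuration = 8, baseSeed = 60)
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(manifest$signal)))
  expect_true(all(file.exists(manifest$markers)))
  ses <- readSession(manifest$signal[1], manifest$markers[1])
  expect_equal(ncol(signalMatrix(ses)), 4L)
  truth <- jsonlite::fromJSON(manifest$truth[1])
  expect_equal(truth$envelope_snr, 10)
  unlink(dir, recursive = TRUE)
})
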