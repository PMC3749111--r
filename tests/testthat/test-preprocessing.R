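test_that("common average reference subtracts the per-sample channel mean", {
  expect_equal(commonAverageReference(matrix(c(1, 3), 1, 2)),
               matrix(c(-1, 1), 1, 2))
  set.seed(7)
  x <- matrix(rnorm(20), 5, 4)
  out <- commonAverageReference(x)
  # independent per-row-mean oracle
  oracle <- t(vapply(seq_len(5), function(i) x[i, ] - sum(x[i, ]) / 4,
                     numeric(4)))
  expect_equal(out, oracle, tolerance = 1e-14)
  expect_lt(max(abs(rowSums(out))), 1e-12)
  expect_error(commonAverageReference(matrix(1, 5, 1)), "2 channels")
})

test_that("filter bank matches the analytic Butterworth bandpass response", {
  fs <- 1000
  t <- (0:19999) / fs
  probe <- function(f) sin(2 * pi * f * t)
  bands <- pipelineConfig()@bandEdges
  # steady-state amplitude over the last half, after transient decay
  ssAmp <- function(y) sqrt(2 * mean(y[10001:20000]^2))
  for (b in seq_len(nrow(bands))) {
    fc <- (bands[b, 1] + bands[b, 2]) / 2
    out <- bandpassFilterbank(probe(fc), bands, 4L, fs)
    expect_equal(ssAmp(out[, b]),
                 ecogtraj:::.butterBandpassGain(4, bands[b, 1], bands[b, 2], fs, fc),
                 tolerance = 0.05)
  }
  # 25 Hz probe: near-unit gain in beta2, strong rejection in delta
  out <- bandpassFilterbank(probe(25), bands, 4L, fs)
  expect_equal(ssAmp(out[, 5]), 1.0, tolerance = 0.05)
  expect_lt(ssAmp(out[, 1]), 0.01)
  # zero in, zero out; Nyquist guard
  expect_equal(bandpassFilterbank(numeric(100), bands, 4L, fs),
               matrix(0, 100, 7))
  expect_error(bandpassFilterbank(numeric(100), bands, 4L, 150), "Nyquist")
})

test_that("causal and zero-phase filtering modes differ only in phase", {
  fs <- 1000
  t <- (0:9999) / fs
  x <- sin(2 * pi * 25 * t)
  bands <- pipelineConfig()@bandEdges
  yc <- bandpassFilterbank(x, bands, 4L, fs, mode = "causal")[, 5]
  yz <- bandpassFilterbank(x, bands, 4L, fs, mode = "zero-phase")[, 5]
  ss <- 5001:9000
  expect_equal(sqrt(mean(yz[ss]^2)), sqrt(mean(yc[ss]^2)), tolerance = 0.02)
  # zero-phase output is unshifted relative to the probe
  expect_gt(cor(yz[ss], x[ss]), 0.999)
})

test_that("envelope extraction rectifies and smooths with unit DC gain", {
  fs <- 1000
  # constant negative input converges to its magnitude
  env <- smoothedEnvelope(rep(-2.5, 5000), 2.2, 2L, fs)
  expect_equal(env[5000], 2.5, tolerance = 1e-3)
  # 40 Hz unit sinusoid: envelope approaches mean(|sin|) = 2/pi
  t <- (0:9999) / fs
  env <- smoothedEnvelope(sin(2 * pi * 40 * t), 2.2, 2L, fs)
  expect_equal(mean(env[5001:10000]), 2 / pi, tolerance = 0.1 * 2 / pi)
  expect_equal(smoothedEnvelope(numeric(100), 2.2, 2L, fs), numeric(100))
})

test_that("downsampling keeps every k-th sample from index 0", {
  expect_equal(downsampleSeries(rep(0, 10), 1000, 100), 0)
  expect_length(downsampleSeries(numeric(2000), 1000, 100), 200)
  # index-arithmetic oracle on a ramp
  expect_equal(downsampleSeries(0:999, 1000, 100), seq(0, 990, by = 10))
  expect_error(downsampleSeries(1:10, 1000, 300), "integer multiple")
})

test_that("z-scoring uses population statistics over the stats window", {
  fs <- zscoreNormalize(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(envelopeMatrix(fs)),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  s <- normalizationStats(fs)
  expect_equal(s$sigma, sqrt(2 / 3))
  # constant feature is dropped with a warning
  expect_warning(fs2 <- zscoreNormalize(cbind(c(1, 2, 3), c(5, 5, 5))),
                 "zero-variance")
  expect_equal(ncol(envelopeMatrix(fs2)), 1L)
  expect_error(zscoreNormalize(cbind(c(1, 2, 3), c(5, 5, 5)), strict = TRUE),
               "zero-variance")
  # stored stats applied to the window itself give mean 0, sd 1
  set.seed(3)
  env <- matrix(rexp(500), 100, 5)
  win <- 11:60
  fs3 <- zscoreNormalize(env, win)
  z <- envelopeMatrix(fs3)[win, ]
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(z^2) - colMeans(z)^2) - 1)), 1e-9)
})

test_that("the preprocessing chain yields channels x bands features at 100 Hz", {
  set.seed(5)
  ses <- rawSession(matrix(rnorm(4000 * 3), ncol = 3), 1000)
  fs <- preprocessSession(ses, pipelineConfig())
  expect_s4_class(fs, "FeatureSeries")
  expect_equal(dim(envelopeMatrix(fs)), c(400L, 21L))  # 3 channels x 7 bands
  expect_equal(samplingRate(fs), 100)
  expect_equal(featureChannels(fs), rep(1:3, each = 7))
  expect_equal(featureBands(fs), rep(1:7, times = 3))
  # determinism: identical input and config give bit-identical output
  fs2 <- preprocessSession(ses, pipelineConfig())
  expect_identical(envelopeMatrix(fs), envelopeMatrix(fs2))
})

test_that("a channel whose band envelope is modulated is found by correlation", {
  # amplitude-modulate the beta2 carrier of channel 2 with a slow signal
  set.seed(11)
  fs <- 1000
  n <- 60000
  t <- (seq_len(n) - 1) / fs
  modulator <- 1 + 0.8 * sin(2 * pi * 0.2 * t)
  sig <- matrix(rnorm(n * 3, sd = 0.3), n, 3)
  carrier <- sin(2 * pi * 25 * t)
  sig[, 2] <- sig[, 2] + carrier * modulator
  ses <- rawSession(sig, fs)
  feats <- preprocessSession(ses, pipelineConfig())
  m100 <- modulator[seq(1, n, by = 10)]
  ccs <- abs(apply(envelopeMatrix(feats)[300:6000, ], 2, cor,
                   y = m100[300:6000]))
  best <- which.max(ccs)
  expect_equal(featureChannels(feats)[best], 2L)
  expect_equal(featureBands(feats)[best], 5L)  # beta2 holds 25 Hz
})

test_that("configuration defaults encode the published analysis constants", {
  cfg <- pipelineConfig()
  expect_equal(unname(cfg@bandEdges),
               cbind(c(0.5, 4, 8, 14, 20, 30, 50),
                     c(4, 8, 14, 20, 30, 50, 90)))
  expect_equal(cfg@bandNames,
               c("delta", "theta", "alpha", "beta1", "beta2",
                 "gamma1", "gamma2"))
  expect_equal(cfg@bpOrder, 4L)
  expect_equal(cfg@lpCutoff, 2.2)
  expect_equal(cfg@lpOrder, 2L)
  expect_equal(cfg@fsOut, 100)
  expect_equal(cfg@nLags, 100L)
  expect_equal(cfg@lagStep, 0.01)
  expect_equal(cfg@velocityThresholdFraction, 0.05)
  # invalid combinations are rejected
  expect_error(pipelineConfig(lagStep = 0.02), "sampling interval")
  expect_error(pipelineConfig(velocityThresholdFraction = 1.2), "0, 1")
})
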