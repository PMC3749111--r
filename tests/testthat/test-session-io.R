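test_that("CSV sessions round-trip exactly", {
  set.seed(41)
  ses <- rawSession(matrix(rnorm(20), 10, 2), 1000,
                    markers = matrix(rnorm(9), 1, 9), fsMarkers = 100)
  sig <- tempfile(fileext = ".csv"); mrk <- tempfile(fileext = ".csv")
  writeSession(ses, sig, mrk)
  # marker/signal durations differ grossly here; read the signal alone
  back <- readSession(sig)
  expect_equal(dim(signalMatrix(back)), c(10L, 2L))
  expect_equal(samplingRate(back), 1000)
  expect_lt(max(abs(signalMatrix(back) - signalMatrix(ses))), 1e-12)
  expect_equal(channelLabels(back), channelLabels(ses))
  unlink(c(sig, mrk))
})

test_that("sessions with markers validate alignment and units", {
  set.seed(42)
  n <- 2000
  ses <- rawSession(matrix(rnorm(n * 2), n, 2), 1000,
                    markers = matrix(rnorm(200 * 9), 200, 9))
  sig <- tempfile(fileext = ".csv"); mrk <- tempfile(fileext = ".csv")
  writeSession(ses, sig, mrk)
  back <- readSession(sig, mrk)
  expect_lt(max(abs(markerMatrix(back) - markerMatrix(ses))), 1e-12)
  # unit conversion on load
  backCm <- readSession(sig, mrk, markerUnits = "cm")
  expect_equal(markerMatrix(backCm), markerMatrix(back) * 0.01)
  # mismatched durations are an alignment error
  shortM <- tempfile(fileext = ".csv")
  d <- read.csv(mrk)
  write.csv(d[1:50, ], shortM, row.names = FALSE)
  expect_error(readSession(sig, shortM), "alignment error")
  # schema and parse errors
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 1:3, sx = 1:3), bad, row.names = FALSE)
  expect_error(readSession(sig, bad), "schema error")
  unlink(c(sig, mrk, shortM, bad))
})

test_that("EDF files round-trip within quantization error", {
  set.seed(43)
  fs <- 500
  n <- 3 * fs  # three 1 s records
  x <- matrix(sin(2 * pi * 7 * (1:n) / fs) + rnorm(n) * 0.1, n, 1)
  x <- cbind(x, 5 + cumsum(rnorm(n, sd = 0.01)))
  labels <- c("C3", "C4")
  path <- tempfile(fileext = ".edf")
  writeEdf(x, fs, labels, path)
  e <- readEdf(path)
  expect_equal(e$fs, fs)
  expect_equal(e$labels, labels)
  expect_equal(dim(e$signal), dim(x))
  # 16-bit quantization over the per-channel range
  for (ch in 1:2) {
    qstep <- (max(x[, ch]) - min(x[, ch])) / 65535
    expect_lt(max(abs(e$signal[, ch] - x[, ch])), qstep)
  }
  # readSession dispatches on the extension
  ses <- readSession(path)
  expect_equal(channelLabels(ses), labels)
  expect_equal(samplingRate(ses), fs)
  unlink(path)
})

test_that("an EDF written here is readable by an independent implementation", {
  set.seed(44)
  x <- matrix(rnorm(1000 * 15), 1000, 15)
  path <- tempfile(fileext = ".edf")
  writeEdf(x, 1000, sprintf("ch%02d", 1:15), path)
  py <- sprintf(paste0(
    "import mne, sys\n",
    "raw = mne.io.read_raw_edf('%s', verbose='error')\n",
    "d = raw.get_data()\n",
    "print(d.shape[0], d.shape[1], int(raw.info['sfreq']))\n"), path)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = FALSE)
  expect_equal(tail(out, 1), "15 1000 1000")
  unlink(path)
})

test_that("truncated EDF input errors rather than returning a partial read", {
  set.seed(45)
  x <- matrix(rnorm(400), 200, 2)
  path <- tempfile(fileext = ".edf")
  writeEdf(x, 100, c("a", "b"), path)
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 100)], path)
  expect_error(readEdf(path), "truncated EDF")
  unlink(path)
})

test_that("decoder models round-trip bit-exactly through JSON", {
  env <- makeEnvelopeSession(nTrials = 2, trialLen = 300, restLen = 80,
                             nFeatures = 4, lag = 3, seed = 46)
  fs <- zscoreNormalize(env$raw$env,
                        channelOfFeature = env$raw$channelOfFeature,
                        bandOfFeature = env$raw$bandOfFeature,
                        bandNames = env$raw$bandNames,
                        channelLabels = env$raw$channelLabels)
  d <- buildDesign(fs, env$target, trialMask(env$trials, env$n), m = 6)
  model <- fitSLR(d, target = "y",
                  config = ecogtraj:::.configSnapshot(pipelineConfig()))
  path <- tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(modelBias(back), modelBias(model))
  expect_identical(modelWeights(back), modelWeights(model))
  expect_identical(activeColumns(back), activeColumns(model))
  expect_identical(back@beta, model@beta)
  expect_identical(back@alpha, model@alpha)
  # identical predictions on a fixed input
  p1 <- predictSeries(model, fs)
  p2 <- predictSeries(back, fs)
  expect_identical(p1, p2)
  # version and corruption guards
  txt <- readLines(path)
  writeLines(sub('"format_version":"1"', '"format_version":"99"', txt), path)
  expect_error(loadModel(path), "version mismatch.*99")
  writeLines(substr(paste(txt, collapse = ""), 1, 80), path)
  expect_error(loadModel(path), "corrupt model file")
  unlink(path)
})

test_that("prediction refuses features from a mismatched preprocessing config", {
  env <- makeEnvelopeSession(nTrials = 2, trialLen = 250, restLen = 80,
                             nFeatures = 4, seed = 47)
  fs <- zscoreNormalize(env$raw$env, fs = 100)
  d <- buildDesign(fs, env$target, m = 5)
  model <- fitSLR(d, target = "y",
                  config = list(fsOut = 50))  # trained at another rate
  expect_error(predictSeries(model, fs), "preprocessing mismatch")
})

test_that("feature series and trial sets export to readable tables", {
  env <- makeEnvelopeSession(nTrials = 2, trialLen = 250, restLen = 80,
                             nFeatures = 4, seed = 48)
  fs <- zscoreNormalize(env$raw$env,
                        channelOfFeature = env$raw$channelOfFeature,
                        bandOfFeature = env$raw$bandOfFeature,
                        bandNames = env$raw$bandNames,
                        channelLabels = env$raw$channelLabels)
  csv <- tempfile(fileext = ".csv")
  exportFeatureSeries(fs, csv)
  d <- read.csv(csv)
  expect_equal(nrow(d), env$n)
  expect_equal(ncol(d), 5L)
  side <- jsonlite::fromJSON(paste0(csv, ".json"))
  expect_equal(side$sigma, normalizationStats(fs)$sigma, tolerance = 1e-12)
  trCsv <- tempfile(fileext = ".csv")
  exportTrialSet(env$trials, trCsv)
  td <- read.csv(trCsv)
  expect_equal(nrow(td), 2L)
  expect_equal(td$status, rep("retained", 2))
  unlink(c(csv, paste0(csv, ".json"), trCsv))
})
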