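test_that("pearson CC matches brute-force evaluation and flags constants", {
  expect_equal(pearsonCC(c(1, 2, 3, 4), c(1, 2, 2, 5)), 6 / sqrt(45),
               tolerance = 1e-12)
  set.seed(10)
  x <- rnorm(50)
  expect_equal(pearsonCC(x, x), 1)
  expect_equal(pearsonCC(x, -x), -1)
  expect_true(is.na(pearsonCC(rep(1, 10), rnorm(10))))
  for (r in 1:100) {
    p <- rnorm(30); a <- rnorm(30)
    expect_equal(pearsonCC(p, a), bruteCC(p, a), tolerance = 1e-12)
  }
})

test_that("nRMSE matches direct computation and its algebraic identities", {
  expect_equal(nrmse(c(0, 1, 3), c(0, 1, 2)), sqrt(1 / 3) / 2, tolerance = 1e-12)
  set.seed(11)
  a <- rnorm(40)
  expect_equal(nrmse(a, a), 0)
  # constant offset: |c| / range
  expect_equal(nrmse(a + 0.3, a), 0.3 / (max(a) - min(a)), tolerance = 1e-12)
  expect_true(is.na(nrmse(rnorm(10), rep(2, 10))))
  for (r in 1:100) {
    p <- rnorm(25); a <- rnorm(25)
    expect_equal(nrmse(p, a), bruteNrmse(p, a), tolerance = 1e-12)
  }
  # sd normalization variant
  expect_equal(nrmse(a + 0.3, a, normalization = "sd"), 0.3 / sd(a),
               tolerance = 1e-12)
})

test_that("CC and nRMSE transform correctly under affine maps", {
  set.seed(12)
  p <- rnorm(60); a <- rnorm(60)
  expect_equal(pearsonCC(2.7 * p + 3, a), pearsonCC(p, a), tolerance = 1e-12)
  s <- 3.2; b <- -1
  expect_equal(nrmse(s * p + b, s * a + b), nrmse(p, a), tolerance = 1e-12)
})

test_that("LOO-CV scores every trial per target with training-only statistics", {
  env <- makeEnvelopeSession(nTrials = 4, trialLen = 500, restLen = 120,
                             nFeatures = 6, lag = 5, seed = 31)
  cfg <- pipelineConfig(nLags = 12L, maxIter = 40L, designStride = 2L)
  targets <- cbind(v1 = env$target,
                   v2 = 2 - 0.5 * env$target)
  rep <- looDecodeEnvelopes(env$raw, targets, env$trials, cfg)
  pt <- perTrialScores(rep)
  expect_equal(nrow(pt), 4 * 2)      # one row per trial per variable
  expect_true(all(table(pt$variable) == 4))
  # noise-free linear construction: decoder class matches the generator
  agg <- aggregateScores(rep)
  expect_true(all(agg$mean_cc >= 0.99))
  expect_true(all(pt$cc >= -1 & pt$cc <= 1))
  expect_true(all(pt$nrmse >= 0))
  # aggregate equals the arithmetic mean / SEM of the per-trial rows
  for (v in agg$variable) {
    rows <- pt[pt$variable == v, ]
    expect_equal(agg$mean_cc[agg$variable == v], mean(rows$cc),
                 tolerance = 1e-12)
    expect_equal(agg$sem_cc[agg$variable == v],
                 sd(rows$cc) / sqrt(nrow(rows)), tolerance = 1e-12)
    expect_equal(agg$sem_nrmse[agg$variable == v],
                 sd(rows$nrmse) / sqrt(nrow(rows)), tolerance = 1e-12)
  }
})

test_that("an 11-trial session yields 11 scored rows per decoded variable", {
  env <- makeEnvelopeSession(nTrials = 11, trialLen = 250, restLen = 80,
                             nFeatures = 3, lag = 3, seed = 32)
  cfg <- pipelineConfig(nLags = 6L, maxIter = 20L)
  rep <- looDecodeEnvelopes(env$raw, cbind(y = env$target), env$trials, cfg)
  expect_equal(nrow(perTrialScores(rep)), 11L)
  expect_equal(aggregateScores(rep)$n_trials, 11L)
})

test_that("band restriction uses only that band's features", {
  env <- makeEnvelopeSession(nTrials = 3, trialLen = 400, restLen = 100,
                             nFeatures = 6, lag = 4, seed = 33)
  # make the target depend on band 'low' features only (odd columns)
  lowCols <- which(env$raw$bandOfFeature == 1L)
  y <- rowSums(env$raw$env[, lowCols]) * 0.8
  y <- c(rep(y[1], 4), y[seq_len(env$n - 4)])
  cfg <- pipelineConfig(nLags = 8L, maxIter = 30L)
  repLow <- looDecodeEnvelopes(env$raw, cbind(y = y), env$trials, cfg,
                               band = "low")
  repHigh <- looDecodeEnvelopes(env$raw, cbind(y = y), env$trials, cfg,
                                band = "high")
  expect_gt(aggregateScores(repLow)$mean_cc,
            aggregateScores(repHigh)$mean_cc)
  expect_gt(aggregateScores(repLow)$mean_cc, 0.95)
  expect_error(looDecodeEnvelopes(env$raw, cbind(y = y), env$trials, cfg,
                                  band = "gamma9"), "unknown band")
})

test_that("per-band design restriction has the expected column count", {
  # delta-only restriction on 60 channels: 60 x 100 + 1 columns
  expect_equal(60L * 100L + 1L, 6001L)
  env <- makeEnvelopeSession(nTrials = 2, trialLen = 300, restLen = 80,
                             nFeatures = 6, seed = 34)
  raw <- ecogtraj:::.restrictBand(env$raw, "high")
  expect_equal(ncol(raw$env), 3L)
  d <- buildDesign(zscoreNormalize(raw$env), env$target, m = 10)
  expect_equal(ncol(d@X), 3L * 10L + 1L)
})

test_that("corrupting the held-out trial never touches the training fits", {
  env <- makeEnvelopeSession(nTrials = 3, trialLen = 300, restLen = 100,
                             nFeatures = 4, lag = 3, noiseSd = 0.05, seed = 35)
  cfg <- pipelineConfig(nLags = 6L, maxIter = 15L)
  res <- looDecodeEnvelopes(env$raw, cbind(y = env$target), env$trials, cfg,
                            returnModels = TRUE)
  hashes <- vapply(res$models, function(f) modelHash(f$y), "")
  # corrupt every sample of trial 2 (features and target) and refit
  iv <- trialIntervals(env$trials)
  idx <- iv[2, 1]:(iv[2, 2] - 1)
  env2 <- env
  set.seed(99)
  env2$raw$env[idx, ] <- matrix(10 * rnorm(length(idx) * 4), ncol = 4)
  y2 <- env$target
  y2[idx] <- sample(y2[idx])
  res2 <- looDecodeEnvelopes(env2$raw, cbind(y = y2), env2$trials, cfg,
                             returnModels = TRUE)
  hashes2 <- vapply(res2$models, function(f) modelHash(f$y), "")
  # fold 2's own model is trained on the other trials: unchanged; the other
  # folds' training sets contain trial 2: changed
  expect_identical(hashes[2], hashes2[2])
  expect_false(hashes[1] == hashes2[1])
  # and fold 2's test-trial score does change
  cc1 <- perTrialScores(res$report)$cc[2]
  cc2 <- perTrialScores(res2$report)$cc[2]
  expect_false(isTRUE(all.equal(cc1, cc2)))
})
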