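# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code at test time; no stored data.

# brute-force Pearson correlation straight from the defining formula
bruteCC <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force normalized RMSE (range normalization)
bruteNrmse <- function(p, a) {
  sqrt(sum((p - a)^2) / length(a)) / (max(a) - min(a))
}

# trial set with intervals laid out as  rest | trial | rest | trial | ...
makeTrialSet <- function(nTrials, trialLen, restLen, fs = 100) {
  starts <- restLen + (seq_len(nTrials) - 1L) * (trialLen + restLen) + 1L
  iv <- cbind(start = starts, end = starts + trialLen)
  n <- nTrials * (trialLen + restLen) + restLen
  new("TrialSet", intervals = iv,
      excluded = data.frame(start = integer(0), end = integer(0),
                            reason = character(0)),
      fs = fs, sourceSpeed = numeric(n), thresholdFraction = 0.05)
}

# envelope-level synthetic session: smooth positive envelopes plus a target
# that is an exact lagged linear function of them (noise-free by default).
# Returns a list shaped like rawEnvelopes() output plus target/trials.
makeEnvelopeSession <- function(nTrials = 4, trialLen = 600, restLen = 150,
                                nFeatures = 6, lag = 5, noiseSd = 0,
                                seed = 1, fs = 100) {
  set.seed(seed)
  trials <- makeTrialSet(nTrials, trialLen, restLen, fs)
  n <- nTrials * (trialLen + restLen) + restLen
  lp <- signal::butter(2, 0.02, type = "low")
  env <- vapply(seq_len(nFeatures), function(f)
    1 + 0.5 * as.numeric(signal::filtfilt(lp, rnorm(n))), numeric(n))
  w <- rnorm(nFeatures)
  y <- as.numeric(env %*% w)
  y <- c(rep(y[1], lag), y[seq_len(n - lag)])  # target lags the envelopes
  if (noiseSd > 0) y <- y + rnorm(n, sd = noiseSd)
  nb <- 2L  # pretend two bands so band bookkeeping is exercised
  list(raw = list(env = env,
                  channelOfFeature = as.integer(rep(seq_len(ceiling(nFeatures / nb)),
                                                    each = nb))[seq_len(nFeatures)],
                  bandOfFeature = as.integer(rep(seq_len(nb),
                                                 length.out = nFeatures)),
                  bandNames = c("low", "high"),
                  channelLabels = paste0("ch", seq_len(ceiling(nFeatures / nb))),
                  fs = fs),
       target = y, trials = trials, weights = w, lag = lag, n = n)
}

# md5 fingerprint of a model's fitted state (no digest dependency)
modelHash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(model@w0, model@weights, model@alpha, model@beta,
               model@activeSet), f, compress = FALSE)
  unname(tools::md5sum(f))
}

# minimum-jerk wrist path of length `d` meters over `T` seconds along +x
minJerkPath <- function(d = 0.25, T = 1, fs = 100, lead = 100, trail = 100) {
  tau <- seq(0, 1, length.out = round(T * fs) + 1)
  s <- d * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  x <- c(rep(0, lead), s, rep(d, trail))
  cbind(x = x, y = 0, z = 0)
}
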