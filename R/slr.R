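## Sparse Bayesian linear regression by automatic relevance determination
## (ARD), evidence-approximation fixed-point updates:
##   Sigma = (beta X'X + diag(alpha))^-1,  m = beta Sigma X' y
##   gamma_k = 1 - alpha_k Sigma_kk,  alpha_k <- gamma_k / m_k^2
##   beta <- (N - sum(gamma)) / ||y - X m||^2
## Columns whose alpha exceeds the prune threshold leave the active set with
## weight exactly zero, which keeps the linear solves at active-set size.
## When the active set is larger than the number of rows, the posterior
## moments are computed through the dual (Woodbury) form
##   m = A^-1 X' C^-1 y,  diag(Sigma) = 1/alpha - colSums(W * C^-1 W),
##   C = I/beta + X A^-1 X',  W = X A^-1,
## so 10k-column lagged designs stay tractable.
## The bias is an unpenalized coefficient, realized by centering the feature
## columns and the target over the training rows; it is never pruned.

.ardMoments <- function(Xa, y, alphaA, beta, jitterScale = 1e-10) {
  N <- nrow(Xa); Ka <- ncol(Xa)
  if (Ka == 0L) {
    return(list(m = numeric(0), Sdiag = numeric(0), rss = sum(y^2),
                evidence = -0.5 * (N * log(2 * pi) - N * log(beta) + beta * sum(y^2))))
  }
  if (Ka <= N) {
    H <- beta * crossprod(Xa)
    dg <- diag(H) + alphaA
    jit <- jitterScale * sum(dg) / Ka
    diag(H) <- dg + jit
    ch <- chol(H)
    Xty <- crossprod(Xa, y)
    m <- beta * backsolve(ch, backsolve(ch, Xty, transpose = TRUE))
    Sdiag <- diag(chol2inv(ch))
    resid <- y - as.numeric(Xa %*% m)
    rss <- sum(resid^2)
    logdetH <- 2 * sum(log(diag(ch)))
    evidence <- 0.5 * (sum(log(alphaA)) + N * log(beta) - N * log(2 * pi) -
                       logdetH - beta * rss - sum(alphaA * m^2))
  } else {
    Ainv <- 1 / alphaA
    W <- Xa * rep(Ainv, each = N)
    G <- tcrossprod(W, Xa)
    dg <- diag(G) + 1 / beta
    jit <- jitterScale * sum(dg) / N
    diag(G) <- dg + jit
    ch <- chol(G)
    cy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    m <- Ainv * as.numeric(crossprod(Xa, cy))
    V <- backsolve(ch, backsolve(ch, W, transpose = TRUE))
    Sdiag <- Ainv - colSums(W * V)
    Sdiag[Sdiag < 0] <- 0
    resid <- y - as.numeric(Xa %*% m)
    rss <- sum(resid^2)
    logdetC <- 2 * sum(log(diag(ch)))
    evidence <- -0.5 * (N * log(2 * pi) + logdetC + sum(y * cy))
  }
  list(m = as.numeric(m), Sdiag = as.numeric(Sdiag), rss = rss,
       evidence = evidence)
}

## Relevance audit (Tipping-Faul statistics): with S_k = x_k' C^-1 x_k,
## Q_k = x_k' C^-1 y, s_k = alpha_k S_k / (alpha_k - S_k),
## q_k = alpha_k Q_k / (alpha_k - S_k), the per-column marginal likelihood
## is maximized at alpha -> infinity iff q_k^2 <= s_k, and retaining the
## column at its optimal alpha buys a log-evidence gain of
## (r - 1 - log r)/2 nats, r = q_k^2/s_k.  Under a pure-noise column r is
## ~chi-square(1), so r barely above 1 occurs in a third of null columns;
## requiring a minimal evidence gain (Occam margin) removes those while
## leaving genuinely supported columns untouched.
.relevanceKeep <- function(Xa, y, alphaA, beta, minGain = 0.5) {
  G <- crossprod(Xa)
  Xty <- as.numeric(crossprod(Xa, y))
  H <- beta * G
  diag(H) <- diag(H) + alphaA + 1e-10 * sum(diag(H) + alphaA) / ncol(Xa)
  Sig <- chol2inv(chol(H))
  m <- beta * as.numeric(Sig %*% Xty)
  S <- beta * diag(G) - beta^2 * colSums(G * (Sig %*% G))
  Q <- beta * Xty - beta * as.numeric(G %*% m)
  denom <- alphaA - S
  s <- alphaA * S / denom
  q <- alphaA * Q / denom
  r <- q^2 / s
  gain <- numeric(length(r))
  pos <- which(is.finite(r) & r > 1)
  gain[pos] <- 0.5 * (r[pos] - 1 - log(r[pos]))
  denom <= 0 | gain > minGain
}

#' Fit the lagged decoder by sparse Bayesian linear regression
#'
#' Automatic relevance determination with per-column precision
#' hyperparameters, fixed-point (evidence approximation) updates, active-set
#' pruning, and early stopping on a chronological validation holdout
#' ("terminate just before over-training"): the last `validationFraction` of
#' design rows is held out, fitting stops after `patience` consecutive
#' validation-MSE increases, and the snapshot with the best validation MSE
#' is returned.  Initialization: `alpha = 1` for every column,
#' `beta = 1/var(y)`.
#'
#' @param design a [LaggedDesign-class].
#' @param maxIter maximum number of update iterations.
#' @param pruneThreshold columns with `alpha` above this are removed from
#'   the active set (weight exactly 0); `Inf` disables pruning.
#' @param validationFraction fraction in `[0, 0.5)` of (chronologically
#'   last) rows held out for early stopping; 0 disables the holdout.
#' @param patience consecutive validation-MSE rises tolerated before
#'   stopping.
#' @param tolerance relative weight-change convergence threshold.
#' @param betaCapRel upper bound on `beta * var(y)` (the implied training
#'   signal-to-noise ratio); keeps the noise-precision update finite on
#'   interpolating designs.
#' @param target optional name of the decoded variable (metadata).
#' @param config optional list snapshot of the preprocessing configuration.
#' @return A [DecoderModel-class].
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(300), ncol = 3)
#' y <- c(0, 2 * z[-nrow(z), 1])  # y(t) = 2 z1(t-1)
#' d <- buildDesign(z, y, m = 1)
#' fitSLR(d, validationFraction = 0)
#' @export
fitSLR <- function(design, maxIter = 50L, pruneThreshold = 1e12,
                   validationFraction = 0.1, patience = 3L,
                   tolerance = 1e-6, betaCapRel = 1e8,
                   target = character(0), config = list()) {
  stopifnot(is(design, "LaggedDesign"))
  X <- design@X
  y <- design@y
  N <- nrow(X)
  K <- ncol(X) - 1L   # feature columns (bias excluded)
  if (N < 2) stop("design must have at least 2 rows")
  if (anyNA(X) || anyNA(y)) stop("design contains NA")
  if (validationFraction < 0 || validationFraction >= 0.5)
    stop("validationFraction must lie in [0, 0.5)")
  if (patience < 1) stop("patience must be >= 1")

  nVal <- if (validationFraction > 0) max(1L, floor(validationFraction * N)) else 0L
  nTr <- N - nVal
  if (nTr < 2) stop("too few training rows after validation split")
  trIdx <- seq_len(nTr)
  valIdx <- if (nVal) (nTr + 1L):N else integer(0)

  Xf <- X[, -1L, drop = FALSE]
  yTr <- y[trIdx]
  vy <- var(yTr) * (nTr - 1) / nTr

  if (K == 0L) {
    ## bias-only design: the posterior mean of an unpenalized intercept
    return(new("DecoderModel", w0 = mean(yTr), weights = numeric(0),
               alpha = numeric(0), beta = if (vy > 0) 1 / vy else 1e12,
               activeSet = integer(0), nItersRun = 0L,
               earlyStopReason = "converged",
               nFeatures = design@nFeatures, nLags = design@nLags,
               channelOfFeature = design@channelOfFeature,
               bandOfFeature = design@bandOfFeature,
               bandNames = design@bandNames,
               channelLabels = design@channelLabels,
               target = as.character(target), config = config,
               trace = data.frame()))
  }
  if (vy <= 0)
    stop("degenerate design: target has zero variance over the training rows")

  cmX <- colMeans(Xf[trIdx, , drop = FALSE])
  cmY <- mean(yTr)
  Xc <- sweep(Xf[trIdx, , drop = FALSE], 2, cmX)
  yc <- yTr - cmY
  XvC <- if (nVal) sweep(Xf[valIdx, , drop = FALSE], 2, cmX) else NULL
  yv <- if (nVal) y[valIdx] else NULL

  alpha <- rep(1, K)
  beta <- 1 / vy
  active <- seq_len(K)
  wPrev <- rep(0, K)
  best <- NULL
  bestVal <- Inf
  prevVal <- Inf
  rises <- 0L
  reason <- "max_iter"
  trace <- vector("list", maxIter)
  iter <- 0L

  for (iter in seq_len(maxIter)) {
    mo <- .ardMoments(Xc[, active, drop = FALSE], yc, alpha[active], beta)
    w <- rep(0, K)
    w[active] <- mo$m
    w0 <- cmY - sum(cmX * w)
    trainMse <- mo$rss / nTr
    valMse <- NA_real_
    if (nVal) {
      predV <- cmY + as.numeric(XvC[, active, drop = FALSE] %*% mo$m)
      valMse <- mean((yv - predV)^2)
    }
    trace[[iter]] <- data.frame(iter = iter, train_mse = trainMse,
                                val_mse = valMse, active = length(active),
                                evidence = mo$evidence)
    snap <- list(w = w, w0 = w0, alpha = alpha, beta = beta,
                 active = active, iter = iter)
    if (!nVal || valMse <= bestVal) {
      bestVal <- if (nVal) valMse else -iter  # without holdout keep latest
      best <- snap
    }
    if (nVal) {
      if (valMse > prevVal) rises <- rises + 1L else rises <- 0L
      prevVal <- valMse
      if (rises >= patience) { reason <- "validation_rise"; break }
    }
    if (!all(is.finite(mo$m)) || !all(is.finite(mo$Sdiag)))
      stop("non-finite posterior moments at iteration ", iter)
    ## fixed-point hyperparameter updates
    gam <- 1 - alpha[active] * mo$Sdiag
    gam[gam < 0] <- 0
    gam[gam > 1] <- 1
    alphaOld <- alpha[active]
    newAlpha <- ifelse(mo$m^2 > 0, gam / mo$m^2, Inf)
    alpha[active] <- newAlpha
    denom <- max(nTr - sum(gam), 1e-3)
    beta <- denom / max(mo$rss, 1e-300)
    ## scale-relative cap: in the interpolating regime (columns >> rows)
    ## the training residual collapses and the raw update sends beta to
    ## infinity, freezing the alpha dynamics; bounding the implied SNR
    ## keeps pruning moving without affecting well-posed problems
    beta <- min(beta, betaCapRel / vy)
    ## convergence: weights stable AND relevance precisions stable (alphas
    ## of eventually-pruned columns keep growing until they cross the
    ## threshold, so weight stability alone is not convergence)
    dw <- sqrt(sum((w - wPrev)^2)) / max(sqrt(sum(w^2)), 1e-300)
    wPrev <- w
    da <- max(abs(log(pmin(pmax(newAlpha, 1e-300), 1e300)) -
                  log(pmin(pmax(alphaOld, 1e-300), 1e300))))
    if (iter > 1L && dw < tolerance && da < 1e-2) {
      ## before declaring convergence, audit the active set: drop columns
      ## whose evidence is maximized at infinite alpha (cheap only in the
      ## overdetermined regime; elsewhere the validation stop governs)
      if (is.finite(pruneThreshold) && length(active) <= nTr) {
        keepRel <- .relevanceKeep(Xc[, active, drop = FALSE], yc,
                                  alpha[active], beta)
        if (!all(keepRel)) {
          alpha[active[!keepRel]] <- Inf
          active <- active[keepRel]
          if (length(active)) next
        }
      }
      reason <- "converged"
      break
    }
    keep <- which(alpha[active] < pruneThreshold & is.finite(alpha[active]))
    active <- active[keep]
    if (!length(active)) {
      ## everything pruned: intercept-only model from this point on
      mo0 <- .ardMoments(matrix(0, nTr, 0), yc, numeric(0), beta)
      trace[[iter]] <- trace[[iter]]  # keep last record
      snap <- list(w = rep(0, K), w0 = cmY, alpha = alpha, beta = beta,
                   active = integer(0), iter = iter)
      if (nVal) {
        valMse0 <- mean((yv - cmY)^2)
        if (valMse0 <= bestVal) { bestVal <- valMse0; best <- snap }
      } else best <- snap
      reason <- "converged"
      break
    }
  }
  tr <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  act <- sort(best$active)
  w <- best$w
  w[setdiff(seq_len(K), act)] <- 0
  alphaOut <- best$alpha
  alphaOut[setdiff(seq_len(K), act)] <- Inf
  new("DecoderModel",
      w0 = best$w0, weights = w, alpha = alphaOut, beta = best$beta,
      activeSet = as.integer(act), nItersRun = as.integer(iter),
      earlyStopReason = reason,
      nFeatures = design@nFeatures, nLags = design@nLags,
      channelOfFeature = design@channelOfFeature,
      bandOfFeature = design@bandOfFeature,
      bandNames = design@bandNames,
      channelLabels = design@channelLabels,
      target = as.character(target), config = config, trace = tr)
}

#' Sparsity diagnostics of a fitted decoder
#'
#' Aggregates absolute weight mass per (channel, band) cell, ordered by
#' nonincreasing mass.  Masses sum to the total absolute weight mass of the
#' model.
#'
#' @param model a [DecoderModel-class] fitted on a design built from a
#'   [FeatureSeries-class] (so feature metadata is available).
#' @return data.frame: `channel`, `band`, `mass`, `fraction`, `n_active`.
#' @export
sparsityReport <- function(model) {
  stopifnot(is(model, "DecoderModel"))
  if (!length(model@channelOfFeature))
    stop("model carries no channel/band metadata")
  if (!length(model@activeSet)) {
    warning("empty active set: all weights pruned")
    return(data.frame(channel = character(0), band = character(0),
                      mass = numeric(0), fraction = numeric(0),
                      n_active = integer(0)))
  }
  m <- model@nLags
  act <- model@activeSet
  feat <- (act - 1L) %/% m + 1L
  w <- abs(model@weights[act])
  ch <- model@channelOfFeature[feat]
  bd <- model@bandOfFeature[feat]
  key <- paste(ch, bd, sep = ":")
  mass <- tapply(w, key, sum)
  cnt <- tapply(w, key, length)
  parts <- strsplit(names(mass), ":", fixed = TRUE)
  chI <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  bdI <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  out <- data.frame(
    channel = if (length(model@channelLabels)) model@channelLabels[chI] else as.character(chI),
    band = if (length(model@bandNames)) model@bandNames[bdI] else as.character(bdI),
    mass = as.numeric(mass),
    fraction = as.numeric(mass) / sum(w),
    n_active = as.integer(cnt),
    stringsAsFactors = FALSE)
  out[order(-out$mass), , drop = FALSE]
}
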