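# Shared fixtures and independent oracles.

# A small, fast synthetic configuration (shorter sessions, coarser
# sampling) that keeps kernel geometry at the reference defaults.
smallSimConfig <- function(..., nTrials = 8, samplingRateHz = 250,
                           itiMeanS = 20, seed = 1) {
  simConfig(nTrials = nTrials, samplingRateHz = samplingRateHz,
            itiMeanS = itiMeanS, seed = seed, ...)
}

# Generate + preprocess + align both sensors of one synthetic session.
runSessionPipeline <- function(out, cfg = analysisConfig()) {
  sess <- out$session
  ev <- sessionEvents(sess, "lever_extension")
  info <- data.frame(latency_s = out$truth$latency_s)
  tmA <- alignTrials(processSession(sess, "ACh", cfg), ev, cfg,
                     trialInfo = info)
  tmD <- alignTrials(processSession(sess, "DA", cfg), ev, cfg,
                     trialInfo = info)
  list(tmA = tmA, tmD = tmD)
}

# Trapezoid integral of the piecewise-linear path through (tt, y) over
# [t0, t1] -- independent of the package's integrator.
oracleTrapz <- function(tt, y, t0, t1) {
  dense <- seq(t0, t1, length.out = 20001)
  yd <- approx(tt, y, xout = dense, rule = 2)$y
  sum((yd[-1] + yd[-length(yd)]) / 2) * (dense[2] - dense[1])
}

# Brute-force dip quantification on a densely oversampled copy of a
# piecewise-linear row: min over (0, W], zero crossings by sign scan on
# the dense grid, Riemann integrals for the AUC components.
oracleDipMetrics <- function(tt, y, W, oversample = 1000) {
  dt <- median(diff(tt))
  dense <- seq(tt[1], tt[length(tt)], by = dt / oversample)
  yd <- approx(tt, y, xout = dense)$y
  sel <- dense > 0 & dense <= W
  amp <- min(yd[sel])
  res <- list(amplitude = amp, duration = 0, neg = 0, rebound = 0,
              total = sum(yd[sel]) * dt / oversample)
  if (amp >= 0) return(res)
  iMin <- which(sel)[which.min(yd[sel])]
  iPre <- iMin
  while (iPre > 1 && yd[iPre - 1] < 0) iPre <- iPre - 1
  tPre <- if (iPre == 1) dense[1] else dense[iPre - 1]
  iPost <- iMin
  while (iPost < length(yd) && yd[iPost + 1] < 0) iPost <- iPost + 1
  censored <- iPost >= length(yd) || dense[iPost + 1] > W
  tPost <- if (censored) W else dense[iPost + 1]
  res$duration <- min(tPost - tPre, W)
  segN <- dense >= max(tPre, 0) & dense <= min(tPost, W)
  res$neg <- sum(yd[segN]) * dt / oversample
  if (!censored) {
    iEnd <- iPost + 1
    while (iEnd < length(yd) && dense[iEnd + 1] <= W &&
           yd[iEnd + 1] >= 0) iEnd <- iEnd + 1
    segR <- dense >= tPost & dense <= dense[iEnd]
    res$rebound <- max(0, sum(yd[segR]) * dt / oversample)
  }
  res
}

# Random piecewise-linear trial row: knots on the sample grid every 0.5 s
# inside (0, 5], zero baseline elsewhere.
randomPiecewiseRow <- function(relTime) {
  y <- numeric(length(relTime))
  knotT <- seq(0.5, 4.5, by = 0.5)
  knotV <- rnorm(length(knotT), 0, 1)
  sel <- relTime > 0 & relTime < 5
  y[sel] <- approx(c(0, knotT, 5), c(0, knotV, 0),
                   xout = relTime[sel])$y
  y
}

# Direct within-subjects sums-of-squares decomposition (loops, no matrix
# shortcuts) as an oracle for rmAnovaOneway.
oracleRmSS <- function(y) {
  n <- nrow(y); m <- ncol(y)
  grand <- mean(y)
  ssCond <- 0
  for (j in 1:m) ssCond <- ssCond + n * (mean(y[, j]) - grand)^2
  ssSubj <- 0
  for (i in 1:n) ssSubj <- ssSubj + m * (mean(y[i, ]) - grand)^2
  ssErr <- 0
  for (i in 1:n) for (j in 1:m)
    ssErr <- ssErr + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + grand)^2
  list(ss_cond = ssCond, ss_subj = ssSubj, ss_err = ssErr)
}
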