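# Lagged Pearson cross-correlation between the DA and ACh dF/F signals.

# Row-wise Pearson correlation between two equally sized matrices.
.rowCor <- function(A, B) {
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  r <- rowSums(Ac * Bc) / den
  r[den == 0] <- NA_real_
  r
}

#' Lag scan of the DA-ACh correlation
#'
#' For every integer-sample lag tau in `[-lagMaxS, +lagMaxS]`, computes
#' the Pearson correlation between the DA row and the tau-shifted ACh row
#' on their overlapping segment, per trial, then averages across trials.
#' Negative tau means the ACh series is shifted so that its features occur
#' after DA's ("ACh lags DA"): at tau = -0.18 s the correlation compares
#' DA at time t with ACh at time t + 0.18 s.
#'
#' @param daTm,achTm paired [TrialMatrix-class] objects (same trials, same
#'   time grid), or plain matrices with an accompanying `dt`.
#' @param config an [AnalysisConfig-class].
#' @param dt sample period in seconds; taken from the trial matrices'
#'   relative time grid when omitted.
#' @param segment `"trial"` or `"iti"`, recorded in the result.
#' @return A [LagCorrResult-class] with `meanR` filled and extrema unset
#'   (apply [findExtrema()]).
#' @export
lagScan <- function(daTm, achTm, config = analysisConfig(), dt = NULL,
                    segment = "trial") {
  if (is(daTm, "TrialMatrix")) {
    if (is.null(dt)) dt <- stats::median(diff(relTime(daTm)))
    da <- trialValues(daTm); ach <- trialValues(achTm)
  } else {
    da <- daTm; ach <- achTm
    if (is.null(dt)) stop("dt required when passing plain matrices")
  }
  if (!all(dim(da) == dim(ach)))
    stop("DA and ACh matrices must have identical dimensions")
  n <- ncol(da)
  K <- round(config@lagMaxS / dt)
  if (n - K < 10)
    stop("overlap at maximum lag is shorter than 10 samples; ",
         "reduce lagMaxS or supply longer segments")
  lags <- (-K):K
  mr <- vapply(lags, function(k) {
    m <- abs(k)
    if (k <= 0) { i <- 1:(n - m); j <- (1 + m):n }
    else { i <- (1 + m):n; j <- 1:(n - m) }
    mean(.rowCor(da[, i, drop = FALSE], ach[, j, drop = FALSE]),
         na.rm = TRUE)
  }, numeric(1))
  new("LagCorrResult", lags = lags * dt, meanR = mr,
      negPeak = list(r = NA_real_, lag_s = NA_real_, var_pct = NA_real_),
      posPeak = list(r = NA_real_, lag_s = NA_real_, var_pct = NA_real_),
      nTrials = nrow(da), segment = segment)
}

#' Identify the correlation extrema of a lag scan
#'
#' The negative peak is the global minimum of the mean correlation curve;
#' the positive peak is the maximum restricted to lags at or below the
#' configured search bound (default -0.5 s), which keeps the rebound
#' extremum clear of the shoulder of the main trough. Ties are broken
#' toward the lag of smaller magnitude.
#'
#' @param result a [LagCorrResult-class] from [lagScan()].
#' @param config an [AnalysisConfig-class].
#' @return The result with `negPeak` and `posPeak` filled (`r`, `lag_s`,
#'   `var_pct`).
#' @export
findExtrema <- function(result, config = analysisConfig()) {
  lags <- result@lags
  mr <- result@meanR
  pick <- function(idx, target) {
    idx <- idx[is.finite(mr[idx])]
    if (!length(idx)) stop("no finite correlations on the lag grid")
    v <- mr[idx]
    best <- if (target == "min") min(v) else max(v)
    cand <- idx[abs(v - best) < 1e-15]
    cand[which.min(abs(lags[cand]))]
  }
  iNeg <- pick(seq_along(lags), "min")
  result@negPeak <- list(r = mr[iNeg], lag_s = lags[iNeg],
                         var_pct = varianceExplained(mr[iNeg]))
  posIdx <- which(lags <= config@posPeakLagBoundS)
  if (!length(posIdx))
    stop("no lags at or below the positive-peak search bound")
  iPos <- pick(posIdx, "max")
  result@posPeak <- list(r = mr[iPos], lag_s = lags[iPos],
                         var_pct = varianceExplained(mr[iPos]))
  result
}

#' Variance explained by a correlation
#'
#' `r^2 x 100`: the percent of one signal's variance linearly predicted by
#' the other (a correlation of 0.5 explains 25%).
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @return Percent variance explained.
#' @examples
#' varianceExplained(0.5)    # 25
#' varianceExplained(-0.521) # 27.14
#' @export
varianceExplained <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  r^2 * 100
}

#' Fisher z-transformation
#'
#' `z = arctanh(r)`; values with `|r| = 1` map to infinity with a warning.
#'
#' @param r Pearson correlation(s).
#' @return z-score(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  if (any(abs(r) == 1)) warning("|r| = 1 gives an infinite z-score")
  atanh(r)
}

#' Compare two independent correlations via Fisher's z
#'
#' Two-sided normal test of `r1 = r2` using
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Pearson correlations (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @return List with `z_stat` and `p`.
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both groups")
  z <- (fisherZ(r1) - fisherZ(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_stat = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Extract paired DA/ACh intertrial-interval segments
#'
#' Processes both sensors of a session to dF/F, removes every peri-event
#' trial window `[-windowPreS, +windowPostS]`, and chunks the remaining
#' intertrial stretches into fixed 10 s pieces so each segment contributes
#' a comparable sample count to the correlation.
#'
#' @param session a [PhotometrySession-class].
#' @param config an [AnalysisConfig-class].
#' @param eventLabel label whose occurrences define the trial windows
#'   (default `"lever_extension"`).
#' @param chunkS segment length in seconds (default 10).
#' @return List with matrices `da` and `ach` (segments x samples), `dt`,
#'   and `nSegments`; zero available segments yields matrices with zero
#'   rows.
#' @export
itiSegments <- function(session, config = analysisConfig(),
                        eventLabel = "lever_extension", chunkS = 10) {
  dffA <- processSession(session, "ACh", config)
  dffD <- processSession(session, "DA", config)
  tt <- dffA$time_s
  dt <- stats::median(diff(tt))
  ev <- sessionEvents(session, eventLabel)
  inTrial <- rep(FALSE, length(tt))
  for (e in ev)
    inTrial <- inTrial | (tt >= e - config@windowPreS &
                          tt <= e + config@windowPostS)
  free <- !inTrial
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nChunk <- max(1L, round(chunkS / dt))
  segIdx <- list()
  for (k in which(r$values)) {
    i <- starts[k]
    while (i + nChunk - 1L <= ends[k]) {
      segIdx[[length(segIdx) + 1L]] <- i:(i + nChunk - 1L)
      i <- i + nChunk
    }
  }
  if (!length(segIdx)) {
    return(list(da = matrix(numeric(0), 0, nChunk),
                ach = matrix(numeric(0), 0, nChunk),
                dt = dt, nSegments = 0L))
  }
  da <- t(vapply(segIdx, function(ix) dffD$dff_pct[ix], numeric(nChunk)))
  ach <- t(vapply(segIdx, function(ix) dffA$dff_pct[ix], numeric(nChunk)))
  list(da = da, ach = ach, dt = dt, nSegments = length(segIdx))
}
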