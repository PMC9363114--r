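# Per-trial quantification of the ACh dip and DA peak.

# Interpolated zero crossings flanking the minimum at index iMin:
# pre = last down-crossing at or before iMin, post = first up-crossing
# after iMin. NA when the signal never returns to zero on that side.
# Samples within `tol` of zero count as zero, so a residual offset far
# smaller than the feature being measured cannot drag a crossing away
# from it.
.zeroCrossings <- function(tt, y, iMin, tol = 0) {
  pre <- NA_real_; post <- NA_real_
  i <- iMin
  while (i > 1) {
    if (y[i - 1] >= -tol) {
      pre <- if (y[i - 1] <= 0) tt[i - 1] else
        tt[i - 1] + (0 - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
      break
    }
    i <- i - 1
  }
  i <- iMin
  while (i < length(y)) {
    if (y[i + 1] >= -tol) {
      post <- if (y[i + 1] <= 0) tt[i + 1] else
        tt[i] + (0 - y[i]) / (y[i + 1] - y[i]) * (tt[i + 1] - tt[i])
      break
    }
    i <- i + 1
  }
  c(pre = pre, post = post)
}

# Zero band for crossing searches: 0.1% of the feature amplitude guards
# against numerical residue, and half a baseline SD treats samples that
# are statistically indistinguishable from baseline as baseline -- so a
# slow noise excursion abutting the dip cannot drag the crossing away.
.crossingTol <- function(amp, bsd = 0) {
  max(1e-12, 1e-3 * abs(amp), 0.5 * bsd)
}

# Trapezoidal integral of the piecewise-linear path through (tt, y)
# between t0 and t1, with interpolated endpoints.
.trapzSegment <- function(tt, y, t0, t1) {
  if (t1 <= t0) return(0)
  yAt <- function(t) stats::approx(tt, y, xout = t, rule = 2)$y
  inner <- which(tt > t0 & tt < t1)
  xs <- c(t0, tt[inner], t1)
  ys <- c(yAt(t0), y[inner], yAt(t1))
  sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
}

#' Local-baseline standard deviation of a trial row
#'
#' Sample SD of the `[-baselineS, 0)` segment of a baseline-subtracted
#' trial row; this is the noise scale against which dip and peak
#' amplitudes are thresholded.
#'
#' @param row numeric dF/F row (baseline-subtracted).
#' @param relTime relative time grid of the row.
#' @param config an [AnalysisConfig-class].
#' @return Numeric scalar.
#' @export
baselineSd <- function(row, relTime, config = analysisConfig()) {
  sel <- relTime >= -config@baselineS & relTime < 0
  if (!any(sel)) stop("empty baseline segment")
  stats::sd(row[sel])
}

#' Detect and quantify the ACh dip in one trial
#'
#' Amplitude is the minimum of the row over `(0, aucWindowS]`; the trial
#' qualifies when that minimum is at least `dipSdK` baseline SDs below
#' zero. Duration runs from the last zero down-crossing preceding the
#' minimum to the first zero up-crossing following it, with crossings
#' located by linear interpolation between adjacent samples. When the
#' signal has not returned to zero by the end of the AUC window the
#' duration is censored at the window end.
#'
#' @param row numeric baseline-subtracted dF/F row.
#' @param relTime relative time grid.
#' @param config an [AnalysisConfig-class].
#' @return List: `amplitude_pct`, `duration_s`, `t_min_s`,
#'   `crossing_pre_s`, `crossing_post_s`, `qualified`, `censored`,
#'   `baseline_sd`.
#' @export
detectDip <- function(row, relTime, config = analysisConfig()) {
  bsd <- baselineSd(row, relTime, config)
  W <- config@aucWindowS
  sel <- which(relTime > 0 & relTime <= W)
  amp <- min(row[sel])
  iMin <- sel[which.min(row[sel])]
  tMin <- relTime[iMin]
  out <- list(amplitude_pct = amp, duration_s = 0, t_min_s = tMin,
              crossing_pre_s = NA_real_, crossing_post_s = NA_real_,
              qualified = FALSE, censored = FALSE, baseline_sd = bsd)
  if (amp >= -1e-9) return(out)  # numerically silent row
  out$qualified <- amp <= -config@dipSdK * bsd
  cr <- .zeroCrossings(relTime, row, iMin,
                       tol = .crossingTol(amp, bsd))
  pre <- if (is.na(cr["pre"])) relTime[1] else unname(cr["pre"])
  if (is.na(cr["post"]) || cr["post"] > W) {
    out$censored <- TRUE
    post <- W
  } else post <- unname(cr["post"])
  out$crossing_pre_s <- pre
  out$crossing_post_s <- post
  out$duration_s <- min(post - pre, W)
  out
}

#' AUC decomposition of one ACh trial
#'
#' Trapezoidal integration over the AUC window: `total_auc` is the signed
#' integral over `[0, aucWindowS]` (all response components); `neg_auc`
#' the integral between the dip's two zero crossings (non-positive);
#' `rebound_auc` the integral of the positive segment from the dip's end
#' crossing to the next down-crossing or the window end (non-negative,
#' zero when the dip is censored). An initial positive peak before the
#' dip contributes to the total only.
#'
#' @param row numeric baseline-subtracted dF/F row.
#' @param relTime relative time grid.
#' @param dip result of [detectDip()] on the same row.
#' @param config an [AnalysisConfig-class].
#' @return List: `total_auc`, `neg_auc`, `rebound_auc` (percent-seconds).
#' @export
aucComponents <- function(row, relTime, dip, config = analysisConfig()) {
  W <- config@aucWindowS
  total <- .trapzSegment(relTime, row, 0, W)
  neg <- 0; reb <- 0
  if (dip$duration_s > 0) {
    neg <- .trapzSegment(relTime, row, max(dip$crossing_pre_s, 0),
                         min(dip$crossing_post_s, W))
    if (!dip$censored) {
      # positive lobe immediately after the dip, up to the next
      # down-crossing or the window end
      i0 <- which(relTime > dip$crossing_post_s & relTime <= W)
      endT <- W
      below <- i0[row[i0] < -.crossingTol(dip$amplitude_pct,
                                          dip$baseline_sd)]
      if (length(below)) {
        iNeg <- below[1]
        j <- iNeg - 1L
        endT <- if (row[j] == 0) relTime[j] else
          relTime[j] + (0 - row[j]) / (row[iNeg] - row[j]) *
            (relTime[iNeg] - relTime[j])
      }
      reb <- .trapzSegment(relTime, row, dip$crossing_post_s, endT)
    }
  }
  list(total_auc = total, neg_auc = min(neg, 0), rebound_auc = max(reb, 0))
}

#' Detect and quantify the DA peak in one trial
#'
#' Mirror image of [detectDip()]: amplitude is the maximum over
#' `(0, aucWindowS]`, qualifying at `peakSdK` baseline SDs above zero;
#' `auc` is the signed integral over the window.
#'
#' @inheritParams detectDip
#' @return List: `amplitude_pct`, `auc`, `t_max_s`, `qualified`,
#'   `baseline_sd`.
#' @export
detectPeak <- function(row, relTime, config = analysisConfig()) {
  bsd <- baselineSd(row, relTime, config)
  W <- config@aucWindowS
  sel <- which(relTime > 0 & relTime <= W)
  amp <- max(row[sel])
  tMax <- relTime[sel[which.max(row[sel])]]
  list(amplitude_pct = amp,
       auc = .trapzSegment(relTime, row, 0, W),
       t_max_s = tMax,
       qualified = amp > 0 && amp >= config@peakSdK * bsd,
       baseline_sd = bsd)
}

#' Optogenetic inhibition onset latency
#'
#' For a trial row aligned to light onset: the first time after 0 at which
#' the signal falls below `-dipSdK x baseline SD` and stays below that
#' threshold for at least 50 ms.
#'
#' @inheritParams detectDip
#' @return Numeric latency in seconds, or `NA` if the signal never
#'   sustains a sub-threshold excursion.
#' @export
optoOnsetLatency <- function(row, relTime, config = analysisConfig()) {
  bsd <- baselineSd(row, relTime, config)
  # 0.001% dF/F floor keeps numerically silent baselines from triggering
  thr <- -max(config@dipSdK * bsd, 1e-3)
  dt <- stats::median(diff(relTime))
  need <- max(1L, ceiling(0.05 / dt))
  post <- which(relTime > 0)
  below <- row[post] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  relTime[post[starts[hit[1]]]]
}

#' Filter a metrics table by press latency
#'
#' Retains rows with press latency strictly greater than the configured
#' threshold (separating the cue-evoked response from movement-associated
#' activity). The number of removed rows is attached as attribute
#' `nFiltered`.
#'
#' @param metrics data.frame with a `latency_s` column.
#' @param config an [AnalysisConfig-class] (threshold
#'   `pressLatencyFilterS`).
#' @return Filtered data.frame.
#' @export
filterTrials <- function(metrics, config = analysisConfig()) {
  if (!nrow(metrics)) return(metrics)
  if (!"latency_s" %in% names(metrics))
    stop("metrics table has no latency_s column")
  keep <- metrics$latency_s > config@pressLatencyFilterS
  out <- metrics[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nFiltered") <- sum(!keep)
  out
}

#' Quantify every trial of an aligned session
#'
#' Applies [detectDip()] and [aucComponents()] to each ACh trial row and
#' [detectPeak()] to each DA row, returning one tidy row per trial merged
#' with the trial metadata.
#'
#' @param achTm [TrialMatrix-class] for the ACh sensor.
#' @param daTm optional [TrialMatrix-class] for the DA sensor (same
#'   trials).
#' @param config an [AnalysisConfig-class].
#' @return data.frame with columns `trial`, the trial metadata, dip
#'   metrics (`amplitude_pct`, `duration_s`, `neg_auc`, `rebound_auc`,
#'   `total_auc`, `qualified`, `censored`) and, when `daTm` is supplied,
#'   DA metrics (`da_amplitude_pct`, `da_auc`, `da_qualified`).
#' @export
quantifyTrials <- function(achTm, daTm = NULL, config = analysisConfig()) {
  vals <- trialValues(achTm)
  rt <- relTime(achTm)
  n <- nrow(vals)
  rows <- lapply(seq_len(n), function(i) {
    dip <- detectDip(vals[i, ], rt, config)
    auc <- aucComponents(vals[i, ], rt, dip, config)
    data.frame(trial = i, amplitude_pct = dip$amplitude_pct,
               duration_s = dip$duration_s, t_min_s = dip$t_min_s,
               neg_auc = auc$neg_auc, rebound_auc = auc$rebound_auc,
               total_auc = auc$total_auc, qualified = dip$qualified,
               censored = dip$censored)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trial = integer(0), amplitude_pct = numeric(0),
                      duration_s = numeric(0), t_min_s = numeric(0),
                      neg_auc = numeric(0), rebound_auc = numeric(0),
                      total_auc = numeric(0), qualified = logical(0),
                      censored = logical(0))
  if (!is.null(daTm)) {
    dv <- trialValues(daTm)
    if (nrow(dv) != n) stop("ACh and DA trial matrices differ in rows")
    drt <- relTime(daTm)
    da <- lapply(seq_len(n), function(i) detectPeak(dv[i, ], drt, config))
    out$da_amplitude_pct <- vapply(da, `[[`, numeric(1), "amplitude_pct")
    out$da_auc <- vapply(da, `[[`, numeric(1), "auc")
    out$da_qualified <- vapply(da, `[[`, logical(1), "qualified")
  }
  info <- trialInfo(achTm)
  if (nrow(info) == n && ncol(info)) out <- cbind(info, out)
  rownames(out) <- NULL
  out
}
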