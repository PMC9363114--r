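# Raw dual-wavelength traces -> baseline-subtracted, event-aligned dF/F.

#' Downsample a trace by a block (moving-window) mean
#'
#' True decimation: element `i` of the output is the mean of input samples
#' `(i-1)*factor + 1 ... i*factor`; a trailing partial block is dropped.
#' The time base of a recording must be decimated with the same call so the
#' two stay aligned.
#'
#' @param x numeric vector.
#' @param factor positive integer block size.
#' @return Numeric vector of length `floor(length(x)/factor)`.
#' @examples
#' downsampleTrace(1:20, 10)  # 5.5, 15.5
#' @export
downsampleTrace <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (length(x) < factor) stop("factor exceeds trace length")
  if (factor == 1L) return(x)
  nOut <- length(x) %/% factor
  colMeans(matrix(x[seq_len(nOut * factor)], nrow = factor))
}

#' Least-squares isosbestic fit
#'
#' Fits `f465 ~ a * f405 + b` by ordinary least squares; the fitted values
#' are the activity-independent baseline F0, which carries the bleaching
#' and motion components shared by the two excitation wavelengths.
#'
#' @param f405 isosbestic (405 nm) trace.
#' @param f465 signal (465 nm) trace, same length.
#' @return List with `a` (slope), `b` (intercept) and `f0` (fitted vector).
#' @export
fitIsosbestic <- function(f405, f465) {
  if (length(f405) != length(f465)) stop("f405/f465 length mismatch")
  if (length(f405) < 2) stop("need at least 2 samples")
  if (stats::var(f405) == 0)
    stop("degenerate isosbestic fit: 405 nm trace is constant")
  a <- stats::cov(f405, f465) / stats::var(f405)
  b <- mean(f465) - a * mean(f405)
  list(a = a, b = b, f0 = a * f405 + b)
}

#' Compute dF/F in percent
#'
#' `(F - F0) / F0 x 100`, elementwise; F is the 465 nm signal and F0 the
#' isosbestic-fitted baseline.
#'
#' @param f465 signal trace.
#' @param f0 fitted baseline, same length, strictly positive.
#' @return Numeric dF/F vector in percent.
#' @export
computeDff <- function(f465, f0) {
  if (length(f465) != length(f0)) stop("f465/f0 length mismatch")
  if (any(f0 <= 0))
    stop("non-positive F0 at ", sum(f0 <= 0),
         " sample(s); isosbestic fit is unusable here")
  (f465 - f0) / f0 * 100
}

#' Process one sensor of a session to a dF/F trace
#'
#' Downsamples the 465 and 405 channels and the time base by the configured
#' factor (block mean), fits the isosbestic regression over the full
#' recording, and converts to dF/F percent.
#'
#' @param session a [PhotometrySession-class].
#' @param sensor `"ACh"` or `"DA"`.
#' @param config an [AnalysisConfig-class].
#' @return List with `time_s`, `dff_pct`, `sensor`, and fit diagnostics
#'   `a`, `b`.
#' @export
processSession <- function(session, sensor, config = analysisConfig()) {
  sensor <- match.arg(sensor, KNOWN_SENSORS)
  f <- config@downsampleFactor
  t465 <- downsampleTrace(channel(session, sensor, "465"), f)
  t405 <- downsampleTrace(channel(session, sensor, "405"), f)
  tds <- downsampleTrace(sessionTime(session), f)
  fit <- fitIsosbestic(t405, t465)
  list(time_s = tds, dff_pct = computeDff(t465, fit$f0),
       sensor = sensor, a = fit$a, b = fit$b)
}

#' Align a dF/F trace into an event-locked trial matrix
#'
#' Extracts a window `[-windowPreS, +windowPostS]` around each event
#' (nearest-sample alignment; time 0 is the aligned sample), drops events
#' whose window is not fully inside the recording, and subtracts each
#' row's local baseline (mean over `[-baselineS, 0)`).
#'
#' @param dff list as returned by [processSession()] (needs `time_s`,
#'   `dff_pct`, `sensor`).
#' @param eventTimes numeric event times in seconds.
#' @param config an [AnalysisConfig-class].
#' @param trialInfo optional data.frame with one row per event (subset
#'   along with retained trials).
#' @return A [TrialMatrix-class]; zero usable events gives an empty matrix
#'   (0 rows), not an error.
#' @export
alignTrials <- function(dff, eventTimes, config = analysisConfig(),
                        trialInfo = NULL) {
  tt <- dff$time_s
  dt <- stats::median(diff(tt))
  nPre <- round(config@windowPreS / dt)
  nPost <- round(config@windowPostS / dt)
  relTime <- seq(-nPre, nPost) * dt
  if (!is.null(trialInfo) && nrow(trialInfo) != length(eventTimes))
    stop("trialInfo must have one row per event")

  centers <- vapply(eventTimes,
                    function(e) which.min(abs(tt - e)), integer(1))
  ok <- centers - nPre >= 1 & centers + nPost <= length(tt)
  nDropped <- sum(!ok)
  keep <- which(ok)
  vals <- matrix(numeric(0), nrow = 0, ncol = length(relTime))
  if (length(keep)) {
    vals <- t(vapply(centers[keep], function(c0)
      dff$dff_pct[(c0 - nPre):(c0 + nPost)], numeric(length(relTime))))
    base <- relTime >= -config@baselineS & relTime < 0
    vals <- vals - rowMeans(vals[, base, drop = FALSE])
  }
  info <- if (is.null(trialInfo))
    data.frame(event_time_s = eventTimes[keep])
  else {
    ti <- trialInfo[keep, , drop = FALSE]
    if (!"event_time_s" %in% names(ti)) ti$event_time_s <- eventTimes[keep]
    rownames(ti) <- NULL
    ti
  }
  new("TrialMatrix", relTime = relTime, values = vals, trialInfo = info,
      sensor = dff$sensor, nDropped = as.integer(nDropped))
}
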