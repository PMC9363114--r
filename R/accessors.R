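# Accessors and show methods for the core classes.

#' @describeIn PhotometrySession-class sample times in seconds.
#' @param object,x a `PhotometrySession`.
#' @export
setGeneric("sessionTime", function(x) standardGeneric("sessionTime"))

#' @export
setMethod("sessionTime", "PhotometrySession", function(x) x@time)

#' Extract one raw channel trace
#'
#' @param x a [PhotometrySession-class].
#' @param sensor `"ACh"` or `"DA"`.
#' @param wavelength `"465"` or `"405"`.
#' @return Numeric vector of raw fluorescence.
#' @export
setGeneric("channel",
           function(x, sensor, wavelength) standardGeneric("channel"))

#' @export
setMethod("channel", "PhotometrySession", function(x, sensor, wavelength) {
  sensor <- match.arg(sensor, KNOWN_SENSORS)
  wavelength <- match.arg(as.character(wavelength), KNOWN_WAVELENGTHS)
  x@channels[[paste(sensor, wavelength, sep = "_")]]
})

#' Event stream of a session
#'
#' @param x a [PhotometrySession-class].
#' @param label optional label filter; returns the event times only.
#' @return data.frame `(label, time_s)`, or numeric times if `label` given.
#' @export
setGeneric("sessionEvents",
           function(x, label = NULL) standardGeneric("sessionEvents"))

#' @export
setMethod("sessionEvents", "PhotometrySession", function(x, label = NULL) {
  if (is.null(label)) return(x@events)
  x@events$time_s[x@events$label == label]
})

#' Session metadata list
#' @param x a [PhotometrySession-class].
#' @export
setGeneric("sessionMeta", function(x) standardGeneric("sessionMeta"))

#' @export
setMethod("sessionMeta", "PhotometrySession", function(x) x@meta)

setMethod("show", "PhotometrySession", function(object) {
  n <- length(object@time)
  dt <- if (n > 1) stats::median(diff(object@time)) else NA_real_
  cat("PhotometrySession:", n, "samples @", round(1 / dt, 1), "Hz,",
      sprintf("%.1f s\n", object@time[n] - object@time[1]))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat("  events:", nrow(object@events), "(",
      paste(unique(object@events$label), collapse = ", "), ")\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta,
        as.character)), sep = "=", collapse = ", "), "\n")
})

#' Relative time grid of a trial matrix
#' @param x a [TrialMatrix-class].
#' @export
setGeneric("relTime", function(x) standardGeneric("relTime"))

#' @export
setMethod("relTime", "TrialMatrix", function(x) x@relTime)

#' Trial-by-time value matrix
#' @param x a [TrialMatrix-class].
#' @export
setGeneric("trialValues", function(x) standardGeneric("trialValues"))

#' @export
setMethod("trialValues", "TrialMatrix", function(x) x@values)

#' Per-trial metadata of a trial matrix
#' @param x a [TrialMatrix-class].
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @export
setMethod("trialInfo", "TrialMatrix", function(x) x@trialInfo)

#' Number of trials dropped for truncated windows
#' @param x a [TrialMatrix-class].
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))

#' @export
setMethod("nDropped", "TrialMatrix", function(x) x@nDropped)

setMethod("show", "TrialMatrix", function(object) {
  cat("TrialMatrix (", object@sensor, "): ", nrow(object@values),
      " trials x ", ncol(object@values), " samples, rel time [",
      sprintf("%.2f", min(object@relTime)), ", ",
      sprintf("%.2f", max(object@relTime)), "] s, ", object@nDropped,
      " dropped\n", sep = "")
})

#' Lag grid of a lag-correlation result
#' @param x a [LagCorrResult-class].
#' @export
setGeneric("lagGrid", function(x) standardGeneric("lagGrid"))

#' @export
setMethod("lagGrid", "LagCorrResult", function(x) x@lags)

#' Mean correlation-vs-lag curve
#' @param x a [LagCorrResult-class].
#' @export
setGeneric("meanR", function(x) standardGeneric("meanR"))

#' @export
setMethod("meanR", "LagCorrResult", function(x) x@meanR)

#' Negative / positive correlation extremum
#'
#' Lists with elements `r`, `lag_s` and `var_pct`; NA until
#' [findExtrema()] has been applied.
#' @param x a [LagCorrResult-class].
#' @export
setGeneric("negPeak", function(x) standardGeneric("negPeak"))

#' @export
setMethod("negPeak", "LagCorrResult", function(x) x@negPeak)

#' @rdname negPeak
#' @export
setGeneric("posPeak", function(x) standardGeneric("posPeak"))

#' @export
setMethod("posPeak", "LagCorrResult", function(x) x@posPeak)

setMethod("show", "LagCorrResult", function(object) {
  cat("LagCorrResult (", object@segment, "): ", object@nTrials,
      " trials, lags [", sprintf("%.2f", min(object@lags)), ", ",
      sprintf("%.2f", max(object@lags)), "] s\n", sep = "")
  if (!is.na(object@negPeak$r))
    cat(sprintf("  negative peak: r = %.3f at lag %.3f s (%.1f%% var)\n",
                object@negPeak$r, object@negPeak$lag_s,
                object@negPeak$var_pct))
  if (!is.na(object@posPeak$r))
    cat(sprintf("  positive peak: r = %.3f at lag %.3f s (%.2f%% var)\n",
                object@posPeak$r, object@posPeak$lag_s,
                object@posPeak$var_pct))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTrials, "trials @", object@samplingRateHz,
      "Hz, dose", object@dose, ", genotype", object@genotype,
      ", seed", object@seed, "\n")
  cat(sprintf("  DA peak %.1f%%, ACh dip %.1f%% x %.2f s, rebound %.1f%%\n",
              object@daPeakAmpPct, object@achDipAmpPct,
              object@achDipDurationS, object@achReboundAmpPct))
  cat(sprintf("  lags: dip %.2f s, rebound %.2f s; noise %.2f%%\n",
              object@daAchLagS, object@reboundLagS, object@noiseSdPct))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(paste0("AnalysisConfig: downsample x%d, window [-%g, +%g] s, ",
                     "baseline %g s, AUC %g s, thresholds %gx/%gx SD\n"),
              object@downsampleFactor, object@windowPreS, object@windowPostS,
              object@baselineS, object@aucWindowS, object@dipSdK,
              object@peakSdK))
})

#' AUC window length of an analysis configuration
#' @param x an [AnalysisConfig-class].
#' @export
setGeneric("aucWindow", function(x) standardGeneric("aucWindow"))

#' @export
setMethod("aucWindow", "AnalysisConfig", function(x) x@aucWindowS)
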