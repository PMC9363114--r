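#' @import methods
#' @importFrom stats lm cor cor.test sd qf pf rnorm runif rpois pnorm
#' @importFrom utils head tail
NULL

KNOWN_EVENT_LABELS <- c("lever_extension", "lever_press", "head_entry",
                        "cs_on", "cs_off", "reward", "light_on", "light_off")
KNOWN_SENSORS <- c("ACh", "DA")
KNOWN_WAVELENGTHS <- c("465", "405")
CHANNEL_KEYS <- c("ACh_465", "ACh_405", "DA_465", "DA_405")

#' Analysis configuration
#'
#' Holds every tunable of the preprocessing and quantification chain:
#' the downsampling factor applied to the raw traces, the peri-event window
#' (asymmetric, `windowPreS` before to `windowPostS` after the aligning
#' event, 15 s total by default), the local-baseline span, the AUC window,
#' the SD multipliers qualifying a dip or peak, the lag-scan half-width, the
#' press-latency trial filter and the upper lag bound used when searching
#' for the positive (rebound) correlation extremum.
#'
#' @slot downsampleFactor integer, block size of the moving-window-mean
#'   decimation (default 10).
#' @slot windowPreS,windowPostS numeric seconds before/after the event
#'   (defaults 5 and 10).
#' @slot baselineS numeric, local baseline is the mean over
#'   `[-baselineS, 0)` (default 5).
#' @slot aucWindowS numeric, dip/peak search and AUC integration window
#'   `(0, aucWindowS]` (default 5).
#' @slot dipSdK,peakSdK numeric, a dip (peak) qualifies when its amplitude
#'   is at least this many baseline SDs below (above) baseline (default 2).
#' @slot lagMaxS numeric, lag scan covers `[-lagMaxS, +lagMaxS]` (default 3).
#' @slot pressLatencyFilterS numeric, `filterTrials` keeps trials with press
#'   latency strictly greater than this (default 2).
#' @slot posPeakLagBoundS numeric, the positive extremum is searched at lags
#'   at or below this bound (default -0.5) to avoid the shoulder of the
#'   negative trough.
#' @export
setClass("AnalysisConfig",
  representation(
    downsampleFactor = "integer",
    windowPreS = "numeric",
    windowPostS = "numeric",
    baselineS = "numeric",
    aucWindowS = "numeric",
    dipSdK = "numeric",
    peakSdK = "numeric",
    lagMaxS = "numeric",
    pressLatencyFilterS = "numeric",
    posPeakLagBoundS = "numeric"
  ),
  prototype(
    downsampleFactor = 10L,
    windowPreS = 5,
    windowPostS = 10,
    baselineS = 5,
    aucWindowS = 5,
    dipSdK = 2,
    peakSdK = 2,
    lagMaxS = 3,
    pressLatencyFilterS = 2,
    posPeakLagBoundS = -0.5
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@downsampleFactor < 1L)
      msg <- c(msg, "downsampleFactor must be >= 1")
    for (s in c("windowPreS", "windowPostS", "baselineS", "aucWindowS",
                "dipSdK", "peakSdK", "lagMaxS"))
      if (slot(object, s) <= 0)
        msg <- c(msg, paste(s, "must be positive"))
    if (object@baselineS > object@windowPreS)
      msg <- c(msg, "baselineS must not exceed windowPreS")
    if (object@aucWindowS > object@windowPostS)
      msg <- c(msg, "aucWindowS must not exceed windowPostS")
    if (object@posPeakLagBoundS >= 0)
      msg <- c(msg, "posPeakLagBoundS must be negative")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AnalysisConfig
#'
#' @param downsampleFactor block size of the decimating moving-window mean.
#' @param windowPreS,windowPostS peri-event window extent in seconds.
#' @param baselineS local-baseline span in seconds.
#' @param aucWindowS AUC / feature-search window in seconds.
#' @param dipSdK,peakSdK SD-threshold multipliers for dip/peak qualification.
#' @param lagMaxS half-width of the lag scan in seconds.
#' @param pressLatencyFilterS press-latency trial filter threshold (strict >).
#' @param posPeakLagBoundS upper lag bound for the positive extremum search.
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig()
#' aucWindow(cfg)
#' @export
analysisConfig <- function(downsampleFactor = 10L, windowPreS = 5,
                           windowPostS = 10, baselineS = 5, aucWindowS = 5,
                           dipSdK = 2, peakSdK = 2, lagMaxS = 3,
                           pressLatencyFilterS = 2, posPeakLagBoundS = -0.5) {
  new("AnalysisConfig",
      downsampleFactor = as.integer(downsampleFactor),
      windowPreS = windowPreS, windowPostS = windowPostS,
      baselineS = baselineS, aucWindowS = aucWindowS,
      dipSdK = dipSdK, peakSdK = peakSdK, lagMaxS = lagMaxS,
      pressLatencyFilterS = pressLatencyFilterS,
      posPeakLagBoundS = posPeakLagBoundS)
}

#' One dual-sensor photometry session
#'
#' Container for a single recording session: a common time base, the four
#' raw fluorescence traces (two sensors x two excitation wavelengths), the
#' behavioral event stream and session metadata. Validity enforces equal
#' trace lengths, a strictly increasing near-uniform time base (maximum
#' jitter < 10% of the median sampling interval) and event times inside the
#' recorded span.
#'
#' @slot time numeric vector of sample times in seconds.
#' @slot channels named list of four numeric traces, keys
#'   `ACh_465`, `ACh_405`, `DA_465`, `DA_405`, raw fluorescence units.
#' @slot events data.frame with columns `label`, `time_s`.
#' @slot meta list with `subject`, `date`, `dose`, `genotype`, `task`.
#' @export
setClass("PhotometrySession",
  representation(
    time = "numeric",
    channels = "list",
    events = "data.frame",
    meta = "list"
  ),
  validity = function(object) {
    msg <- character(0)
    miss <- setdiff(CHANNEL_KEYS, names(object@channels))
    if (length(miss))
      msg <- c(msg, paste0("missing channel(s): ",
                           paste(miss, collapse = ", ")))
    n <- length(object@time)
    if (n < 2) msg <- c(msg, "time base must have at least 2 samples")
    for (k in intersect(CHANNEL_KEYS, names(object@channels))) {
      if (length(object@channels[[k]]) != n)
        msg <- c(msg, paste0("channel ", k, " length (",
                             length(object@channels[[k]]),
                             ") != time length (", n, ")"))
    }
    dt <- diff(object@time)
    if (n >= 2 && any(dt <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (n >= 3) {
      med <- stats::median(dt)
      if (max(abs(dt - med)) > 0.1 * med)
        msg <- c(msg, "time base jitter exceeds 10% of the median interval")
    }
    if (nrow(object@events)) {
      if (!all(c("label", "time_s") %in% names(object@events)))
        msg <- c(msg, "events must have columns label, time_s")
      else {
        bad <- object@events$time_s < object@time[1] |
               object@events$time_s > object@time[n]
        if (any(bad))
          msg <- c(msg, paste0("event(s) outside recorded span: ",
                               paste(utils::head(which(bad), 5),
                                     collapse = ", ")))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PhotometrySession
#'
#' @param time numeric sample times (seconds).
#' @param channels named list of the four raw traces (`ACh_465`, `ACh_405`,
#'   `DA_465`, `DA_405`).
#' @param events data.frame with columns `label` and `time_s`.
#' @param meta list of session metadata (subject, date, dose, genotype, task).
#' @return A [PhotometrySession-class].
#' @export
photometrySession <- function(time, channels,
                              events = data.frame(label = character(0),
                                                  time_s = numeric(0)),
                              meta = list()) {
  events$label <- as.character(events$label)
  new("PhotometrySession", time = as.numeric(time),
      channels = lapply(channels, as.numeric),
      events = events, meta = meta)
}

#' Event-aligned trial matrix
#'
#' Baseline-subtracted dF/F traces aligned to one event type for one
#' sensor; rows are trials, columns are time points on the shared relative
#' time grid. Each row has had the mean of its `[-baselineS, 0)` segment
#' subtracted. Trials whose window fell outside the recording were dropped
#' (counted in `nDropped`).
#'
#' @slot relTime numeric vector of times relative to the aligning event.
#' @slot values numeric matrix, trials x time, dF/F in percent.
#' @slot trialInfo data.frame with one row per retained trial (at least
#'   `event_time_s`; typically also `latency_s`, `dose`, `genotype`).
#' @slot sensor character, `"ACh"` or `"DA"`.
#' @slot nDropped integer count of trials dropped at the recording edges.
#' @export
setClass("TrialMatrix",
  representation(
    relTime = "numeric",
    values = "matrix",
    trialInfo = "data.frame",
    sensor = "character",
    nDropped = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@values) > 0 &&
        ncol(object@values) != length(object@relTime))
      msg <- c(msg, "values column count must match relTime length")
    if (nrow(object@values) != nrow(object@trialInfo))
      msg <- c(msg, "trialInfo rows must match values rows")
    if (length(object@relTime) &&
        !any(abs(object@relTime) < 1e-9))
      msg <- c(msg, "relTime must contain 0 (nearest-sample alignment)")
    if (length(msg)) msg else TRUE
  }
)

#' Lagged cross-correlation result
#'
#' Mean Pearson correlation between the DA and ACh dF/F signals as a
#' function of the lag applied to the ACh series. Negative lag means the
#' ACh series is shifted so that its features occur after DA's ("ACh lags
#' DA"). Extrema are filled by [findExtrema()].
#'
#' @slot lags numeric lag grid in seconds.
#' @slot meanR numeric, trial-mean Pearson r at each lag.
#' @slot negPeak,posPeak lists with `r`, `lag_s`, `var_pct` (NA until
#'   [findExtrema()] is applied).
#' @slot nTrials integer, number of trials (or ITI segments) averaged.
#' @slot segment character, `"trial"` or `"iti"`.
#' @export
setClass("LagCorrResult",
  representation(
    lags = "numeric",
    meanR = "numeric",
    negPeak = "list",
    posPeak = "list",
    nTrials = "integer",
    segment = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@lags) != length(object@meanR))
      msg <- c(msg, "lags and meanR must have equal length")
    finite <- object@meanR[is.finite(object@meanR)]
    if (length(finite) && any(abs(finite) > 1 + 1e-12))
      msg <- c(msg, "mean correlations must lie in [-1, 1]")
    if (!object@segment %in% c("trial", "iti"))
      msg <- c(msg, "segment must be 'trial' or 'iti'")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic-session configuration
#'
#' All parameters of the synthetic dual-sensor generator. Event-locked
#' response shapes are compact-support half-sine lobes, so the configured
#' dip duration is exactly the zero-crossing duration of the noise-free
#' kernel and configured lags are exactly the cross-correlation extremum
#' lags (see the methods vignette for the rationale).
#'
#' @slot samplingRateHz raw sampling rate (default 1000).
#' @slot nTrials number of lever-extension trials.
#' @slot itiMeanS mean intertrial interval, drawn from an exponential
#'   truncated to `[itiMeanS/2, 2*itiMeanS]` (default 40 s).
#' @slot daPeakAmpPct dopamine transient amplitude, dF/F percent.
#' @slot daPeakWidthS dopamine transient lobe width in seconds.
#' @slot achInitialPeakAmpPct initial ACh peak amplitude (0 disables it).
#' @slot achDipAmpPct ACh dip amplitude, negative percent.
#' @slot achDipDurationS ACh dip zero-crossing duration in seconds.
#' @slot achReboundAmpPct ACh rebound amplitude, non-negative percent.
#' @slot achReboundWidthS ACh rebound lobe width in seconds; the rebound
#'   lobe starts where the dip ends, and the default width (1.64 s) puts
#'   its peak at `|reboundLagS|` after the DA peak under the default dip
#'   geometry.
#' @slot daAchLagS lag of the dip minimum relative to the DA peak
#'   (negative; default -0.18: the dip trails the peak by 180 ms).
#' @slot reboundLagS nominal lag of the rebound peak relative to the DA
#'   peak (negative; default -1.5); realized exactly at the default dip
#'   duration, earlier when a dose shortens the dip.
#' @slot doseEffect named list: dose label -> numeric triple
#'   `(dip_duration_multiplier, rebound_multiplier, da_amp_multiplier)`.
#' @slot dose active dose label (must be a key of `doseEffect`).
#' @slot genotype `"control"` or `"ko"`; `"ko"` halves the DA-coupled ACh
#'   dip and rebound components.
#' @slot latencyBaseS,latencyCouplingSlope,latencySdS press-latency model:
#'   mean latency = base + slope x trial total AUC, Gaussian jitter,
#'   floored at 0.1 s.
#' @slot motionAmpPct shared motion-artifact amplitude (fractional gain
#'   bumps applied identically to the 405 and 465 channels).
#' @slot motionRateHz Poisson rate of motion bumps.
#' @slot bleachTauS photobleaching time constant (single decaying
#'   exponential multiplying both channels).
#' @slot noiseSdPct independent Gaussian noise SD per channel, percent of
#'   the channel baseline.
#' @slot itiEventRateHz Poisson rate of small spontaneous coupled DA-ACh
#'   events during the ITI.
#' @slot itiAmpScale amplitude of spontaneous ITI events relative to the
#'   cue-evoked ones.
#' @slot trialGainSd SD of the per-trial log-normal response gain.
#' @slot sensorBlocked logical; TRUE zeroes every event-locked component
#'   (pharmacological sensor blockade mode).
#' @slot optoMode `"off"`, `"short"` or `"long"`: optogenetic inhibition at
#'   lever extension, 0.5 s square pulse then a linear ramp back over 1 s
#'   (short) or 3 s (long), with a rebound overshoot after the long ramp.
#' @slot optoOnsetDelayS delay from light onset to the inhibition onset.
#' @slot seed integer RNG seed; same seed + config gives identical output.
#' @export
setClass("SimConfig",
  representation(
    samplingRateHz = "numeric",
    nTrials = "integer",
    itiMeanS = "numeric",
    daPeakAmpPct = "numeric",
    daPeakWidthS = "numeric",
    achInitialPeakAmpPct = "numeric",
    achDipAmpPct = "numeric",
    achDipDurationS = "numeric",
    achReboundAmpPct = "numeric",
    achReboundWidthS = "numeric",
    daAchLagS = "numeric",
    reboundLagS = "numeric",
    doseEffect = "list",
    dose = "character",
    genotype = "character",
    latencyBaseS = "numeric",
    latencyCouplingSlope = "numeric",
    latencySdS = "numeric",
    motionAmpPct = "numeric",
    motionRateHz = "numeric",
    bleachTauS = "numeric",
    noiseSdPct = "numeric",
    itiEventRateHz = "numeric",
    itiAmpScale = "numeric",
    trialGainSd = "numeric",
    sensorBlocked = "logical",
    optoMode = "character",
    optoOnsetDelayS = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@samplingRateHz <= 0)
      msg <- c(msg, "samplingRateHz must be positive")
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    if (object@itiMeanS <= 0) msg <- c(msg, "itiMeanS must be positive")
    if (object@daPeakAmpPct <= 0) msg <- c(msg, "daPeakAmpPct must be > 0")
    if (object@achInitialPeakAmpPct < 0)
      msg <- c(msg, "achInitialPeakAmpPct must be >= 0")
    if (object@achDipAmpPct >= 0)
      msg <- c(msg, "achDipAmpPct must be negative")
    if (object@achDipDurationS <= 0)
      msg <- c(msg, "achDipDurationS must be positive")
    if (object@achReboundAmpPct < 0)
      msg <- c(msg, "achReboundAmpPct must be >= 0")
    if (object@daAchLagS >= 0) msg <- c(msg, "daAchLagS must be negative")
    if (object@reboundLagS >= 0) msg <- c(msg, "reboundLagS must be negative")
    if (!object@genotype %in% c("control", "ko"))
      msg <- c(msg, "genotype must be 'control' or 'ko'")
    if (!object@optoMode %in% c("off", "short", "long"))
      msg <- c(msg, "optoMode must be 'off', 'short' or 'long'")
    if (!object@dose %in% names(object@doseEffect))
      msg <- c(msg, paste0("dose '", object@dose,
                           "' absent from doseEffect map"))
    for (d in names(object@doseEffect)) {
      e <- object@doseEffect[[d]]
      if (length(e) != 3 || !is.numeric(e))
        msg <- c(msg, paste0("doseEffect[['", d,
                             "']] must be a numeric triple"))
      else if (e[1] <= 0 || e[1] > 1 || e[2] < 1 || e[3] < 1)
        msg <- c(msg, paste0("doseEffect[['", d, "']] multipliers out of ",
                             "range (dip_dur in (0,1], rebound >= 1, ",
                             "da_amp >= 1)"))
    }
    if (object@latencyCouplingSlope <= 0)
      msg <- c(msg, "latencyCouplingSlope must be positive")
    if (object@motionAmpPct < 0) msg <- c(msg, "motionAmpPct must be >= 0")
    if (object@bleachTauS <= 0) msg <- c(msg, "bleachTauS must be positive")
    if (object@noiseSdPct < 0) msg <- c(msg, "noiseSdPct must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Default dose-effect map
#'
#' Multiplier triples `(dip_duration, rebound_amplitude, da_amplitude)` for
#' a saline + five-dose D2R-antagonist series: dip duration shortens
#' monotonically, the rebound is enhanced monotonically, and the DA peak is
#' modestly increased (autoreceptor blockade), saturating at low doses.
#'
#' @return Named list of numeric triples in increasing dose order.
#' @export
defaultDoseEffect <- function() {
  list(
    saline  = c(1.00, 1.0, 1.00),
    d0.1    = c(0.90, 1.4, 1.30),
    d0.25   = c(0.75, 1.8, 1.40),
    d1.0    = c(0.60, 2.2, 1.45),
    d2.5    = c(0.50, 2.8, 1.50),
    d5.0    = c(0.40, 3.5, 1.50)
  )
}

#' Construct a SimConfig
#'
#' All arguments default to the generator's reference conditions; see
#' [SimConfig-class] for their meaning.
#'
#' @param samplingRateHz,nTrials,itiMeanS session structure.
#' @param daPeakAmpPct,daPeakWidthS dopamine transient.
#' @param achInitialPeakAmpPct,achDipAmpPct,achDipDurationS,achReboundAmpPct,achReboundWidthS
#'   ACh multiphasic response.
#' @param daAchLagS,reboundLagS component lags relative to the DA peak.
#' @param doseEffect,dose dose-effect map and active dose label.
#' @param genotype `"control"` or `"ko"`.
#' @param latencyBaseS,latencyCouplingSlope,latencySdS press-latency model.
#' @param motionAmpPct,motionRateHz,bleachTauS,noiseSdPct artifact model.
#' @param itiEventRateHz,itiAmpScale spontaneous ITI events.
#' @param trialGainSd per-trial response-gain variability.
#' @param sensorBlocked,optoMode,optoOnsetDelayS special modes.
#' @param seed RNG seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTrials = 5, seed = 1)
#' @export
simConfig <- function(samplingRateHz = 1000, nTrials = 60L, itiMeanS = 40,
                      daPeakAmpPct = 4, daPeakWidthS = 0.6,
                      achInitialPeakAmpPct = 0, achDipAmpPct = -3,
                      achDipDurationS = 1.0, achReboundAmpPct = 1,
                      achReboundWidthS = 1.64, daAchLagS = -0.18,
                      reboundLagS = -1.5, doseEffect = defaultDoseEffect(),
                      dose = "saline", genotype = "control",
                      latencyBaseS = 3.0, latencyCouplingSlope = 1.0,
                      latencySdS = 0.4, motionAmpPct = 1,
                      motionRateHz = 0.02, bleachTauS = 3000,
                      noiseSdPct = 0.3, itiEventRateHz = 0.08,
                      itiAmpScale = 0.5, trialGainSd = 0.2,
                      sensorBlocked = FALSE, optoMode = "off",
                      optoOnsetDelayS = 0.2, seed = 1L) {
  new("SimConfig",
      samplingRateHz = samplingRateHz, nTrials = as.integer(nTrials),
      itiMeanS = itiMeanS, daPeakAmpPct = daPeakAmpPct,
      daPeakWidthS = daPeakWidthS,
      achInitialPeakAmpPct = achInitialPeakAmpPct,
      achDipAmpPct = achDipAmpPct, achDipDurationS = achDipDurationS,
      achReboundAmpPct = achReboundAmpPct,
      achReboundWidthS = achReboundWidthS, daAchLagS = daAchLagS,
      reboundLagS = reboundLagS, doseEffect = doseEffect, dose = dose,
      genotype = genotype, latencyBaseS = latencyBaseS,
      latencyCouplingSlope = latencyCouplingSlope, latencySdS = latencySdS,
      motionAmpPct = motionAmpPct, motionRateHz = motionRateHz,
      bleachTauS = bleachTauS, noiseSdPct = noiseSdPct,
      itiEventRateHz = itiEventRateHz, itiAmpScale = itiAmpScale,
      trialGainSd = trialGainSd, sensorBlocked = sensorBlocked,
      optoMode = optoMode, optoOnsetDelayS = optoOnsetDelayS,
      seed = as.integer(seed))
}
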