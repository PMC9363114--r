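# Synthetic dual-sensor session generator.
#
# Event-locked components are half-sine lobes: compact support gives exact
# ground-truth zero crossings (the configured dip duration IS the
# zero-crossing duration) and their symmetry puts the lag-correlation
# extremum exactly at the configured peak-to-peak lag. Channel model:
#   F_465 = B465 * bleach(t) * (1 + motion(t)) * (1 + dff(t)/100) + noise
#   F_405 = B405 * bleach(t) * (1 + motion(t))                    + noise
# so the isosbestic regression of 465 on 405 removes bleaching and motion
# exactly in the noise-free limit.

CHANNEL_BASELINES <- c(ACh_465 = 100, ACh_405 = 70, DA_465 = 110,
                       DA_405 = 75)

# Add amp * halfsine lobe centred at `center` with total width `width`
# to signal `sig` sampled at times `tt`; returns modified signal.
.addLobe <- function(sig, tt, center, width, amp) {
  if (amp == 0 || width <= 0) return(sig)
  a <- center - width / 2
  i1 <- findInterval(a, tt) + 1L
  i2 <- findInterval(a + width, tt)
  if (i2 < i1) return(sig)
  i1 <- max(i1, 1L); i2 <- min(i2, length(tt))
  sig[i1:i2] <- sig[i1:i2] + amp * sin(pi * (tt[i1:i2] - a) / width)
  sig
}

# Band-limited Gaussian noise emulating the acquisition low-pass (~3 Hz):
# iid Gaussian knots at twice the cutoff, linearly interpolated onto the
# sample grid, scaled so the average variance matches sd^2.
.smoothNoise <- function(tt, sd, cutoffHz = 3) {
  if (sd == 0) return(numeric(length(tt)))
  knotDt <- 1 / (2 * cutoffHz)
  knots <- seq(tt[1] - knotDt, tt[length(tt)] + knotDt, by = knotDt)
  kv <- rnorm(length(knots), 0, sd / sqrt(2 / 3))
  stats::approx(knots, kv, xout = tt)$y
}

# The full event-locked ACh kernel (initial peak + dip + rebound, or the
# optogenetic inhibition shape) evaluated on a grid of times relative to
# the aligning event. Shared between signal synthesis and ground truth.
.achEventKernel <- function(config, trel, g, durM, rebM, koScale) {
  y <- numeric(length(trel))
  daPeakT <- 0.02 + config@daPeakWidthS / 2
  if (config@optoMode == "off") {
    if (config@achInitialPeakAmpPct > 0)
      y <- .addLobe(y, trel, 0.12, 0.24, config@achInitialPeakAmpPct * g)
    dipDur <- config@achDipDurationS * durM
    dipEndT <- daPeakT + abs(config@daAchLagS) + dipDur / 2
    y <- .addLobe(y, trel, daPeakT + abs(config@daAchLagS), dipDur,
                  config@achDipAmpPct * koScale * g)
    # rebound begins where the dip ends (the rebound follows the pause);
    # at default geometry its peak trails the DA peak by |reboundLagS|
    y <- .addLobe(y, trel, dipEndT + config@achReboundWidthS / 2,
                  config@achReboundWidthS,
                  config@achReboundAmpPct * rebM * koScale * g)
  } else {
    # optogenetic inhibition replaces the natural cue-evoked ACh
    # response: 0.5 s square pulse then linear ramp back
    rampS <- if (config@optoMode == "short") 1 else 3
    on <- config@optoOnsetDelayS
    amp <- -abs(config@achDipAmpPct) * g
    sq <- trel >= on & trel < on + 0.5
    y[sq] <- y[sq] + amp
    rp <- trel >= on + 0.5 & trel < on + 0.5 + rampS
    y[rp] <- y[rp] + amp * (1 - (trel[rp] - on - 0.5) / rampS)
    if (config@optoMode == "long")
      y <- .addLobe(y, trel, on + 0.5 + rampS + 0.6, 1.2,
                    1.5 * config@achReboundAmpPct * koScale * g)
  }
  y
}

# Truncated-exponential ITI draw: rate 1/mean, support [mean/2, 2*mean].
.drawIti <- function(n, meanS) {
  a <- meanS / 2; b <- 2 * meanS
  u <- runif(n)
  ea <- exp(-a / meanS); eb <- exp(-b / meanS)
  -meanS * log(ea - u * (ea - eb))
}

# Zero-crossing dip duration of a noise-free kernel segment (dense grid).
# Shared with detectDip's interpolation convention.
.kernelDipDuration <- function(tt, sig, windowS) {
  sel <- tt > 0 & tt <= windowS
  if (!any(sel) || min(sig[sel]) >= -1e-9) return(0)
  amp <- min(sig[sel])
  iMin <- which(sel)[which.min(sig[sel])]
  cr <- .zeroCrossings(tt, sig, iMin, tol = .crossingTol(amp))
  endT <- if (is.na(cr["post"])) windowS else unname(cr["post"])
  startT <- if (is.na(cr["pre"])) tt[1] else unname(cr["pre"])
  endT - startT
}

#' Generate one synthetic dual-sensor session
#'
#' Builds a full session of raw 465/405 nm traces for both sensors: shared
#' photobleaching and motion artifacts, independent Gaussian noise, and
#' event-locked kernels on the 465 channels only (DA transient at lever
#' extension; ACh optional initial peak, dip trailing the DA peak by
#' `|daAchLagS|`, rebound trailing by `|reboundLagS|`). Spontaneous
#' small coupled DA-ACh events occur during the intertrial interval. Press
#' latency is drawn with mean `latencyBaseS + latencyCouplingSlope x`
#' (trial total ACh AUC), floored at 0.1 s. The same seed and
#' configuration always produce identical output.
#'
#' @param config a [SimConfig-class].
#' @return List with elements `session` (a [PhotometrySession-class]) and
#'   `truth` (data.frame: `trial`, `event_time_s`, `true_dip_amp`,
#'   `true_dip_dur`, `true_da_amp`, `true_lag_s`, `latency_s`,
#'   `true_total_auc`).
#' @examples
#' out <- generateSession(simConfig(nTrials = 3, itiMeanS = 20,
#'                                  samplingRateHz = 250, seed = 42))
#' out$session
#' out$truth
#' @export
generateSession <- function(config) {
  validObject(config)
  set.seed(config@seed)
  fs <- config@samplingRateHz
  dt <- 1 / fs
  mult <- config@doseEffect[[config@dose]]
  durM <- mult[1]; rebM <- mult[2]; daM <- mult[3]
  koScale <- if (config@genotype == "ko") 0.5 else 1
  n <- config@nTrials

  # --- trial timing ------------------------------------------------------
  itis <- if (n > 1) .drawIti(n - 1, config@itiMeanS) else numeric(0)
  evTimes <- 8 + c(0, cumsum(itis))
  totalT <- evTimes[n] + 12
  tt <- seq(0, totalT, by = dt)
  N <- length(tt)

  # --- per-trial response gains -----------------------------------------
  gACh <- exp(rnorm(n, 0, config@trialGainSd))
  gDA <- exp(rnorm(n, 0, config@trialGainSd))

  daPeakOffset <- 0.02 + config@daPeakWidthS / 2  # DA peak time after event
  dipDur <- config@achDipDurationS * durM

  achSig <- numeric(N)
  daSig <- numeric(N)
  if (!config@sensorBlocked) {
    for (i in seq_len(n)) {
      ev <- evTimes[i]
      daSig <- .addLobe(daSig, tt, ev + daPeakOffset,
                        config@daPeakWidthS,
                        config@daPeakAmpPct * daM * gDA[i])
      rng <- which(tt >= ev - 1 & tt <= ev + 9)
      achSig[rng] <- achSig[rng] +
        .achEventKernel(config, tt[rng] - ev, gACh[i], durM, rebM,
                        koScale)
    }
  }

  # --- spontaneous coupled ITI events -----------------------------------
  if (!config@sensorBlocked && config@itiEventRateHz > 0) {
    nSp <- rpois(1, config@itiEventRateHz * totalT)
    spT <- sort(runif(nSp, 0, totalT))
    # keep events clear of the peri-trial windows
    keep <- vapply(spT, function(s)
      all(s < evTimes - 7 | s > evTimes + 12), logical(1))
    spT <- spT[keep]
    spG <- exp(rnorm(length(spT), 0, config@trialGainSd))
    for (j in seq_along(spT)) {
      pkT <- spT[j] + daPeakOffset
      daSig <- .addLobe(daSig, tt, pkT, config@daPeakWidthS,
                        config@daPeakAmpPct * daM * config@itiAmpScale *
                          spG[j])
      achSig <- .addLobe(achSig, tt, pkT + abs(config@daAchLagS), dipDur,
                         config@achDipAmpPct * koScale *
                           config@itiAmpScale * spG[j])
      achSig <- .addLobe(achSig, tt,
                         pkT + abs(config@daAchLagS) + dipDur / 2 +
                           config@achReboundWidthS / 2,
                         config@achReboundWidthS,
                         config@achReboundAmpPct * rebM * koScale *
                           config@itiAmpScale * spG[j])
    }
  }

  # --- ground truth (event-relative dense grid, timing-independent) -----
  trueTotalAuc <- numeric(n)
  trueDipAmp <- numeric(n)
  trueDipDur <- numeric(n)
  trel <- seq(-1, 5, by = 1e-3)
  inWin <- trel > 0 & trel <= 5
  for (i in seq_len(n)) {
    seg <- if (config@sensorBlocked) numeric(length(trel)) else
      .achEventKernel(config, trel, gACh[i], durM, rebM, koScale)
    w <- seg[inWin]
    trueTotalAuc[i] <- sum((w[-1] + w[-length(w)]) / 2) * 1e-3
    trueDipAmp[i] <- min(0, min(w))
    trueDipDur[i] <- .kernelDipDuration(trel, seg, 5)
  }
  latMean <- config@latencyBaseS +
    config@latencyCouplingSlope * trueTotalAuc
  lat <- pmax(0.1, rnorm(n, latMean, config@latencySdS))
  nextGap <- c(itis, 12) - 5
  lat <- pmin(lat, nextGap)

  events <- data.frame(label = "lever_extension", time_s = evTimes)
  events <- rbind(events,
                  data.frame(label = "lever_press",
                             time_s = evTimes + lat),
                  data.frame(label = "reward", time_s = evTimes + lat + 0.2),
                  data.frame(label = "head_entry",
                             time_s = evTimes + lat + 1.0))
  if (config@optoMode != "off") {
    rampS <- if (config@optoMode == "short") 1 else 3
    events <- rbind(events,
                    data.frame(label = "light_on", time_s = evTimes),
                    data.frame(label = "light_off",
                               time_s = evTimes + config@optoOnsetDelayS +
                                 0.5 + rampS))
  }
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  # --- raw channels ------------------------------------------------------
  bleach <- exp(-tt / config@bleachTauS)
  motion <- numeric(N)
  if (config@motionAmpPct > 0) {
    nB <- rpois(1, config@motionRateHz * totalT)
    if (nB > 0) {
      bc <- runif(nB, 0, totalT)
      ba <- runif(nB, -1, 1) * config@motionAmpPct / 100
      for (j in seq_len(nB)) {
        i1 <- max(1L, findInterval(bc[j] - 0.6, tt))
        i2 <- min(N, findInterval(bc[j] + 0.6, tt) + 1L)
        motion[i1:i2] <- motion[i1:i2] +
          ba[j] * exp(-(tt[i1:i2] - bc[j])^2 / (2 * 0.15^2))
      }
    }
  }
  shared <- bleach * (1 + motion)
  mkChan <- function(base, dff = NULL) {
    sig <- if (is.null(dff)) base * shared else
      base * shared * (1 + dff / 100)
    if (config@noiseSdPct > 0)
      sig <- sig + .smoothNoise(tt, config@noiseSdPct / 100 * base)
    sig
  }
  channels <- list(
    ACh_465 = mkChan(CHANNEL_BASELINES["ACh_465"], achSig),
    ACh_405 = mkChan(CHANNEL_BASELINES["ACh_405"]),
    DA_465 = mkChan(CHANNEL_BASELINES["DA_465"], daSig),
    DA_405 = mkChan(CHANNEL_BASELINES["DA_405"])
  )

  session <- photometrySession(
    time = tt, channels = channels, events = events,
    meta = list(subject = paste0("sim", config@seed),
                date = "synthetic", dose = config@dose,
                genotype = config@genotype,
                task = if (config@optoMode == "off") "crf" else "crf",
                opto_mode = config@optoMode,
                sampling_rate_hz = fs, seed = config@seed))
  truth <- data.frame(
    trial = seq_len(n),
    event_time_s = evTimes,
    true_dip_amp = trueDipAmp,
    true_dip_dur = trueDipDur,
    true_da_amp = if (config@sensorBlocked) rep(0, n) else
      config@daPeakAmpPct * daM * gDA,
    true_lag_s = rep(config@daAchLagS, n),
    latency_s = lat,
    true_total_auc = trueTotalAuc
  )
  list(session = session, truth = truth)
}

#' Generate a dose series of synthetic sessions
#'
#' One session per dose label, in the given order; dose labels must all be
#' present in the configuration's `doseEffect` map. Session `i` uses seed
#' `base@seed + (i - 1)`, so a single-dose series at the base dose is
#' identical to `generateSession(base)`.
#'
#' @param base a [SimConfig-class] used as the template.
#' @param doses character vector of dose labels.
#' @return List (one element per dose) of `list(session, truth)`.
#' @export
generateDoseSeries <- function(base, doses) {
  unknown <- setdiff(doses, names(base@doseEffect))
  if (length(unknown))
    stop("unknown dose label(s): ", paste(unknown, collapse = ", "))
  lapply(seq_along(doses), function(i) {
    cfg <- base
    cfg@dose <- doses[i]
    cfg@seed <- base@seed + (i - 1L)
    generateSession(cfg)
  })
}
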