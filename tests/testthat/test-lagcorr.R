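mkRows <- function(nTrials, nSamp, gen) {
  t(vapply(seq_len(nTrials), function(i) gen(i), numeric(nSamp)))
}

test_that("identical signals correlate perfectly at zero lag", {
  set.seed(51)
  da <- mkRows(5, 400, function(i) rnorm(400))
  res <- findExtrema(lagScan(da, da, analysisConfig(lagMaxS = 1),
                             dt = 0.01))
  expect_equal(max(meanR(res)), 1)
  expect_equal(lagGrid(res)[which.max(meanR(res))], 0)
})

test_that("a constructed delay is recovered with sign convention intact", {
  # ACh = -(DA delayed by 0.2 s): most negative correlation at -0.2 s
  dt <- 0.01
  n <- 600
  kernel <- sin(pi * seq(0, 1, by = dt) / 1)
  base <- numeric(n)
  base[100 + seq_along(kernel)] <- kernel
  shift <- round(0.2 / dt)
  ach <- -c(numeric(shift), base[1:(n - shift)])
  da <- matrix(base, 1)[rep(1, 4), ]
  am <- matrix(ach, 1)[rep(1, 4), ]
  res <- findExtrema(lagScan(da, am, analysisConfig(), dt = dt))
  expect_equal(negPeak(res)$r, -1, tolerance = 1e-9)
  expect_equal(negPeak(res)$lag_s, -0.2)
})

test_that("independent white noise stays inside the null bound", {
  set.seed(52)
  nT <- 50; nS <- 1000
  da <- mkRows(nT, nS, function(i) rnorm(nS))
  ach <- mkRows(nT, nS, function(i) rnorm(nS))
  res <- lagScan(da, ach, analysisConfig(lagMaxS = 1), dt = 0.01)
  expect_lt(max(abs(meanR(res))), 3 / sqrt(nT * nS) * 1.5)
})

test_that("shift equivariance holds exactly for noise-free rows", {
  dt <- 0.02
  n <- 500
  kernel <- sin(pi * seq(0, 1, by = dt))
  mk <- function(off) {
    y <- numeric(n); y[off + seq_along(kernel)] <- kernel; y
  }
  da <- matrix(mk(100), 1)[rep(1, 3), ]
  for (k in c(5, 17)) {
    ach0 <- matrix(-mk(120), 1)[rep(1, 3), ]
    achK <- matrix(-mk(120 + k), 1)[rep(1, 3), ]
    r0 <- findExtrema(lagScan(da, ach0, analysisConfig(), dt = dt))
    rk <- findExtrema(lagScan(da, achK, analysisConfig(), dt = dt))
    expect_equal(negPeak(rk)$lag_s, negPeak(r0)$lag_s - k * dt,
                 tolerance = 1e-9)
  }
})

test_that("extremum ties break toward the smaller absolute lag", {
  lags <- seq(-1, 1, by = 0.1)
  mkRes <- function(mr) new("LagCorrResult", lags = lags, meanR = mr,
                            negPeak = list(r = NA_real_, lag_s = NA_real_,
                                           var_pct = NA_real_),
                            posPeak = list(r = NA_real_, lag_s = NA_real_,
                                           var_pct = NA_real_),
                            nTrials = 1L, segment = "trial")
  flat <- findExtrema(mkRes(rep(0, length(lags))))
  expect_equal(negPeak(flat)$r, 0)
  expect_equal(negPeak(flat)$lag_s, 0)
  expect_equal(posPeak(flat)$lag_s, -0.5)  # smallest |lag| within bound
  mr <- rep(0, length(lags))
  mr[which.min(abs(lags + 0.8))] <- -0.6
  mr[which.min(abs(lags + 0.2))] <- -0.6
  two <- findExtrema(mkRes(mr))
  expect_equal(negPeak(two)$lag_s, -0.2)
})

test_that("variance explained is r squared in percent with domain checks", {
  expect_equal(varianceExplained(0), 0)
  expect_equal(varianceExplained(1), 100)
  expect_equal(varianceExplained(-0.3), 9)
  expect_error(varianceExplained(1.2), "exceed")
})

test_that("Fisher z matches an arctanh oracle and compares correlations", {
  expect_equal(fisherZ(0), 0)
  # series oracle: arctanh(r) = sum r^(2k+1)/(2k+1)
  r <- 0.5
  k <- 0:200
  expect_equal(fisherZ(r), sum(r^(2 * k + 1) / (2 * k + 1)))
  expect_warning(z1 <- fisherZ(1), "infinite")
  expect_true(is.infinite(z1))
  cmp <- compareCorrelations(0.4, 30, 0.4, 50)
  expect_equal(cmp$z_stat, 0)
  expect_equal(cmp$p, 1)
  expect_error(compareCorrelations(0.4, 3, 0.4, 50), "n >= 4")
})

test_that("ITI segments exclude every trial window exactly", {
  out <- generateSession(smallSimConfig(nTrials = 4, itiMeanS = 30,
                                        seed = 55))
  cfg <- analysisConfig()
  seg <- itiSegments(out$session, cfg)
  expect_gt(seg$nSegments, 0)
  expect_equal(ncol(seg$da), round(10 / seg$dt))
  # reconstruct segment times and check the set difference property
  dffA <- processSession(out$session, "ACh", cfg)
  ev <- sessionEvents(out$session, "lever_extension")
  # no segment sample may fall inside any [-5, +10] window
  tt <- dffA$time_s
  inTrial <- rep(FALSE, length(tt))
  for (e in ev) inTrial <- inTrial | (tt >= e - 5 & tt <= e + 10)
  free <- which(!inTrial)
  # total ITI samples bound the chunked sample count from above
  expect_lte(seg$nSegments * ncol(seg$da), length(free))
})

test_that("back-to-back trials leave no ITI segments", {
  tt <- seq(0, 50, by = 0.02)
  ch <- lapply(list(ACh_465 = 100, ACh_405 = 70, DA_465 = 110,
                    DA_405 = 75),
               function(b) b + 0.01 * sin(tt))
  ev <- data.frame(label = "lever_extension", time_s = c(10, 25, 40))
  sess <- photometrySession(tt, ch, ev)
  seg <- itiSegments(sess, analysisConfig(downsampleFactor = 1L))
  expect_equal(seg$nSegments, 0L)
  expect_equal(nrow(seg$da), 0)
})

test_that("ITI coupling is present but weaker than the trial coupling", {
  out <- generateSession(simConfig(nTrials = 12, itiMeanS = 30,
                                   samplingRateHz = 500, seed = 56))
  cfg <- analysisConfig()
  p <- runSessionPipeline(out, cfg)
  trial <- findExtrema(lagScan(p$tmD, p$tmA, cfg), cfg)
  seg <- itiSegments(out$session, cfg)
  iti <- findExtrema(lagScan(seg$da, seg$ach, cfg, dt = seg$dt,
                             segment = "iti"), cfg)
  expect_lt(negPeak(iti)$r, 0)
  expect_lt(negPeak(trial)$r, negPeak(iti)$r)  # trial coupling stronger
  expect_lt(abs(negPeak(iti)$lag_s - (-0.18)), 0.15)
})
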