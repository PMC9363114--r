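# Rows below live on a relative time grid containing [-5, 10]; the
# baseline segment is zero unless stated.
mkRow <- function(dt = 0.1, knots = NULL) {
  rt <- seq(-5, 10, by = dt)
  y <- numeric(length(rt))
  if (!is.null(knots)) {
    sel <- rt >= min(knots$t) & rt <= max(knots$t)
    y[sel] <- approx(knots$t, knots$v, xout = rt[sel])$y
    y[abs(y) < 1e-12] <- 0  # snap float-grid residue at the knots
  }
  list(rt = rt, y = y)
}

test_that("baseline SD matches the direct formula", {
  r <- mkRow()
  r$y[r$rt < 0] <- rep(c(-1, 1), length.out = sum(r$rt < 0))
  expect_equal(baselineSd(r$y, r$rt),
               sd(r$y[r$rt >= -5 & r$rt < 0]))
  expect_equal(baselineSd(numeric(151), seq(-5, 10, by = 0.1)), 0)
})

test_that("a hand-computed piecewise-linear dip is quantified exactly", {
  r <- mkRow(knots = list(t = c(0.1, 0.7, 1.3), v = c(0, -1, 0)))
  dip <- detectDip(r$y, r$rt)
  expect_equal(dip$amplitude_pct, -1)
  expect_equal(dip$t_min_s, 0.7)
  expect_equal(dip$duration_s, 1.2)
  expect_false(dip$censored)
  # zero baseline SD: any dip qualifies
  expect_true(dip$qualified)
})

test_that("zero crossings are located by linear interpolation", {
  r <- mkRow(knots = list(t = c(0.0, 0.1, 0.5), v = c(0.5, -0.5, 0)))
  dip <- detectDip(r$y, r$rt)
  expect_equal(dip$crossing_pre_s, 0.05)
  expect_equal(dip$t_min_s, 0.1)
})

test_that("all-zero and unreturning rows behave per contract", {
  r0 <- mkRow()
  dip <- detectDip(r0$y, r0$rt)
  expect_false(dip$qualified)
  expect_equal(dip$duration_s, 0)
  # dip that never returns to zero inside the window: censored at 5 s
  rc <- mkRow(knots = list(t = c(0.5, 1.0, 10), v = c(0, -2, -2)))
  dipc <- detectDip(rc$y, rc$rt)
  expect_true(dipc$censored)
  expect_equal(dipc$duration_s, 5 - 0.5)
  auc <- aucComponents(rc$y, rc$rt, dipc)
  expect_equal(auc$rebound_auc, 0)  # censored: no rebound segment
})

test_that("triangle dip and rebound areas decompose exactly", {
  r <- mkRow(knots = list(t = c(0, 0.5, 1, 1.5, 2),
                          v = c(0, -1, 0, 0.5, 0)))
  dip <- detectDip(r$y, r$rt)
  auc <- aucComponents(r$y, r$rt, dip)
  expect_equal(auc$neg_auc, -0.5)
  expect_equal(auc$rebound_auc, 0.25)
  expect_equal(auc$total_auc, -0.25)
})

test_that("an initial positive peak contributes to the total AUC only", {
  r <- mkRow(knots = list(t = c(0, 0.3, 0.6, 1.1, 1.6),
                          v = c(0, 0.8, 0, -1, 0)))
  dip <- detectDip(r$y, r$rt)
  auc <- aucComponents(r$y, r$rt, dip)
  expect_equal(auc$neg_auc, -0.5)
  expect_equal(auc$rebound_auc, 0)
  expect_equal(auc$total_auc, 0.24 - 0.5)  # peak area enters total only
})

test_that("the DA peak mirror works and negative rows stay unqualified", {
  r <- mkRow(knots = list(t = c(0, 0.5, 1), v = c(0, 2, 0)))
  pk <- detectPeak(r$y, r$rt)
  expect_equal(pk$amplitude_pct, 2)
  expect_equal(pk$auc, 1.0)
  expect_true(pk$qualified)
  rn <- mkRow(knots = list(t = c(0, 0.5, 1), v = c(0, -2, 0)))
  pkn <- detectPeak(rn$y, rn$rt)
  expect_false(pkn$qualified)
  expect_lte(pkn$amplitude_pct, 0)
  expect_false(detectPeak(mkRow()$y, mkRow()$rt)$qualified)
})

test_that("scaling a row scales amplitudes and AUCs but not duration", {
  set.seed(44)
  r <- mkRow()
  r$y[r$rt > 0 & r$rt < 5] <-
    approx(c(0, 1, 2, 3, 5), c(0, -2, 1, -0.3, 0),
           xout = r$rt[r$rt > 0 & r$rt < 5])$y
  for (c in c(0.5, 2, 7)) {
    d1 <- detectDip(r$y, r$rt); a1 <- aucComponents(r$y, r$rt, d1)
    d2 <- detectDip(c * r$y, r$rt); a2 <- aucComponents(c * r$y, r$rt, d2)
    expect_equal(d2$amplitude_pct, c * d1$amplitude_pct)
    expect_equal(d2$duration_s, d1$duration_s)
    expect_equal(a2$neg_auc, c * a1$neg_auc)
    expect_equal(a2$rebound_auc, c * a1$rebound_auc)
    expect_equal(a2$total_auc, c * a1$total_auc)
  }
})

test_that("AUC decomposition is additive over signed segments", {
  set.seed(45)
  rt <- seq(-5, 10, by = 0.1)
  for (i in 1:25) {
    y <- randomPiecewiseRow(rt)
    dip <- detectDip(y, rt)
    auc <- aucComponents(y, rt, dip)
    expect_lte(auc$neg_auc, 1e-12)
    expect_gte(auc$rebound_auc, -1e-12)
    if (dip$duration_s > 0 && !dip$censored) {
      om <- oracleDipMetrics(rt, y, 5)
      expect_equal(auc$neg_auc + auc$rebound_auc,
                   om$neg + om$rebound, tolerance = 1e-4)
      expect_equal(auc$total_auc, om$total, tolerance = 1e-6)
    }
  }
})

test_that("opto onset latency finds sustained threshold crossings", {
  rt <- seq(-5, 10, by = 0.01)
  y <- numeric(length(rt))
  y[rt < 0] <- rep(c(-0.1, 0.1), length.out = sum(rt < 0))  # sd ~ 0.1
  y[rt >= 0.2] <- -3
  lat <- optoOnsetLatency(y, rt)
  expect_equal(lat, 0.2, tolerance = 0.011)
  expect_true(is.na(optoOnsetLatency(numeric(length(rt)), rt)))
  # a 20 ms blip does not count as sustained
  y2 <- numeric(length(rt))
  y2[rt < 0] <- rep(c(-0.1, 0.1), length.out = sum(rt < 0))
  y2[rt >= 0.2 & rt < 0.22] <- -3
  expect_true(is.na(optoOnsetLatency(y2, rt)))
})

test_that("the press-latency filter is strict and counts removals", {
  m <- data.frame(latency_s = c(1, 2, 3), total_auc = 1:3)
  f <- filterTrials(m)
  expect_equal(nrow(f), 1)
  expect_equal(f$latency_s, 3)
  expect_equal(attr(f, "nFiltered"), 2)
  expect_equal(nrow(filterTrials(m[0, , drop = FALSE])), 0)
  all3 <- data.frame(latency_s = c(2.5, 3, 4))
  expect_equal(nrow(filterTrials(all3)), 3)
})
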