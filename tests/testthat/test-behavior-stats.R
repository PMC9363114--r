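test_that("press latency is the extension-to-first-press interval", {
  ev <- data.frame(label = c("lever_extension", "lever_press",
                             "lever_extension", "head_entry"),
                   time_s = c(10, 12.5, 40, 41))
  pl <- pressLatency(ev)
  expect_equal(pl$latency_s[1], 2.5)
  expect_false(pl$completed[2])  # no press in trial 2
  expect_true(is.infinite(pl$latency_s[2]))
  bad <- data.frame(label = c("lever_press", "lever_extension"),
                    time_s = c(5, 10))
  expect_error(pressLatency(bad), "precedes")
})

test_that("anticipatory index contrasts late vs first quintile", {
  expect_equal(anticipatoryIndex(seq(0.5, 9.5, by = 1), 10), 0)  # uniform
  expect_equal(anticipatoryIndex(c(8.1, 8.5, 9.2, 9.9), 10), 4)
  expect_equal(anticipatoryIndex(numeric(0), 10), 0)
  # max over Q4 and Q5
  expect_equal(anticipatoryIndex(c(6.5, 6.9, 7.3, 9.1), 10), 3)
  expect_error(anticipatoryIndex(1, 0), "positive")
})

test_that("AUC-latency correlation handles exact and null pairings", {
  m <- data.frame(total_auc = c(0.2, 0.5, 1, 1.5, 2),
                  latency_s = 2 + c(0.2, 0.5, 1, 1.5, 2))
  r <- aucLatencyCorrelation(m, "total_auc")
  expect_equal(r$r, 1)
  expect_equal(r$n, 5)
  expect_error(aucLatencyCorrelation(m[1:3, ], "total_auc"), "at least 4")
  set.seed(61)
  hits <- sum(vapply(1:100, function(i) {
    mm <- data.frame(total_auc = rnorm(200), latency_s = rnorm(200))
    abs(aucLatencyCorrelation(mm, "total_auc")$r) < 0.2
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("RM ANOVA handles degenerate and two-level designs", {
  y <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)  # identical columns
  a <- rmAnovaOneway(y)
  expect_equal(a$F, 0)
  expect_equal(a$partial_eta_sq, 0)
  set.seed(62)
  y2 <- matrix(rnorm(12), nrow = 6, ncol = 2)
  expect_equal(rmAnovaOneway(y2)$epsilon_gg, 1)  # m = 2: sphericity holds
  expect_error(rmAnovaOneway(matrix(c(1, NA, 2, 3), 2)), "missing cells")
})

test_that("RM ANOVA sums of squares match the direct decomposition", {
  set.seed(63)
  y <- matrix(rnorm(30), nrow = 5, ncol = 6)
  a <- rmAnovaOneway(y)
  o <- oracleRmSS(y)
  expect_equal(a$ss_cond, o$ss_cond, tolerance = 1e-12)
  expect_equal(a$ss_subj, o$ss_subj, tolerance = 1e-12)
  expect_equal(a$ss_err, o$ss_err, tolerance = 1e-12)
  # cross-check F against base R aov
  df <- data.frame(v = as.vector(y),
                   subj = factor(rep(1:5, 6)),
                   cond = factor(rep(1:6, each = 5)))
  fit <- summary(aov(v ~ cond + Error(subj / cond), data = df))
  Ftab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(a$F, Ftab["cond", "F value"], tolerance = 1e-9)
  # internal consistency of the effect-size formula
  expect_equal(a$partial_eta_sq,
               partialEtaSq(a$F, a$df_effect, a$df_error))
})

test_that("effect-size helpers follow their closed forms", {
  expect_equal(partialEtaSq(0, 2, 10), 0)
  expect_equal(cohensF(0), 0)
  expect_equal(cohensF(0.5), 1)
  expect_warning(f1 <- cohensF(1), "infinite")
  expect_true(is.infinite(f1))
  expect_error(partialEtaSq(-1, 2, 10), ">= 0")
  expect_error(cohensF(1.2), "0, 1")
})

test_that("sample size floors at 2 and is monotone in f and power", {
  expect_equal(rmSampleSize(f = 100, m = 6, rho = 0, epsilon = 1), 2)
  fs <- c(0.3, 0.6, 1.2)
  ns <- vapply(fs, function(f)
    rmSampleSize(f = f, m = 4, rho = 0.2, epsilon = 0.7), numeric(1))
  expect_true(all(diff(ns) <= 0))  # larger effects need fewer subjects
  pws <- c(0.5, 0.8, 0.95)
  np <- vapply(pws, function(p)
    rmSampleSize(f = 0.4, power = p, m = 4, rho = 0.2, epsilon = 0.7),
    numeric(1))
  expect_true(all(diff(np) >= 0))
})

test_that("analytic power matches a Monte-Carlo noncentral-F oracle", {
  set.seed(64)
  f <- 0.8; m <- 4; rho <- 0.1; eps <- 0.8; alpha <- 0.05
  n <- rmSampleSize(f = f, alpha = alpha, power = 0.8, m = m, rho = rho,
                    epsilon = eps)
  lambda <- f^2 * n * m * eps / (1 - rho)
  df1 <- (m - 1) * eps; df2 <- (n - 1) * (m - 1) * eps
  draws <- rf(50000, df1, df2, ncp = lambda)
  mc <- mean(draws > qf(1 - alpha, df1, df2))
  expect_equal(rmAnovaPower(n, f, alpha, m, rho, eps), mc,
               tolerance = 0.01)
  # boundary property of the returned n
  expect_gte(rmAnovaPower(n, f, alpha, m, rho, eps), 0.8)
  expect_lt(rmAnovaPower(n - 1, f, alpha, m, rho, eps), 0.8)
})

test_that("dose-response table aggregates, trends and refuses degenerates", {
  m <- data.frame(subject = rep(c("a", "b"), each = 6),
                  dose = rep(rep(c("sal", "low", "high"), each = 2), 2),
                  duration_s = c(1, 1.1, 0.8, 0.9, 0.5, 0.6,
                                 1.2, 1.3, 0.9, 1.0, 0.6, 0.7))
  dr <- doseResponseTable(m, "duration_s",
                          doseOrder = c("sal", "low", "high"))
  expect_equal(dim(dr$table), c(2, 3))
  expect_lt(dr$spearman_rho, 0)
  expect_false(is.null(dr$anova))
  # identical values at every dose: flat trend by definition
  flat <- m; flat$duration_s <- 1
  expect_equal(doseResponseTable(flat, "duration_s")$spearman_rho, 0)
  # single subject: trend still reported, ANOVA refused
  one <- m[m$subject == "a", ]
  drOne <- doseResponseTable(one, "duration_s",
                             doseOrder = c("sal", "low", "high"))
  expect_true(is.null(drOne$anova))
  expect_lt(drOne$spearman_rho, 0)
  expect_error(doseResponseTable(m[m$dose == "sal", ], "duration_s"),
               "2 doses")
})
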