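# Behavioral metrics, dose aggregation, repeated-measures ANOVA and the
# effect-size / power chain.

#' Press latency of each trial
#'
#' For every lever extension, the time to the first lever press before the
#' next extension; trials with no press are marked incomplete with
#' infinite latency.
#'
#' @param events data.frame `(label, time_s)` containing
#'   `lever_extension` and `lever_press` events.
#' @return data.frame with `trial`, `extension_time_s`, `latency_s`,
#'   `completed`.
#' @export
pressLatency <- function(events) {
  ext <- sort(events$time_s[events$label == "lever_extension"])
  press <- sort(events$time_s[events$label == "lever_press"])
  if (!length(ext)) stop("no lever_extension events")
  if (length(press) && press[1] < ext[1])
    stop("lever_press precedes the first lever_extension ",
         "(corrupt event stream)")
  bounds <- c(ext, Inf)
  lat <- vapply(seq_along(ext), function(i) {
    p <- press[press >= ext[i] & press < bounds[i + 1]]
    if (length(p)) p[1] - ext[i] else Inf
  }, numeric(1))
  data.frame(trial = seq_along(ext), extension_time_s = ext,
             latency_s = lat, completed = is.finite(lat))
}

#' Anticipatory-responding index during the conditioned stimulus
#'
#' Splits the CS period into quintiles, counts head entries per quintile,
#' and returns the count in the better of the last two quintiles minus the
#' count in the first: positive values indicate reward-anticipatory
#' responding ramping up toward CS offset.
#'
#' @param headEntryTimes head-entry times in seconds relative to CS onset.
#' @param csDuration CS duration in seconds (> 0).
#' @param nQuintiles number of bins (default 5).
#' @return Integer index (max of the last two bins minus the first bin).
#' @export
anticipatoryIndex <- function(headEntryTimes, csDuration, nQuintiles = 5) {
  if (csDuration <= 0) stop("csDuration must be positive")
  inCs <- headEntryTimes[headEntryTimes >= 0 & headEntryTimes < csDuration]
  if (!length(inCs)) return(0L)
  bin <- pmin(floor(inCs / (csDuration / nQuintiles)) + 1L, nQuintiles)
  counts <- tabulate(bin, nbins = nQuintiles)
  as.integer(max(counts[nQuintiles - 1L], counts[nQuintiles]) - counts[1L])
}

#' Correlation between ACh AUC and press latency
#'
#' Pearson correlation over pooled trials (typically pre-filtered to press
#' latencies above the movement-separation threshold) between an AUC field
#' and press latency.
#'
#' @param metrics data.frame with `latency_s` and the AUC field.
#' @param field `"total_auc"` or `"neg_auc"`.
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
aucLatencyCorrelation <- function(metrics, field = c("total_auc",
                                                     "neg_auc")) {
  field <- match.arg(field)
  x <- metrics[[field]]
  y <- metrics$latency_s
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4) stop("need at least 4 complete trials")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subjects decomposition of a complete subjects x
#' conditions matrix: condition, subject and residual sums of squares; the
#' Greenhouse-Geisser non-sphericity epsilon from the double-centered
#' sample covariance of the condition columns; degrees of freedom
#' multiplied by epsilon for the p-value; partial eta-squared as
#' `F * df_effect / (F * df_effect + df_error)` (invariant to the epsilon
#' scaling of both dfs); and the mean off-diagonal correlation among the
#' repeated measures (the rho of the power calculation).
#'
#' @param y numeric matrix, subjects in rows, conditions in columns,
#'   complete cases only.
#' @return List: `F`, `df_effect`, `df_error` (epsilon-corrected), `p`,
#'   `partial_eta_sq`, `epsilon_gg`, `mean_r_repeated`, plus uncorrected
#'   `df_effect_raw`, `df_error_raw` and the sums of squares `ss_cond`,
#'   `ss_subj`, `ss_err`.
#' @export
rmAnovaOneway <- function(y) {
  y <- as.matrix(y)
  if (any(!is.finite(y)))
    stop("missing cells; fit a mixed-effects model instead ",
         "(incomplete repeated measures are out of scope here)")
  n <- nrow(y); m <- ncol(y)
  if (m < 2) stop("need at least 2 conditions")
  if (n < 2) stop("need at least 2 subjects")
  grand <- mean(y)
  colM <- colMeans(y); rowM <- rowMeans(y)
  ssCond <- n * sum((colM - grand)^2)
  ssSubj <- m * sum((rowM - grand)^2)
  ssTot <- sum((y - grand)^2)
  ssErr <- max(ssTot - ssCond - ssSubj, 0)
  df1 <- m - 1
  df2 <- (m - 1) * (n - 1)
  Fval <- if (ssCond == 0) 0 else (ssCond / df1) / (ssErr / df2)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(y)
  dc <- S - outer(rowMeans(S), rep(1, m)) -
    outer(rep(1, m), colMeans(S)) + mean(S)
  eps <- if (sum(dc^2) == 0) 1 else
    sum(diag(dc))^2 / ((m - 1) * sum(dc^2))
  eps <- min(eps, 1)
  p <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  C <- suppressWarnings(stats::cor(y))  # NA for zero-variance columns
  meanR <- mean(C[lower.tri(C)], na.rm = TRUE)
  if (!is.finite(meanR)) meanR <- NA_real_
  list(F = Fval, df_effect = df1 * eps, df_error = df2 * eps, p = p,
       partial_eta_sq = partialEtaSq(Fval, df1 * eps, df2 * eps),
       epsilon_gg = eps, mean_r_repeated = meanR,
       df_effect_raw = df1, df_error_raw = df2,
       ss_cond = ssCond, ss_subj = ssSubj, ss_err = ssErr)
}

#' Partial eta-squared from an F statistic
#'
#' `F * df_effect / (F * df_effect + df_error)`.
#'
#' @param F F statistic (>= 0).
#' @param dfEffect,dfError degrees of freedom (> 0).
#' @return Partial eta-squared in `[0, 1)`.
#' @export
partialEtaSq <- function(F, dfEffect, dfError) {
  if (F < 0 || dfEffect <= 0 || dfError <= 0)
    stop("F must be >= 0 and dfs positive")
  F * dfEffect / (F * dfEffect + dfError)
}

#' Cohen's f from partial eta-squared
#'
#' `f = sqrt(eta2 / (1 - eta2))`; eta2 = 1 gives infinite f with a
#' warning.
#'
#' @param eta2 partial eta-squared in `[0, 1]`.
#' @return Cohen's f.
#' @examples
#' cohensF(0.681)  # 1.46
#' cohensF(0.5)    # exactly 1
#' @export
cohensF <- function(eta2) {
  if (eta2 < 0 || eta2 > 1) stop("eta2 must lie in [0, 1]")
  if (eta2 == 1) {
    warning("eta2 = 1 gives an infinite effect size")
    return(Inf)
  }
  sqrt(eta2 / (1 - eta2))
}

#' Power of the repeated-measures within-factors F test
#'
#' Noncentral-F power with noncentrality
#' `lambda = f^2 * n * m * epsilon / (1 - rho)`, numerator df
#' `(m - 1) * epsilon` and denominator df `(n - 1) * (m - 1) * epsilon`.
#'
#' @param n number of subjects.
#' @param f Cohen's f.
#' @param alpha type-I error rate.
#' @param m number of repeated measures.
#' @param rho mean correlation among repeated measures.
#' @param epsilon non-sphericity correction in `(1/(m-1), 1]`.
#' @return Power in `[0, 1]`.
#' @export
rmAnovaPower <- function(n, f, alpha = 0.05, m, rho = 0, epsilon = 1) {
  if (!is.finite(rho) || rho >= 1)
    stop("rho must be finite and < 1")
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  fCrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fCrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size for the repeated-measures within-factors design
#'
#' Smallest `n >= 2` whose [rmAnovaPower()] reaches the target.
#'
#' @param f Cohen's f (> 0).
#' @param alpha type-I error rate in (0, 1).
#' @param power target power in (0, 1).
#' @param m number of repeated measures (>= 2).
#' @param rho mean correlation among repeated measures.
#' @param epsilon non-sphericity correction.
#' @param nMax search ceiling (error if the target is unreachable).
#' @return Integer sample size.
#' @examples
#' rmSampleSize(f = 1.46, alpha = 0.05, power = 0.8, m = 6,
#'              rho = -0.068, epsilon = 0.3193)  # 5
#' @export
rmSampleSize <- function(f, alpha = 0.05, power = 0.8, m, rho = 0,
                         epsilon = 1, nMax = 1e6) {
  if (f <= 0) stop("f must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  if (m < 2) stop("need at least 2 repeated measures")
  n <- 2L
  while (n <= nMax) {
    if (rmAnovaPower(n, f, alpha, m, rho, epsilon) >= power)
      return(n)
    n <- n + 1L
  }
  stop("target power unreachable below n = ", nMax)
}

#' Subject x dose summary and dose-trend statistics
#'
#' Averages a per-trial metric to the subject x dose level (complete-case
#' subjects only; incomplete subjects are dropped and counted), reports
#' the Spearman trend of the subject means against dose rank, and -- when
#' at least two complete subjects exist -- the one-way repeated-measures
#' ANOVA over doses.
#'
#' @param metrics data.frame with columns `subject`, `dose` and the
#'   metric.
#' @param metric metric column name (e.g. `"duration_s"`).
#' @param doseOrder character vector giving the dose ordering; defaults to
#'   the order of appearance.
#' @return List: `table` (subjects x doses matrix of means),
#'   `spearman_rho`, `spearman_p`, `anova` (NULL for a single subject),
#'   `n_dropped_subjects`.
#' @export
doseResponseTable <- function(metrics, metric, doseOrder = NULL) {
  if (is.null(doseOrder)) doseOrder <- unique(as.character(metrics$dose))
  if (length(doseOrder) < 2) stop("need at least 2 doses")
  agg <- stats::aggregate(metrics[[metric]],
                          by = list(subject = metrics$subject,
                                    dose = as.character(metrics$dose)),
                          FUN = mean)
  names(agg)[3] <- "value"
  subjects <- unique(agg$subject)
  tab <- matrix(NA_real_, nrow = length(subjects),
                ncol = length(doseOrder),
                dimnames = list(as.character(subjects), doseOrder))
  for (i in seq_len(nrow(agg)))
    tab[as.character(agg$subject[i]), agg$dose[i]] <- agg$value[i]
  complete <- stats::complete.cases(tab)
  nDropped <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]
  if (!nrow(tab)) stop("no subject has every dose")
  rank <- rep(seq_along(doseOrder), each = nrow(tab))
  vals <- as.vector(tab)
  if (stats::sd(vals) == 0) {
    rho <- 0; rhoP <- 1  # flat response: no trend by definition
  } else {
    st <- suppressWarnings(
      stats::cor.test(rank, vals, method = "spearman"))
    rho <- unname(st$estimate); rhoP <- st$p.value
  }
  anova <- if (nrow(tab) >= 2) rmAnovaOneway(tab) else NULL
  list(table = tab, spearman_rho = rho,
       spearman_p = rhoP, anova = anova,
       n_dropped_subjects = nDropped)
}
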