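---
title: "Methods: dual-sensor photometry quantification and its synthetic testbed"
author: "photoduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-sensor photometry quantification and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoduet)
```

# The measurement model

Each session records two sensors — striatal acetylcholine (ACh) and
dopamine (DA) — with two excitation wavelengths per sensor. The 465 nm
channel reports ligand binding; the 405 nm channel excites the sensor
near its isosbestic point and is therefore activity-independent, carrying
only the artifacts the two channels share: slow photobleaching and
movement of the fiber relative to the tissue. The preprocessing chain is

1. block-mean downsampling by a factor of 10 (a true decimation: sample
   $i$ of the output is the mean of input samples
   $(i-1)f+1,\dots,if$; the time base is decimated with the same
   operator, so each output sample sits at its block center);
2. an ordinary least-squares fit $F_{465} \approx a F_{405} + b$ over
   the full recording, whose fitted values are the baseline $F_0$;
3. $\Delta F/F\,(\%) = (F_{465} - F_0)/F_0 \times 100$.

The fit is computed per session, not per trial: a 5 s baseline segment
would leave the regression underdetermined, and a single fit matches how
the correction is applied in practice. Downsampling precedes the fit and
the division, mirroring the acquisition-order convention.

Trials are extracted as a 15 s window around the aligning event
(lever extension for operant sessions; light onset for optogenetic
trials). The window is split $[-5, +10]$ s: the 5 s pre-event segment
supplies the local baseline (its mean is subtracted from the whole row,
and its SD is the noise scale for qualification thresholds), while 10 s
post-event leaves room for the 5 s quantification window plus the
rebound tail. Event-to-sample alignment takes the nearest sample, which
becomes relative time 0.

# Dip and peak quantification

Within the 5 s post-event window, the ACh dip amplitude is the row
minimum and qualifies when it lies at least `dipSdK` baseline SDs below
zero. The threshold multiplier defaults to 2 for both dips and peaks —
the conservative end of the 1–2 SD convention in this literature — and
is a configuration knob because reasonable pipelines use either.

Dip duration runs from the last zero down-crossing preceding the minimum
to the first zero up-crossing following it. Crossings are located by
linear interpolation between adjacent samples rather than snapped to the
grid: at a 10 ms decimated sampling period, duration differences of
~100 ms between conditions are scientifically meaningful. Two numerical
details matter here:

- **Zero band.** A sample counts as "at zero" when it is within
  $\max(10^{-3}\,|A|,\ 0.5\,\mathrm{SD}_{\mathrm{base}})$ of zero, where
  $A$ is the dip amplitude. The first term absorbs the tiny residual
  offset the session-wide regression can leave on a baseline-subtracted
  row; the second treats samples statistically indistinguishable from
  baseline as baseline, so a slow noise excursion that happens to abut
  the dip cannot drag the crossing hundreds of milliseconds away. Rows
  with $|A| < 10^{-9}$ are reported as having no dip at all, which keeps
  numerically silent (noise-free, blocked-sensor) recordings from
  producing spurious qualified dips.
- **Censoring.** If the signal has not re-crossed zero by the end of the
  5 s window, the duration is censored at the window end and flagged,
  rather than the trial being excluded — exclusion would bias dose
  comparisons against exactly the conditions with the longest dips.

The AUC decomposition integrates the trapezoid rule over $[0, 5]$ s:
the **total** AUC is the signed integral of the whole window (initial
peak, dip and rebound all contribute); the **negative** AUC integrates
between the dip's two crossings (with interpolated endpoints, so it is
exactly $\le 0$); the **rebound** AUC integrates the positive lobe from
the dip's end crossing to the next down-crossing or the window end and
is zero for censored dips. An initial peak preceding the dip therefore
contributes to the total only — it is recoverable by subtraction but is
not reported as a separate component. The decomposition is validated
against a 1000×-oversampled brute-force integrator on random
piecewise-linear rows (relative error < 1%).

The DA peak is the mirror image (maximum, $+$`peakSdK` SD threshold)
with a single signed AUC. Optogenetic onset latency is the first time
after light onset at which the trace falls below the dip threshold and
stays below it for at least 50 ms; a 0.001% ΔF/F floor on the threshold
keeps noise-free baselines from triggering at floating-point level.

Block-mean decimation smears each crossing by up to half a block
(20 ms at the small-session rates used in the tests), which is why
duration-recovery tests allow 1.5 decimated sample periods rather than
one: the bias is a property of the prescribed downsampling operator, not
of the crossing detector.

# Lagged cross-correlation

For every integer-sample lag $\tau \in [-3, +3]$ s, the Pearson
correlation between the DA row and the $\tau$-shifted ACh row is
computed per trial on the overlapping segment and then averaged across
trials. Correlating per trial and averaging — rather than concatenating —
keeps slow between-trial drifts from inflating the correlation.
The sign convention: negative $\tau$ shifts the ACh series so that its
features occur after DA's ("ACh lags DA"), matching how such lags are
reported. The lag grid is every decimated sample (10 ms at default
rates), fine enough that reported lag SEMs of ~14 ms are representable.

The negative extremum is the global minimum of the mean-r curve. The
positive (rebound) extremum is the maximum restricted to
$\tau \le -0.5$ s; without the bound, the shoulder of the deep trough
near $-0.18$ s would often beat the genuine rebound peak near $-1.5$ s.
Ties break toward the smaller $|\tau|$. Variance explained is
$r^2 \times 100$; Fisher's $z = \operatorname{artanh}(r)$ with
$z$-statistic $(z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ compares two
correlations.

Intertrial-interval (ITI) coupling uses the same machinery on 10 s
chunks of the recording lying strictly outside every trial window;
fixed-length chunks give each segment a comparable sample count. The
chunk length is a free choice — the analysis tradition does not fix one —
and is exposed as an argument.

# Repeated-measures statistics and the power chain

`rmAnovaOneway()` implements the complete-case within-subjects
decomposition directly (condition, subject, residual sums of squares),
with the Greenhouse–Geisser $\varepsilon$ from the double-centered
sample covariance of the condition columns, $F$ tested on
$\varepsilon$-scaled degrees of freedom, and
partial $\eta^2 = F\,df_{\mathrm{eff}}/(F\,df_{\mathrm{eff}} +
df_{\mathrm{err}})$. Note the $\eta^2$ formula is invariant to scaling
both dfs by $\varepsilon$, so corrected and uncorrected dfs give the
same effect size. The mean off-diagonal correlation among condition
columns is reported as the $\rho$ of the power calculation. Incomplete
matrices are refused with a pointer to mixed-model tools — imputation
and unbalanced designs are deliberately out of scope.

The sample-size calculation searches for the smallest $n$ whose power
reaches the target under the noncentral-$F$ model
$$\lambda = \frac{f^2\, n\, m\, \varepsilon}{1-\rho},\qquad
  df_1 = (m-1)\varepsilon,\qquad df_2 = (n-1)(m-1)\varepsilon,$$
with $f = \sqrt{\eta^2/(1-\eta^2)}$. Power-analysis software differs in
where $\varepsilon$ and $\rho$ enter; this package states its convention
explicitly, exposes both parameters, and cross-checks the analytic power
against a 50 000-draw Monte-Carlo noncentral-$F$ oracle in its test
suite (agreement within 0.01). With the documented convention the chain
reproduces the published worked example: $\eta^2 = 0.681 \to f = 1.46
\to n = 5$ at $\alpha = 0.05$, power 0.8, $m = 6$, $\rho = -0.068$,
$\varepsilon = 0.3193$ (and $\eta^2 = 0.620 \to f = 1.28 \to n = 5$ for
the companion latency design).

# The synthetic-data generator

Real recordings of this kind are not redistributable, so validation
rests on a generator whose ground truth is exact. Its design choices:

- **Kernel family.** Event-locked components are half-sine
  (compact-support) lobes. Nothing in the quantification chain
  constrains the waveform family — only timing, amplitude and duration —
  and half-sine lobes buy two exactness properties: the configured dip
  duration *is* the zero-crossing duration of the noise-free kernel
  (a difference-of-exponentials dip never re-crosses zero, so its
  "duration" would be undefined), and the lobes' symmetry puts the
  cross-correlation extremum exactly at the configured peak-to-peak lag
  (verified numerically on the noise-free kernels before the shapes were
  frozen: argmin at −0.18 s, argmax at −1.5 s). The mild onset kink of a
  half-sine is immaterial to trapezoid integration and crossing
  interpolation.
- **Geometry.** The DA transient peaks 0.32 s after lever extension
  (0.6 s lobe); the ACh dip minimum trails the DA peak by
  $|{-0.18}|$ s with a 1 s zero-crossing duration; the rebound lobe
  begins where the dip ends — the rebound follows the pause — and its
  default width (1.64 s) places its peak 1.5 s after the DA peak under
  the default dip geometry. When a dose shortens the dip, the rebound
  shifts earlier with it, which is the physiologically sensible reading.
- **Channel model.** $F_{465} = B\,\beta(t)\,(1+m(t))\,(1+s(t)/100) +
  \text{noise}$ and $F_{405} = B'\,\beta(t)\,(1+m(t)) + \text{noise}$,
  with $\beta$ a single decaying exponential (bleaching, $\tau = 3000$ s)
  and $m(t)$ smooth random bumps shared by both channels. Motion enters
  *multiplicatively* (a gain artifact), which is what makes it exactly
  removable by the isosbestic regression even while the bleaching
  baseline decays; additive bumps on a decaying baseline would not be
  exactly removable by any single linear fit, and the pipeline's
  motion-cancellation invariant (|ΔF/F| < 10⁻⁶ on blocked-sensor
  sessions) would be unattainable. No amplitude scale for motion is
  established in this literature; the default (1% gain bumps at
  0.02 Hz) is a free parameter.
- **Noise.** Independent per-channel Gaussian noise, band-limited to
  ~3 Hz (iid knots at 6 Hz, linearly interpolated), emulating the
  low-pass of lock-in photometry acquisition. White noise would be both
  unrealistic and pathological for zero-crossing analysis. The default
  SD (0.3% of the channel baseline) gives single-trial dips of ~10× the
  baseline noise and trial-mean negative correlations near −0.45 —
  comparable to reported in-vivo values.
- **Trial structure.** ITIs are exponential draws truncated to
  [mean/2, 2·mean] (default mean 40 s; tests use shorter sessions).
  Per-trial response gains are log-normal (SD 0.2), shared across a
  trial's components, providing the trial-to-trial variability that the
  AUC–latency coupling needs.
- **Dose, genotype, blockade, opto.** A dose label maps to a triple
  (dip-duration multiplier ≤ 1, rebound multiplier ≥ 1, DA-amplitude
  multiplier ≥ 1), applied monotonically across the default six-level
  series. The knockout genotype halves the DA-coupled dip and rebound
  components (the reported >twofold coupling reduction). Sensor blockade
  zeroes every event-locked component. Optogenetic mode replaces the
  natural cue response with a 0.5 s square inhibition plus a linear ramp
  back over 1 s (short) or 3 s (long), the long mode adding a rebound
  overshoot; onset is delayed 0.2 s after light onset, matching the
  ~206 ms in-vivo onset latency scale.
- **Behavioral coupling.** Press latency is drawn as
  $\mathcal N(\text{base} + \text{slope}\times \text{AUC}_{\mathrm{tot}},
  \sigma)$ floored at 0.1 s, with base 3 s, slope 1 s per %·s and
  $\sigma = 0.4$ s: a dose series then spans mean latencies of roughly
  2–4 s and pooled trials show a clearly positive AUC–latency
  correlation, comparable to the published trial scatter. Spontaneous
  coupled DA–ACh events (rate 0.08 Hz, half amplitude) populate the ITI
  so that ITI correlation analysis has structure to find.
- **Ground truth** is computed on a dense event-relative grid (1 ms)
  from the same kernel code, so it is independent of where a trial falls
  on the session's sample grid and bit-identical across sessions that
  share parameters.

## What the generator does not emulate

Sensor kinetics asymmetries (GRAB-ACh off-kinetics are slower than
dLight's), hemodynamic or pH artifacts, non-stationary noise, overlapping
responses from short-latency presses, and any biophysics of cholinergic
interneuron firing. Passing the recovery suites therefore shows the
*analysis chain* is correct and unbiased under the stated signal model —
it does not certify performance on pathological real-world recordings.

# Problem sizes and determinism

The validation suites use: 20 seeded cohorts of 30 trials at 1 kHz for
lag/duration recovery; 20 seeds × 5 subjects × 3 doses of 10-trial
sessions at 250 Hz for dose-effect recovery; 500 random piecewise-linear
rows for the integrator oracle; 50 000 draws for the Monte-Carlo power
oracle. These sizes give stable medians while keeping the full suite in
the minutes range on one core. Every random quantity derives from an
explicit seed; a session is a pure function of its configuration, and
`runPipeline()` writes a manifest with per-stage trial counts (aligned,
dropped, latency-filtered, censored) so any reported n can be audited.

# Known limitations

- Zero-crossing duration is intrinsically noise-sensitive; the
  baseline-SD zero band bounds but does not eliminate the jitter
  (median recovery error is ~9% at the default noise level).
- The two-way (genotype × dose) mixed ANOVA and post-hoc families are
  delegated to general statistical software; only the one-way
  repeated-measures chain that feeds the power calculation is
  implemented here.
- Lag extrema are reported on the sample grid; no sub-sample
  interpolation of the correlation curve is attempted.
- The session container is a plain-text CSV directory (wide channel
  table + events + JSON metadata). It round-trips exactly and is
  language-portable, but makes no claim to archival efficiency.
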