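# photoduet

Analysis of simultaneously recorded dual-sensor fiber-photometry signals:
striatal dopamine (dLight-type sensor) and acetylcholine (GRAB-ACh-type
sensor), each acquired with a 465 nm signal channel and a 405 nm
isosbestic control channel on a common time base, together with operant
behavioral events (lever extension, press, reward, head entry, optogenetic
light pulses).

The scientific setting: a reward-predicting cue evokes a phasic dopamine
(DA) peak and a multiphasic acetylcholine (ACh) response — an optional
initial peak, a prominent dip whose minimum trails the DA peak by roughly
180 ms, and a rebound about 1.5 s later. D2-receptor manipulation
(antagonist dose series, cell-type-specific knockout) reshapes the dip
duration and rebound without abolishing the dip, and the size of the
cue-evoked ACh deficit couples to the latency of the subsequent lever
press. `photoduet` implements the quantification chain for this kind of
experiment and ships a seeded synthetic-session generator with complete
ground truth, so every stage is testable against known answers.

## What the package computes

- **ΔF/F preprocessing** — block-mean downsampling (factor 10 by
  default), a least-squares fit of the 405 nm channel to the 465 nm
  channel giving the activity-independent baseline F0, and
  ΔF/F (%) = (F − F0)/F0 × 100. The isosbestic fit removes photobleaching
  and motion artifacts shared by the two excitation wavelengths.
- **Event-aligned trials** — a 15 s window ([−5, +10] s) around each
  event, nearest-sample alignment, local baseline (mean over [−5, 0) s)
  subtracted per trial; truncated windows are dropped and counted.
- **Dip / peak metrics** — dip amplitude (minimum over the 5 s
  post-event window, qualified at ≥ k·SD below baseline, k = 2 by
  default), dip duration between interpolated zero crossings, and the
  AUC decomposition: total, negative (between the dip's crossings) and
  rebound (positive lobe following the dip), all in %·s.
- **Lagged cross-correlation** — per-trial Pearson r between the DA and
  ACh signals at every sample lag in ±3 s, averaged across trials;
  negative lag means ACh lags DA. The global minimum locates the
  dip-coupling (r < 0 near −0.18 s) and a bounded search locates the
  rebound coupling (r > 0 near −1.5 s). Variance explained is r² × 100;
  Fisher's z compares correlations.
- **Behavior and statistics** — press latency per trial, the >2 s
  latency filter separating cue-evoked from movement-associated activity,
  AUC–latency Pearson correlation, anticipatory-responding quintile
  index, one-way repeated-measures ANOVA with Greenhouse–Geisser ε,
  partial η² = F·df_eff/(F·df_eff + df_err), Cohen's f = √(η²/(1−η²)),
  and the repeated-measures sample-size calculation from the noncentral-F
  distribution with λ = f²·n·m·ε/(1−ρ).

## Worked example

```r
library(photoduet)

cfg <- simConfig(nTrials = 20, samplingRateHz = 500, itiMeanS = 20,
                 seed = 42)
out <- generateSession(cfg)          # session + ground truth
ana <- analysisConfig()
ev  <- sessionEvents(out$session, "lever_extension")
tmA <- alignTrials(processSession(out$session, "ACh", ana), ev, ana,
                   trialInfo = data.frame(latency_s = out$truth$latency_s))
tmD <- alignTrials(processSession(out$session, "DA", ana), ev, ana)

head(quantifyTrials(tmA, tmD, ana)[, c("latency_s", "amplitude_pct",
     "duration_s", "neg_auc", "rebound_auc", "total_auc")], 4)
#>   latency_s amplitude_pct duration_s neg_auc rebound_auc total_auc
#> 1     1.668        -2.970      0.979  -2.044       0.958    -0.810
#> 2     2.908        -2.594      1.240  -1.847       0.331    -2.738
#> 3     1.908        -4.462      1.020  -2.567       1.991    -0.175
#> 4     2.163        -3.248      0.920  -1.876       0.040    -1.535

findExtrema(lagScan(tmD, tmA, ana), ana)
#> LagCorrResult (trial): 20 trials, lags [-3.00, 3.00] s
#>   negative peak: r = -0.491 at lag -0.200 s (24.1% var)
#>   positive peak: r = 0.200 at lag -1.600 s (4.01% var)
```

Each quantified trial reports the ACh dip amplitude (% ΔF/F), its
zero-crossing duration (s) and the three AUC components (%·s); the lag
scan recovers the configured coupling — the ACh dip trailing the DA peak
by ≈ 0.2 s with a negative correlation near −0.5, and the weaker rebound
coupling near −1.5 s (this 20-trial session lands within a couple of
samples of the generator's −0.18 s / −1.5 s truth).

The effect-size chain, run on a published design (η² = 0.681, six
repeated measures, ρ = −0.068, ε = 0.3193, α = 0.05, power 0.8):

```r
rmSampleSize(f = cohensF(0.681), alpha = 0.05, power = 0.8, m = 6,
             rho = -0.068, epsilon = 0.3193)
#> [1] 5
```

`runPipeline()` orchestrates the whole chain for a simulated cohort
(subjects × doses) and writes `metrics.csv`, `lagcorr.csv`,
`dose_response.csv`, `power.csv`, `correlations.csv`, per-dose
trial-average traces and a `manifest.json` with exact per-stage trial
bookkeeping.

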