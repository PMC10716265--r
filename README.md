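# afhorizon

Near-term atrial fibrillation (AF) risk from **AF-free** single-lead
ambulatory ECG.

Paroxysmal AF is intermittent: even two weeks of continuous patch
monitoring can miss it entirely. `afhorizon` implements a hierarchical
framework that looks only at stretches of ECG *without* AF — from 10
minutes up to 24 hours — and estimates the probability that the
individual shows AF during the monitoring period, enabling risk-guided
re-monitoring of people whose first patch came back negative.

The pipeline, end to end:

* **Windowing + quality rules** — the ECG is split into 10-minute
  windows; a window is rejected if mean heart rate < 20 bpm, if > 2 min
  is labelled artifact, or if R peaks are too few/too sparse for HRV.
* **Per-window features** — standard short-term HRV metrics on NN
  intervals (ectopic beats excluded: any interval adjacent to a PAC/PVC
  is dropped), ectopic counts/rates, non-AF abnormal-rhythm burdens, and
  a 128-dimensional learned embedding from a 1-D convolutional window
  encoder (*DL module A*, trained with weak recording-level labels, then
  frozen).
* **Normalization** — burden/rate features via `y = 1 − exp(−(x−offset)/scale)`;
  other continuous features via Box-Cox (maximum-likelihood exponent)
  plus standardization; fitted on the training split only.
* **Sequence risk score** — a 2-layer bidirectional LSTM over the window
  sequence, plus 2 fully connected layers with demographics appended
  (*DL module B*), with six input configurations from demographics-only
  (`AG`) to `All Features`.
* **Calibration** — per-age-group isotonic regression (weighted
  pool-adjacent-violators) on a natural-prevalence calibration cohort:
  raw scores become probabilities of observing AF, with the mean fitted
  probability exactly equal to the cohort prevalence.
* **Evaluation** — AUC / average precision with percentile bootstrap
  confidence intervals, paired bootstrap two-sided tests on identical
  resample indices, operating points at sensitivity 0.80
  (specificity / precision / F1 = 2·prec·sens/(prec+sens)), stratified by
  age (<65 / ≥65), input length and AF-burden range (<1%, 1–10%, >10%).

Clinical patch data cannot be redistributed, so the package ships a
seeded **synthetic ambulatory-ECG cohort simulator** (sum-of-Gaussians
PQRST waveforms driven by autocorrelated sinus and irregular AF RR
processes, ectopy, artifacts, and a controllable association between
AF-prone status and the AF-free signal) that exercises the whole
framework; see the methods vignette
(`vignettes/af-risk-from-af-free-ecg.Rmd`) for the model and every design
decision.

## Worked example

Simulate one annotated recording, label it, select an AF-free hour and
extract features:

```r
library(afhorizon)

p   <- sim_profile(af_episode_rate = 20, af_episode_duration = c(300, 0.5),
                   pac_rate = 6, age = 71, sex = "F")
rec <- simulate_recording(p, duration = 10800, seed = 42, fs = 100)

lab <- label_recording(rec$episodes, rec$fs)
#> AF positive: TRUE | burden: 0.023 | persistent: FALSE

sel <- select_af_free_interval(rec$timeline, 3600)  # earliest clean hour
sel$start
#> [1] 0

round(window_features(rec$episodes, rec$beats, sel$windows$start[1], rec$fs)[
  c("mean_nn", "sdnn", "rmssd", "pnn50", "pac_count", "lf_hf_ratio")], 4)
#>     mean_nn        sdnn       rmssd       pnn50   pac_count lf_hf_ratio
#>      0.8479      0.0493      0.0330      0.1530      0.0000      0.6910
```

The recording is AF positive (a 4-minute episode, burden 2.3%), yet the
selected input hour is AF-free — exactly the prediction setting.

The full experiment — simulate a cohort, train both modules, calibrate,
evaluate — runs in a few minutes on one CPU:

```r
ex <- run_af_pipeline(seed = 7, config = af_pipeline_config())
print(ex)
#> AF prediction experiment (seed 7 )
#>   analyzed recordings: 1343 of 1380
#>   module A held-out window AUC: 0.878
#>   AUC [AG]: 0.657 (95% CI 0.576-0.741)
#>   AUC [All Features]: 0.986 (95% CI 0.972-0.997)
#>   paired All Features vs AG: dAUC 0.330 (p = 0.0010)
```

Reading the numbers: the demographics-only model (`AG`) reaches AUC 0.657
purely from the age structure of AF risk; adding HRV, ectopic, rhythm and
learned morphology features lifts discrimination to 0.986 on this
synthetic cohort, and the paired bootstrap puts the improvement far from
chance. Scoring the same subjects from a single 10-minute window instead
of the full hour gives AUC 0.972 — longer AF-free observation helps,
while the AG model is exactly insensitive to input length.

A thin CLI wraps the same functions: `inst/cli/afhorizon simulate ...`
writes a cohort (optionally as WFDB records with text annotations), and
`inst/cli/afhorizon run --seed 7 --out report.json` runs the experiment.

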