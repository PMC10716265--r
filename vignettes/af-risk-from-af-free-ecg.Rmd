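---
title: "Predicting near-term AF from AF-free single-lead ECG: models, simulator and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting near-term AF from AF-free single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Paroxysmal atrial fibrillation (AF) is intermittent: a person can wear an
ambulatory single-lead ECG patch for days and show no AF at all, yet carry
substantial risk of an episode in the near term. `afhorizon` implements a
complete framework for quantifying that risk from **AF-free** stretches of
single-lead ECG between 10 minutes and 24 hours long. A recording is
*AF positive* when it contains at least one AF (or atrial flutter) episode
lasting more than 30 s anywhere in the monitoring period; prediction,
however, may only look at intervals that contain no AF at all. Recordings
in persistent or near-persistent AF (burden above 70%) are excluded, since
for them detection, not prediction, is the clinical question.

Because clinical patch-monitor datasets cannot be redistributed, the
package ships a first-class synthetic cohort generator that emulates the
statistical structure such data are assumed to have, so that the entire
pipeline — windowing, feature extraction, both deep modules, calibration,
and the bootstrap evaluation protocol — can be exercised and validated end
to end.

## Pipeline overview

1. **Windowing.** The ECG is divided into contiguous 10-minute windows. A
   window is invalid when any of three independent quality rules fires:
   mean heart rate below 20 beats/min; more than 2 minutes labelled
   artifact; or R peaks too few or too sparse for HRV computation.
2. **Per-window features.** Heart-rate-variability metrics on
   ectopic-excluded NN intervals; ectopic counts and rates; non-AF
   abnormal-rhythm burdens; and a 128-dimensional learned embedding from a
   convolutional window encoder ("module A").
3. **Normalization.** Burden/rate-like features get an exponential
   transform `1 - exp(-(x - offset)/scale)`; other continuous features a
   Box-Cox transform followed by standardization. All parameters are
   fitted on the training split only.
4. **Sequence scoring.** A 2-layer bidirectional LSTM followed by 2 fully
   connected layers ("module B") maps the window-feature sequence plus
   demographics to a raw risk score in (0, 1).
5. **Calibration.** Per-age-group isotonic regression on a
   natural-prevalence calibration cohort converts raw scores to
   probabilities of observing AF in the monitoring window.
6. **Evaluation.** AUC and average precision with percentile bootstrap
   confidence intervals, paired bootstrap model comparisons on identical
   resample indices, operating points at sensitivity 0.80, and strata by
   age (<65 / >=65), input length, and AF burden (<1%, 1-10%, >10%).

## The synthetic cohort generator

`simulate_cohort()` draws per-subject profiles and `simulate_rhythm_timeline()`
realizes each recording as a rhythm-episode partition plus a beat
annotation stream; `synthesize_signal()` renders waveform samples on
demand as a sum-of-Gaussians PQRST template train (5 kernels: P, Q, R, S,
T per beat).

Key mechanisms and their defaults:

* **Sinus rhythm.** NN intervals follow an AR(1) process (lag-1
  coefficient 0.85) plus a respiratory modulation at 0.25 Hz; the two
  variance components are mixed by `rsa_depth` (default 0.3) so that the
  stationary SD equals `sdnn_target` (subject-level, drawn from
  0.04-0.07 s). Mean RR is drawn from 0.7-1.0 s.
* **AF episodes.** A Poisson process of episodes with log-normal
  durations; inside an episode the RR process switches to i.i.d.
  shifted-gamma draws with coefficient of variation about 0.25 (the
  "irregularly irregular" rhythm) and the P wave is suppressed, with a
  5.8 Hz fibrillatory baseline oscillation added. A zero episode rate
  yields burden exactly 0.
* **Ectopy.** PACs and PVCs are premature beats: a selected sinus beat is
  shifted 35% of the preceding RR earlier; PACs keep a narrow QRS with a
  small early P, PVCs get a wide QRS and inverted T.
* **Artifacts.** Segments (default 6/day, about 60 s) replace the signal
  with high-amplitude noise and carry no beat annotations; they are
  labelled, never dropped.
* **The learnable association.** AF-prone subjects receive an 8x PAC-rate
  multiplier, a 1.4x NN-variability multiplier, and a morphology shift of
  0.3 (P-wave amplitude/width up, T-wave amplitude down) in their non-AF
  rhythm. These effect sizes are configuration knobs — the clinical
  literature motivates their direction (ectopy, autonomic tone and atrial
  remodelling precede AF) but no quantitative effect sizes are available,
  so the defaults are declared, not estimated.
* **Burden strata.** AF-prone subjects are assigned a target stratum
  (<1%, 1-10%, >10%) by the requested mix; episode rate and duration are
  solved from a log-uniform target burden within the stratum. Realized
  burden is recomputed from the realized episodes and recorded in the
  manifest together with the latent proneness flag, the observed
  AF-positive label and the persistent-AF exclusion.
* **Ages.** AF-prone subjects are drawn older (normal, mean 70 vs 60),
  reflecting the strong age dependence of AF prevalence, so that the
  demographics-only model has genuine but limited discrimination.

All randomness descends from one integer master seed through a
counter-based splitting scheme (`af_subseed()`), so any subject's
recording can be regenerated independently and reruns are bit-identical.

What the generator does **not** emulate: real atrial electrograms, lead
geometry, respiration-coupled baseline wander beyond a fixed sinusoid,
skin-contact noise spectra, medication effects, or circadian structure.
Passing tests therefore show that the pipeline recovers the planted
association under controlled conditions — not that the shipped effect
sizes match any clinical population.

## Design choices in the models

* **Module A** is a 1-D CNN: four conv(kernel 7)-ReLU-meanpool blocks,
  widths 8/16/32/32 with pooling 8/4/4/4, global average pooling, then a
  fully connected layer of width 128 (the embedding) and a sigmoid unit.
  It consumes the window resampled to 25 Hz: at that rate beat timing,
  prematurity patterns and the low-frequency template content that carry
  the simulated signature are intact, while training stays within
  single-CPU reach. Widths and rate are configurable.
* **Weak labels.** Module A is trained on AF-free windows carrying their
  recording's AF-positive label — the only label its description supports.
  After training its weights are frozen (asserted by exact checksum).
* **Module B** uses hidden width 16 per direction and a head layer of 16.
  Demographics are appended after the recurrent stage. During training
  each sequence is truncated to a random prefix length so a single model
  serves all input lengths from 1 to 144 windows. The demographics-only
  (AG) configuration is implemented as the fully connected head alone, so
  its scores are exactly ECG-independent, and the DL-Only configuration
  feeds embeddings without demographics.
* **Initialization.** Input-to-hidden weights of the first LSTM layer are
  keyed by feature *name*, not column position, which makes the model
  exactly equivariant to the order in which feature groups are
  concatenated — a checkable symmetry rather than an approximate one.
* **Optimization.** Adam at learning rate 1e-3, minibatch 16, early
  stopping on a held-out validation fraction (15%), gradient-norm
  clipping at 5. One shared encoder serves all age groups; at desk scale
  the sequence model is pooled across age groups while calibration stays
  per age group.

## Calibration

Isotonic regression via weighted pool-adjacent-violators with tied raw
scores pooled first; evaluation is stepwise-constant with clipping at the
knot range. The fitted map preserves the calibration-cohort prevalence
exactly and preserves score order, so group-level discrimination is
unchanged up to ties. Headline AUC/AP are computed on raw scores: the
pooled desk-scale sequence model already places all subjects on one
scale, and the coarse step structure of an isotonic map fitted on a few
hundred recordings would only inject tie noise; calibrated probabilities
are used for the reliability analyses, which is what calibration is for.
(With full-scale calibration cohorts of tens of thousands per group
the distinction vanishes.)

## Numerical and protocol choices

* "Too few or too sparse" R peaks is quantified as fewer than 60 usable
  (non-artifact) peaks per window, or any non-artifact inter-peak gap
  over 30 s; both thresholds are arguments.
* The AF-free interval policy is the earliest interval on the 10-minute
  grid whose windows are all valid and AF-free — deterministic and
  label-blind; alternative start policies are a configuration choice.
* Episodes of 30 s or less count toward burden but not toward the
  AF-positive outcome; burden is computed over the entire acquisition,
  including the input interval's day.
* The Box-Cox exponent is fitted by profile maximum likelihood on
  [-2, 2]; non-positive values under a fitted shift are clamped to the
  smallest positive double with a warning. Embeddings are standardized
  only (a fixed exponent of 1): they are already approximately symmetric
  and the choice is toggleable.
* Exponential-family membership is decided by feature role (burden/rate),
  not by a distribution test, keeping the pipeline deterministic.
* The operating point picks the largest score threshold whose sensitivity
  reaches the target; F1 is reported at full precision with 2-decimal
  rounding only in printed tables.
* Bootstrap defaults to B = 2,000 resamples at desk scale (the reference
  protocol's 10,000 is available via the `B` argument); percentile
  intervals at 95%; single-class resamples are redrawn and counted.
  Paired comparisons reuse the identical index stream, so marginal CIs
  coincide with the unpaired ones at the same seed.

## Desk-scale study conditions

The reference experiment (`af_pipeline_config()`, used by the test suite
and the acceptance script) simulates 1,380 subjects at AF prevalence 20%
— slack above the 600 training / 300 calibration / 300 test split so that
recordings without a qualifying AF-free hour (about 3%, mostly
high-burden) do not starve the splits. Recordings are 3 h at 100 Hz;
the AF-free input interval is 1 h (six windows), scored at 10-minute and
1-hour lengths; module A trains on one window per training subject for up
to 8 epochs; module B for up to 30. A full run takes a few minutes on one
CPU. These sizes are the package's reference conditions; every one of
them scales up through the configuration object.

```{r}
library(afhorizon)
ex <- run_af_pipeline(seed = 7, config = af_pipeline_config())
print(ex)
ex$report # stratified bootstrap table
```

On these conditions the experiment reproduces the qualitative orderings
the framework is designed to show: the all-features model dominates the
demographics-only model by a wide AUC margin (paired bootstrap p well
below 0.05); a 1-hour input scores at least as well as a 10-minute input;
and the demographics-only model is exactly insensitive to input length.
The test suite (`tests/testthat/test-acceptance.R`) asserts these
properties, and `scripts/acceptance.R` recomputes and reports them.

## Known limitations

* Waveform realism is limited to what feature extraction consumes; no
  claim is made about morphology beyond the template parameterization.
* Window-level lazy synthesis is deterministic per (seed, window start)
  but its noise realization differs from whole-record synthesis.
* At desk scale the per-age-group isotonic maps rest on ~60 recordings
  each, so pooled decile reliability is noisy (the package reports it as
  computed); the separately tested calibration guarantees use the sample
  sizes at which isotonic regression is dependable.
* The networks are intentionally tiny; absolute AUC values on synthetic
  cohorts say nothing about clinical performance.
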