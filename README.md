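# ewsmotion

Early warning signals (EWS) of intentional motion onset.

## The problem

Before a person starts a reach, their body passes from a stationary state
— fluctuating around a stable posture — to rapid directed motion. If that
switch is a *fold transition* (saddle-node bifurcation) of the underlying
motor dynamics, critical slowing down guarantees statistical precursors in
the resting fluctuations: the lag-1 autocorrelation AR(1) of the velocity
rises, the autocorrelation decay time τ lengthens, and the windowed
variance σ² grows, all *before* any overt motion. An opponent who can read
these signals gains a reaction-time advantage.

`ewsmotion` implements this analysis as a tested R pipeline for people
studying critical-transition signatures in movement data:

* **Fold-transition simulator** — the normal form
  ẋ = y + a·x² − x³ + γ·ξ(t), ẏ = ε (a = 4, γ = 0.063, 10 ms readouts),
  detrended so the dot fluctuates around the origin until a transition at
  t\* ∈ [350, 700] ms, plus step-function controls matched in transition
  time and noise amplitude but free of correlation structure.
* **Synthetic motion capture** — 240 Hz, seven-sensor Attacker/Blocker
  reaching trials with planted ground truth: body center-of-mass onset
  leads finger onset by 52 ms, the latent EWS event leads finger onset by
  131 ms, the Blocker responds 300 ms after the EWS event.
* **EWS statistics** — sliding-window AR(1), decay time
  τ = argₗ R(l) ≤ R(0)/e, and unbiased variance, with threshold-based
  rise detectors (AR(1) > 0.1; τ fold-change > 20%; σ² threshold).
* **Scaling law** — near a fold, σ² ∝ (t\* − t)^(−1/2) (versus (t\* − t)^(−1)
  for pitchfork/Hopf): the pipeline extracts ±100 ms variance curves
  around the divergence, block-averages 30 trials, and fits
  log σ² = −log b + n·log(t\* − t) to estimate the exponent n.
* **Association statistics** — kernel-density outlier filtering followed by
  OLS of onset times on EWS times (the intercept is Δt, the mean lead), and
  reaction-time comparisons (Mann-Whitney U with rank-biserial effect size,
  Kolmogorov-Smirnov, Harrell-Davis decile shift function).

## Worked example

```r
library(ewsmotion)

# simulate a matched stimulus ensemble and look for early warning signals
cfg <- run_config(seed = 1, n_per_arm = 100)
report <- run_experiment3(cfg)
rates <- report$rates
cat(sprintf("AR(1) rise before t*: fold %.0f%%, control %.0f%%\n",
            100 * rates$ar1$fold, 100 * rates$ar1$control))
cat(sprintf("decay-time rise before t*: fold %.0f%%, control %.0f%%\n",
            100 * rates$tau$fold, 100 * rates$tau$control))
cat(sprintf("variance-divergence exponent: n = %.2f\n",
            report$scaling$median_n))
cat(sprintf("observer RT advantage on fold stimuli: %.0f ms (p = %.2g)\n",
            report$rt$mean_diff_ms, report$rt$p_mw))

# synthetic motion-capture trials: recover the planted leads
mtrials <- generate_block(cfg$motion, 30)
onsets <- lapply(mtrials, trial_onsets, cfg = cfg)
lead <- sapply(onsets, function(o) 1000 * (o$finger_onset - o$body_onset))
cat(sprintf("center-of-mass lead over finger onset: %.1f ms\n", mean(lead)))
```

prints

```
AR(1) rise before t*: fold 100%, control 5%
decay-time rise before t*: fold 100%, control 21%
variance-divergence exponent: n = -0.51
observer RT advantage on fold stimuli: 220 ms (p = 1.8e-28)
center-of-mass lead over finger onset: 51.5 ms
```

Reading: nearly every fold trajectory shows an autocorrelation rise in a
window lying wholly before its transition while the matched uncorrelated
controls rarely do; the fitted divergence exponent sits at the fold value
−1/2 (a pitchfork or Hopf transition would give −1); an idealized observer
reading the EWS cues responds substantially earlier on fold stimuli; and
the onset detectors recover the generator's planted 52 ms center-of-mass
lead.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_stimuli.R   # fold + matched control ensembles
Rscript analysis/02_ews_detection.R      # per-arm EWS detection rates
Rscript analysis/03_variance_scaling.R   # divergence exponent (600 trials)
Rscript analysis/04_motion_capture.R     # PCA, onsets, delta-t regressions
Rscript analysis/05_reaction_times.R     # simulated-observer RT comparison
```

The methods vignette (`vignettes/ews-motion-methods.Rmd`) documents the
models, estimator conventions, calibration rationale and limitations.

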