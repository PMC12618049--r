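# saccmix

Two-process decomposition of early saccades in blocked foreperiod tasks.

## What this is for

In a foreperiod paradigm a warning stimulus (WS) precedes an imperative
"go" target by a fixed, blocked delay (FP). Saccades launched before a
visual response is possible ("early saccades", latency from WS offset up to
100 ms after go onset) have a bimodal latency distribution: an impulsive
first mode near 200 ms whose timing ignores the foreperiod, and an
anticipatory second mode whose latency mean and SD grow with the foreperiod
(scalar expectancy). `saccmix` is for researchers in oculomotor and timing
behavior who want a tested, reproducible implementation of that analysis:

* a **synthetic generator** of the full experiment (25 subjects x 4 FP
  blocks x 120 trials; spatial-uncertainty cues with target probabilities
  1, 1/2, 1/3, 1/4) at both the event level and the raw 500 Hz trace
  level, with ground truth for scoring;
* **saccade detection** from raw traces by amplitude (> 1 deg), velocity
  (> 22 deg/s) and acceleration (> 3800 deg/s^2) criteria, plus trial
  artifact rejection;
* **latency-window classification** into early vs visually guided saccades
  with the standard exclusion rules (latency > 1000 ms after go, saccade
  after an early saccade, wrong target box);
* **mixture decomposition**: from-scratch EM for k-component Gaussian
  mixtures per FP block, model selection (BIC or the literal
  lowest-log-likelihood rule), and the analytic crossing point
  `w1 N(x; mu1, s1) = w2 N(x; mu2, s2)` as the 1st/2nd-mode threshold;
* **inference**: Shannon surprise `-log2 p` of the cue conditions,
  mode x FP summaries, two-stage per-subject slopes and
  random-intercept models (via lme4) recovering the planted trends
  (2nd-mode latency slope 0.61 ms/ms, SD slope 0.17 ms/ms, 1st-mode
  log-rate slope -0.001/ms, Vmax difference 21.2 deg/s, amplitude
  difference 0.8 deg), Poisson rate trends, and the tie-corrected Spearman
  correlation of per-subject mode counts.

## Worked example

The analysis is organized as numbered drivers under `analysis/`, each a
thin script over the package functions, writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # generate the experiment + manifest
Rscript analysis/02_detect.R     # raw-trace detection vs ground truth
Rscript analysis/03_classify.R   # latency windows + exclusion rules
Rscript analysis/04_mixture.R    # per-block EM + crossing thresholds
Rscript analysis/05_inference.R  # trends, summaries, surprise table
```

A condensed run (seed 20) prints:

```
early-saccade trials: 10.4% (impulsive 415, anticipatory 839)
anticipatory latency SD by FP block (scalar expectancy):
  400   900  1400  1900
 56.5 145.2 207.3 293.8
detector recall 0.981, precision 0.981 (n = 576 true saccades)
early-saccade trials: 10.4%  (paradigm guide: ~10%)
surviving VG trials:  78.0%  (paradigm guide: ~78%)
selected mixtures and mode thresholds:
   fp k                 means threshold_ms n_obs
  400 3 197.62,410.392,478.69     329.3686   387
  900 2       203.048,714.468     345.2270   340
 1400 2       205.112,1035.39     400.7210   264
 1900 2       201.071,1350.13     379.3690   263
2nd-mode latency ~ FP: slope 0.626 +- 0.016 (planted 0.61)
1st-mode latency ~ FP: slope 0.0123 +- 0.0077 (planted 0)
Vmax: 2nd - 1st mode = 19.3 deg/s (planted 21.2)
amplitude: 2nd - 1st mode = 0.76 deg (planted 0.8)
random-intercept model: slope 0.620 +- 0.013, BIC 11146.6
between-subject mode-count Spearman r = 0.87
```

Read: about one trial in ten ends in an early saccade; each block's early
latency distribution splits into a ~200 ms mode (mean stable across blocks)
and an anticipatory mode tracking the foreperiod; the crossing-point
threshold separates them; and the two-stage estimator recovers the
generating slopes within their standard errors. In the 400 ms block the
censoring of anticipatory latencies at FP + 100 ms makes BIC prefer a third
component -- see the methods vignette
(`vignettes/two-process-decomposition.Rmd`) for why, and for every
modeling and numerical choice.

The same machinery accepts user data: tab-separated trial/event tables in
the documented dialects (`read_tsv`), or a minimal eye-tracker ASCII sample
format via `parse_ascii_samples()`, with pixel-to-degree conversion from a
`screen_geometry()` (default: 54 x 30 cm screen, 1920 x 1080 px, 80 cm
viewing distance).

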