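# eegtrp

Task-related EEG band power analysis with nonparametric factorial
statistics.

`eegtrp` is for researchers who record multichannel EEG while participants
perform extended cognitive tasks (here: interpreting technical drawings and
CAD-modelling from them) and want the complete path from raw microvolts to
inferential tables: signal cleaning, epoch segmentation, artifact
rejection, band-power and task-related-power computation, and robust
repeated-measures statistics. It targets the fixed 14-electrode 10–20
montage of a consumer wireless headset (AF3, F7, F3, FC5, T7, P7, O1, O2,
P8, T8, FC6, F4, F8, AF4) sampled at 128 Hz, with hemisphere (LH/RH) and
cortical-area (frontal FA / rear RA) partitions built in.

## The method

The core quantity is task-related power. For subject *j* and electrode
*i*, with Pow the mean of squared band-passed samples (µV²):

    TRP_ij = log10(Pow_i(task)_j) − log10(Pow_i(baseline)_j)

computed per frequency band (theta 4–7 Hz, alpha 8–12 Hz, beta 13–30 Hz)
against the 20 s baseline recorded immediately before each task. Positive
TRP means power increased during the task.

Around that core the package implements:

* **Cleaning** — 0.16 Hz first-order IIR high-pass (DC offset), 4–45 Hz
  Hamming windowed-sinc FIR applied zero-phase, and muscle-artifact
  removal by blind source separation via canonical correlation analysis
  (BSS-CCA: 2.5 s windows, 1.2 s shift, the 4 least-autocorrelated of 14
  sources removed).
* **Rejection** — 1 s windows sliding one sample at a time, discarded when
  mean |x| exceeds min(subject threshold, 100 µV) or any |sample| exceeds
  100 µV; the subject threshold is mean(|x|) + 3·SD(|x|) over the epoch.
* **Statistics** — median/MAD descriptives, aligned rank transform (ART)
  repeated-measures factorial ANOVA with partial eta squared, and pairwise
  Wilcoxon signed-rank post hocs (exact for n ≤ 25 without ties) with
  Bonferroni correction per comparison family and effect size r = |Z|/√n.
* **Simulation** — a synthetic cohort generator with per-band task/baseline
  amplitude gains (expected TRP = 2·log10(gain)), 1/f background,
  counterbalanced condition order, and injectable DC offsets, spikes and
  EMG bursts, so the whole pipeline is testable against known ground truth.

## Worked example

Simulate an 18-subject cohort in which the alpha-band amplitude rises by a
factor 1.25 during orthographic-condition tasks (so the true alpha TRP is
2·log10(1.25) ≈ 0.194 in that condition and 0 everywhere else), run the
full pipeline, and look at the recovered cohort means:

```r
library(eegtrp)

spec <- cohort_spec(n_subjects = 18,
                    seg1_s = c(isometric = 60, orthographic = 60),
                    seg2_s = c(isometric = 60, orthographic = 60),
                    gains  = list(alpha = list(orthographic = 1.25)),
                    seed   = 11)
bundle <- run_pipeline(run_config(cohort = spec, seed = 11))

aggregate(trp ~ band + projection, data = bundle$trp_table, FUN = mean)
#>    band   projection          trp
#> 1 alpha    isometric 0.0057534778
#> 2  beta    isometric 0.0002999573
#> 3 theta    isometric 0.0014304563
#> 4 alpha orthographic 0.2005365881
#> 5  beta orthographic 0.0069956399
#> 6 theta orthographic 0.0002002787
```

The orthographic alpha mean (0.2005) recovers the planted 0.1938 within
the Monte-Carlo noise of 18 subjects; every unmanipulated band/condition
cell sits near 0. The bundle also carries `art_tables` (one row per
effect: F, dfs, p, partial eta squared for the projection × electrode,
projection × hemisphere and projection × area models per segment and
band), `posthoc` (Wilcoxon families with V, Z, p, Bonferroni-adjusted p
and r, gated on ART significance), `descriptives` (Med/MAD per cell),
`rejection` (per-epoch bad-data percentages) and, for synthetic runs,
the generator's `ground_truth`. `write_bundle(bundle, dir)` exports
everything as CSV/JSON.

A thin command-line wrapper for whole runs lives at
`inst/cli/eegtrp.R` (`simulate` and `run-all` subcommands).

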