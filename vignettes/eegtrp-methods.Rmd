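---
title: "Task-related EEG band power: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-related EEG band power: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtrp)
```

## The analysis problem

`eegtrp` analyses multichannel EEG recorded while participants work through
design tasks, each preceded by a 20 s fixation-cross baseline. The quantity of
interest is task-related power (TRP): for subject $j$ and electrode $i$,

$$\mathrm{TRP}_{ij} = \log_{10} \mathrm{Pow}_i(\mathrm{task})_j -
  \log_{10} \mathrm{Pow}_i(\mathrm{baseline})_j,$$

the log ratio of band power during a task epoch to band power during the
baseline recorded immediately before that task. Positive values mean power
increased during the task; negative values (event-related
desynchronisation in the alpha band, for instance) mean it decreased.
Because TRP is a within-subject, within-electrode log ratio, gain
differences between channels and subjects cancel: multiplying a whole
recording by any positive constant leaves every TRP unchanged.

The supported montage is the fixed 14-electrode 10--20 layout of a consumer
wireless headset (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8,
AF4) sampled at 128 Hz. Odd-numbered electrodes form the left hemisphere
(LH), even-numbered the right (RH); the frontal area (FA) comprises AF3,
F7, F3, F4, F8, AF4, FC5 and FC6, the rear area (RA) O1, O2, P7, P8, T7 and
T8. Seven homologous pairs (AF3|AF4, F3|F4, F7|F8, FC5|FC6, T7|T8, P7|P8,
O1|O2) support electrode-level hemispheric contrasts.

## The processing pipeline

`run_pipeline()` applies the stages in a fixed order:

1. **DC-offset removal** -- first-order Butterworth high-pass at 0.16 Hz
   (bilinear transform). Wireless amplifiers ride on a DC offset of
   thousands of microvolts; at 0.16 Hz the filter's gain at 10 Hz differs
   from unity by less than 0.02%, so analysed bands are untouched.
2. **Broadband band-pass** -- 4--45 Hz FIR, Hamming windowed-sinc. The
   transition bandwidth is 2 Hz at the low edge and 25% of the high cutoff
   (capped at 12.5 Hz) at the high edge; the filter order is
   $\lceil 3.3 / \Delta f_{\mathrm{norm}} \rceil$ from the narrower
   transition, forced odd so the symmetric (linear-phase) filter has an
   integer group delay. Filters are applied once and the $(N-1)/2$-sample
   delay is compensated, preserving the designed single-pass magnitude
   response (an alternative would be forward-backward filtering, which
   squares the response).
3. **BSS-CCA muscle-artifact removal** -- within 2.5 s windows shifted by
   1.2 s, canonical correlation between the window and its one-sample
   lagged copy orders sources by lag-1 autocorrelation. Muscle (EMG)
   activity is broadband and therefore nearly uncorrelated from one sample
   to the next, while cortical rhythms are strongly autocorrelated; the 4
   least-correlated of the 14 sources are zeroed and the window is
   reconstructed through the mixing inverse. "Least correlated" is read as
   lowest canonical correlation with the lagged copy -- the standard
   BSS-CCA criterion. Overlapping reconstructions are blended with a
   linear crossfade over the overlap; a trailing remainder of at least
   0.5 s becomes its own shorter window, anything shorter passes through.
   Near-singular window covariances are ridge-regularised with a warning.
4. **Segmentation** -- the event log cuts each session into the pre-task
   baseline, `seg1` (from drawing presentation to the first sketch
   element: interpreting the drawing) and `seg2` (from first sketch
   element to task end: generating the model). `seg1` ends exactly where
   `seg2` begins; samples are indexed half-open
   $[\mathrm{round}(t_0 f_s), \mathrm{round}(t_1 f_s))$ so epochs tile
   without duplication. Each task's TRP uses the baseline recorded
   immediately before that task; the post-task baseline is segmented but
   unused by default.
5. **Amplitude artifact rejection** -- a 1 s window slides one sample at a
   time. The subject-specific threshold is $\bar{|x|} + 3\,\mathrm{SD}(|x|)$
   pooled over all samples and electrodes of the epoch; absolute values
   are used because band-passed EEG is near zero-mean, where a raw-value
   threshold would degenerate to zero. A window is bad when its mean
   absolute amplitude exceeds $\min(\text{threshold}, 100\,\mu V)$ or any
   single sample exceeds $100\,\mu V$; a sample is kept only if every
   window covering it is good (the conservative union rule). Rejected
   spans are excluded from power averages, not zero-filled, which would
   bias power downward.
6. **Band split and power** -- theta 4--7 Hz, alpha 8--12 Hz, beta
   13--30 Hz, same FIR design rules. Power is the time-domain mean of
   squared band-passed samples over retained samples. The filter's
   edge-transient margin ($(N-1)/2$ samples at each epoch end, where the
   convolution has not reached steady state) is excluded from the average;
   without this exclusion an in-band sinusoid's measured power on a 60 s
   epoch is biased low by about 2%, with it the analytic $a^2/2$ value is
   matched to well under 1%. Log-transform happens after averaging
   (average-then-log). Base 10 is the default and all tolerances in the
   test-suite are stated in log10 units.

## Inferential statistics

Distributions of TRP are summarised by the median and the median absolute
deviation (MAD, scaled by 1.4826 by default to estimate a normal SD;
the raw MAD is available). A Shapiro--Wilk check annotates reports; the
pipeline is nonparametric regardless of its outcome.

Factorial questions -- does TRP differ by projection condition, hemisphere,
cortical area, electrode, and their two-way interactions -- are answered
with the aligned rank transform (ART). For each effect the response is
*aligned* (the full-factorial cell mean is removed and the effect's own
estimate, computed from unweighted cell means, is added back), then
midranked over all observations. ANOVA on the column aligned for effect
$E$ is sensitive to $E$ only; the alignment property that every other
effect's marginal means vanish is verified algebraically in the tests.
Each effect is then tested with a univariate repeated-measures ANOVA on
its aligned ranks, with subject as the random blocking unit and the effect
tested against its subject-by-effect interaction stratum; no sphericity
correction is applied. Effect size is partial eta squared,
$\eta_p^2 = F \cdot df_e / (F \cdot df_e + df_\mathrm{err})$.

Because the electrode factor nests both hemisphere and area, a single
four-way crossed model does not exist; the pipeline fits three two-factor
models per segment and band -- projection $\times$ electrode, projection
$\times$ hemisphere, projection $\times$ area -- mirroring the usual
cortex / hemispheres / areas reporting structure. In the hemisphere and
area models each subject contributes several electrodes per cell; the
design is complete with equal replication per cell across subjects (8
frontal vs 6 rear observations per cell is a property of the montage, not
an imbalance across subjects).

Significant effects are decomposed into pairwise Wilcoxon signed-rank
families: projection over the cortex (paired by subject and electrode),
hemispheres (paired by subject, projection and homologous pair),
projection within hemisphere or area, hemisphere within projection
including the seven homologous pairs (a Bonferroni family of 7), and
projection within electrode (family of 14). Each family is
Bonferroni-adjusted by its own comparison count. For the area-vs-area
contrast the two areas have different electrode counts, so per-subject
area means are paired instead. Zero differences are dropped and absolute
differences midranked; $V$ is the sum of positive-difference ranks. The
p-value is exact (signed-rank null distribution) for up to 25 non-zero
pairs without ties, otherwise a tie- and continuity-corrected normal
approximation. The reported effect size is $r = |Z|/\sqrt{n}$; the
literal statistic-over-$\sqrt{n}$ variant is available behind
`r_method = "statistic"` but is not scale-free, which is why the $Z$
convention is the default.

## The synthetic cohort generator

Real recordings of this kind are rarely redistributable, so the package
ships a simulator that generates full sessions with known ground truth.
Each channel is a sum of one band-limited oscillation per band
(band-pass-filtered white noise by default, so the cleaning stages see
realistic spectra; pure sinusoids are available for analytic tests) and a
$1/f^{\chi}$ background ($\chi = 1$ by default). Defaults emulate the
study conditions the pipeline targets: 18 subjects, two tasks per session
(one per projection condition) with the condition order counterbalanced
across cohort halves, 20 s baselines, and task-segment durations set to
one tenth of the observed median completion times (seg1 3.2 s isometric /
7.15 s orthographic, seg2 86.1 s / 90.4 s) so that a full cohort run
remains desk-scale. Baseline oscillation amplitudes default to 6/10/4
microvolts for theta/alpha/beta (alpha dominant, as in resting EEG) over a
5 microvolt RMS background.

Task epochs multiply each band's amplitude by a gain $g$; since power
scales as amplitude squared, the expected TRP is exactly
$2\log_{10} g$. Gains can be set directly per band and condition, or
through additive TRP offsets attached to the projection, hemisphere or
area factor. Injectable artifacts target each cleaning stage: a constant
DC offset (default 4200 microvolts, a conventional figure for wireless
headsets -- the generator's default, not a measured constant),
single-sample spikes exceeding the rejection limits, and 1 s band-limited
20--45 Hz EMG bursts, each logged exactly as injected.

What the generator does *not* emulate: volume-conducted spatial mixing is
absent by default (each channel's components are independent), there is no
ocular-artifact model, no non-stationarity within epochs, and no
inter-electrode correlation structure. Two consequences matter for
interpreting the tests. First, on generator output the BSS-CCA stage
removes genuine broadband background power (the data are full rank, so the
four lowest-autocorrelation sources are real noise); band powers change,
but TRP is preserved because the removal affects task and baseline epochs
alike -- parameter-recovery checks therefore validate TRP, not raw power,
under CCA. Second, tests of CCA's selectivity (remove the EMG burst, spare
alpha) use a low-rank fixture -- a handful of alpha sources mixed into 14
channels over autocorrelated background -- because that, not independent
channels, is the regime the method is designed for in real EEG. Passing
tests demonstrate correctness of the implementation under these controlled
conditions, not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* FIR designs come from `signal::fir1` with the order rule above; taps are
  checked symmetric in the tests (linear phase).
* The rejection stage computes rolling means by cumulative sums; its
  output is tested for exact agreement with an explicit loop over every
  window.
* CCA windows with near-singular covariance are ridge-regularised
  (relative ridge $10^{-8}$) with a classed warning.
* Epochs fully rejected by the amplitude criterion raise a classed error
  rather than returning `NaN` power; callers exclude the epoch.
* Zero Wilcoxon differences yield the degenerate result ($V = 0$, $p = 1$,
  $r = 0$) flagged as such.
* All generators and the pipeline are pure functions of their
  configuration and a single integer seed; reruns are bit-identical.

## Problem sizes used by the validation suite

The test-suite and the acceptance script simulate at desk scale: the
parameter-recovery cohort uses 18 subjects with 60 s task segments and
20 s baselines; ART calibration uses 500 null and 100 power simulations of
the 2 (projection) by 14 (electrode) within-subject design at $n = 18$;
Wilcoxon exactness is enumerated exhaustively for all sign patterns up to
$n = 8$; rejection oracles use 30 s epochs. These sizes were chosen so the
whole validation runs in minutes on one CPU while keeping Monte-Carlo
error well below the tested tolerances.

## A minimal run

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 18,
                    gains = list(alpha = list(orthographic = 1.25)),
                    seed = 11)
bundle <- run_pipeline(run_config(cohort = spec, seed = 11))
aggregate(trp ~ band + projection, data = bundle$trp_table, FUN = mean)
bundle$art_tables[bundle$art_tables$effect == "projection", ]
```

## Known limitations

* The EDF writer emits a single data record spanning the recording, which
  is read back by the package's own reader and by tolerant EDF readers but
  may exceed the per-record size that strict implementations expect.
* The ART error structure is the univariate repeated-measures one; mixed
  models and sphericity corrections are out of scope.
* Only Bonferroni is offered for multiplicity; only the three two-factor
  models are fitted by the pipeline (custom `art_model()` calls cover
  other crossed subsets).
* No ocular-artifact removal: the cleaning stages target DC offset,
  out-of-band noise, EMG and amplitude excursions only.
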