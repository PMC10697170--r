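# oculoseq

Analysis of **prestimulus oculomotor inhibition** in foreperiod
(temporal-expectation) paradigms: in the few hundred milliseconds before
an anticipated target, the rate of (micro)saccades drops, and the
probability of observing a saccade onset in a fixed pretarget window
([-300, 0) ms relative to target onset) tracks how strongly the
observer expects the target at that moment. `oculoseq` is written for
researchers in eye-movement and timing research who want a tested,
reproducible pipeline from raw binocular gaze samples to the statistical
tables such studies report — and a synthetic-data generator with planted
ground truth to validate every stage of it.

The package covers:

* **Simulation** — binocular 1000-Hz gaze traces with planted saccades
  (raised-cosine profiles obeying the main sequence
  v_peak = k·A^e), blinks, drift, and a planted logistic model of
  pretarget saccade probability, under two designs: five foreperiods
  (500–2100 ms) drawn uniformly or with inverse-U (1:2:3:2:1) weights;
  or fixed vs. random foreperiod blocks (1000–3000 ms).
* **Preprocessing** — pixel-to-degree conversion, zero-phase 60-Hz
  Butterworth low-pass filtering, trial segmentation (−500 ms re cue to
  +500 ms re target), and blink detection (missing-data spans plus a
  binocular 2.5-SD pupil criterion, padded ±200 ms).
* **Detection** — binocular velocity-threshold saccade detection:
  5-point velocity estimator, a threshold of λ = 6 median-based SDs
  above the segment median, ≥ 6-sample minimum duration, a 50-ms
  intersaccadic interval to suppress overshoots, binocular merging, and
  main-sequence quality control (r > 0.9 per participant).
* **Trial tables** — pretarget-window saccade flags, exclusions
  (session-first trials; blinks/missing data in the window), the
  foreperiod difference FP(n) − FP(n−1) and its z-scaled version (SFD),
  and the previous-foreperiod-equal screening rule for fixed/random
  designs.
* **Inference** — binomial-logit mixed models (lme4, Laplace) with the
  parsimonious random-effects ladder, Type-II likelihood-ratio tests,
  BIC-approximated Bayes factors (BF01 = exp(ΔBIC/2)), and
  FDR-corrected Wald contrast tables; broom-style `tidy()`/`glance()`
  methods.
* **Reporting** — condition summaries with Cousineau–Morey
  within-subject error bars, polynomial/linear overlay fits, ggplot2
  figures, and an end-to-end `run_pipeline()` driver.

## Worked example

Simulate a small two-group cohort at trial level, fit the
sequential-effect model, and summarize:

```r
library(oculoseq)

trials <- simulate_exp1_cohort(n_per_group = 10, blocks = 2,
                               n_trials_per_block = 100, seed = 42)
fit <- fit_experiment1(trials)
fit
#> <oseq_exp_fit> exp1, random: (1 + sfd | subject)
#>              term      chisq df           p        bf01
#>               sfd 13.6072422  2 0.001109749    4.416802
#>      distribution  1.4716244  1 0.225089576   30.226117
#>  sfd:distribution  0.6253661  2 0.731481702 2911.297172
```

The SFD family (linear + quadratic, df = 2) is clearly significant:
saccade probability falls as the current foreperiod becomes longer than
the previous one — the oculomotor sequential effect the planted model
contains. At this reduced cohort size (10 subjects per group, 200
trials each) the small planted distribution effect and near-zero
interaction are not detected, and BF01 ≈ 30 and ≈ 2900 quantify the
evidence for those nulls.

```r
tidy(fit)
#> # A tibble: 6 x 5
#>   term                   estimate std.error statistic  p.value
#>   <chr>                     <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)             -1.53      0.103    -14.8   9.61e-50
#> 2 sfd                     -0.205     0.0758    -2.70  6.95e- 3
#> 3 I(sfd^2)                 0.0853    0.0339     2.52  1.19e- 2
#> 4 distribution1           -0.142     0.103     -1.38  1.67e- 1
#> 5 sfd:distribution1       -0.0249    0.0753    -0.330 7.41e- 1
#> 6 I(sfd^2):distribution1   0.0238    0.0337     0.705 4.81e- 1
```

The recovered linear (−0.205 ± 0.076) and quadratic (0.085 ± 0.034)
log-odds coefficients bracket the planted values (−0.238 and 0.081).
`categorical_sfd_contrasts(trials)` re-fits SFD as a factor and tables
each level against the zero level with FDR-corrected p-values, and
`plot_sfd_profile(trials)` draws the probability profile with
within-subject error bars.

The full signal path — synthesized gaze, filtering, blink rejection,
saccade detection, trial building, fitting — runs through one call:

```r
report <- run_pipeline(design = design_spec("exp1", "uniform",
                                            n_subjects = 4, blocks = 2,
                                            n_trials_per_block = 30),
                       seed = 7)
report$main_sequence   # per-participant main-sequence QC (r > 0.9)
```

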