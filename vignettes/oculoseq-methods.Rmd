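---
title: "Methods: simulating and analyzing prestimulus oculomotor inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing prestimulus oculomotor inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoseq)
```

## The phenomenon and the measurement

In foreperiod paradigms a warning cue is followed, after a variable
interval (the *foreperiod*, FP), by a target. In the few hundred
milliseconds before an anticipated target, the rate of saccades — mostly
microsaccades under fixation — drops. This *prestimulus oculomotor
inhibition* scales with temporal expectation, so the probability of
observing any saccade onset in a fixed pretarget window (here
$[-300, 0)$ ms relative to target onset) can serve as a trial-level
marker of anticipation.

`oculoseq` implements the full analysis path for two designs:

* **Variable-foreperiod ("exp1")**: five foreperiods
  (500–2100 ms in 400-ms steps) drawn from either a uniform or an
  inverse-U-shaped (1:2:3:2:1) distribution. The covariate of interest is
  the *foreperiod difference* $FP_n - FP_{n-1}$, z-scaled into the
  standardized foreperiod difference (SFD). A sequential effect shows up
  as a dependence of pretarget saccade probability on SFD.
* **Fixed-vs-random blocks ("exp2")**: foreperiods 1000–3000 ms in 500-ms
  steps, constant within fixed blocks and drawn uniformly per trial in
  random blocks. To separate block-level predictability from the
  first-order sequential effect, random-block trials are screened so that
  only trials whose previous foreperiod equals the current one are
  analyzed.

Because raw eye-tracking data from such studies are not generally
redistributable, the package ships a first-class synthetic-data module
with planted ground truth, and every downstream claim in the test suite
is made against that ground truth.

## The inferential model

Saccade presence $Y_{ij} \in \{0, 1\}$ for subject $j$, trial $i$ is
modeled with a binomial-logit mixed model. For the variable-foreperiod
design:

$$
\mathrm{logit}\,P(Y_{ij}=1) = \beta_0 + b_{0j}
 + (\beta_1 + b_{1j})\,s_{ij} + \beta_2 s_{ij}^2
 + \beta_3 x_j + \beta_4 x_j s_{ij} + \beta_5 x_j s_{ij}^2,
$$

where $s$ is the SFD, $x$ the sum-coded distribution factor (+1 uniform,
−1 inverse-U), and $b_{0j}, b_{1j}$ subject random effects. The quadratic
regressor is the square of the z-scaled variable (raw polynomial, not
orthogonalized), so the linear and quadratic coefficients are directly
interpretable as slope and curvature at SFD = 0.

Model machinery:

* **Estimation** is maximum likelihood with the Laplace approximation via
  `lme4::glmer()`; with `random = "none"` the model reduces exactly to
  ordinary logistic regression. Laplace (rather than adaptive quadrature)
  is the standard choice for trial-level binomial GLMMs of this size and
  is treated here as an approximation knob, not a modeling decision.
* **Term tests** are Type-II likelihood-ratio tests: interactions
  containing the tested term are removed from both members of the nested
  pair, all other terms of equal or lower order are retained, and the
  random structure is held fixed across the pair. The SFD family (linear
  + quadratic) is tested jointly with df = 2.
* **Null-result quantification** uses the BIC approximation to the Bayes
  factor, $BF_{01} = \exp\{(\mathrm{BIC_{full}} -
  \mathrm{BIC_{reduced}})/2\}$, reported with the null in the
  denominator.
* **Random-effects selection** follows the parsimonious ladder: random
  intercept by subject, then random slopes for within-subject main terms
  with their correlations, then interaction slopes. A rung that fails to
  converge or is singular is trimmed by the random slope with the least
  estimated variance and retried; the final structure is the richest one
  that converges with no singular estimate. Singularity is operationalized
  as any random variance below $10^{-4}$ (logit scale) or any correlation
  within $10^{-3}$ of ±1.
* **Contrast tables** (each foreperiod-difference level against the zero
  level; distributions contrasted at each level) use Wald statistics with
  normal 95% CIs and Benjamini–Hochberg FDR correction within the
  contrast family. Factor codings: sum for two-level factors, successive
  (backward) differences for ordered foreperiod levels, treatment coding
  against the zero level for the level-vs-zero table.

## Saccade and blink detection

Detection is the velocity-threshold family standard for microsaccades:

1. Gaze is low-pass filtered at 60 Hz with a zero-phase
   (forward–backward) 4th-order Butterworth filter. Zero-phase filtering
   preserves onset timing, which the window test depends on. Each
   contiguous non-missing run is filtered separately with odd-reflection
   padding (200 samples) so run boundaries produce no start-up
   transients; runs shorter than 30 samples pass through unfiltered.
2. Velocity is the 5-point moving-window estimate
   $v_t = (p_{t+2} + p_{t+1} - p_{t-1} - p_{t-2}) / 6\Delta t$.
3. A sample is flagged when it exceeds the segment's median velocity by
   $\lambda = 6$ *median-based* standard deviations
   ($\sigma^2 = \mathrm{med}(v^2) - \mathrm{med}(v)^2$). The default
   criterion is elliptical (per-axis); a scalar-speed variant is
   available via `detection_params(criterion = "scalar")` because the
   verbal description of such thresholds does not fix the 2-D form.
4. Flagged runs of at least 6 samples are candidates; a candidate
   starting within 50 ms of the previous accepted offset is discarded as
   an overshoot (discarded, not merged, to keep the primary movement's
   offset kinematics intact); candidates intersecting blink exclusion
   intervals are dropped.
5. Only binocular events are kept: a left and right candidate overlapping
   by at least one sample are merged (earlier onset, later offset;
   kinematics averaged over eyes), with greedy one-to-one pairing by
   overlap length.
6. Quality control is the main sequence: per participant, the Pearson
   correlation between log amplitude and log peak velocity must exceed
   0.9. Amplitude is onset→offset displacement — not path length — as is
   standard in this algorithm family.

Blinks are the union of (a) missing/sentinel gaze or pupil spans and (b)
spans in which the pupil deviates from the segment's mean by more than
2.5 segment SDs in both eyes for ≥ 3 consecutive samples. "Change in
pupil size" is read as the deviation of the sample from the segment mean
(the level), which is the sentence-level reading of the criterion; a
first-difference variant is available via `pupil_change = "diff"`.
Detected blinks are padded by ±200 ms into exclusion intervals. Segment
statistics (pupil mean/SD, velocity median/SD) are always computed per
segment, never globally.

Policy and mechanism are separated deliberately: blink detection only
reports intervals; dropping trials whose exclusion interval touches the
$[-300, 0)$ ms window happens in the trial-table module, together with
the discard of each session's first trial (which has no previous
foreperiod).

Two conventions worth making explicit:

* The pretarget window is half-open, $[-300, 0)$, and onset-based: a
  saccade with onset at exactly 0 ms belongs to the post-target epoch.
  This avoids double counting at the boundary.
* The previous foreperiod is the previous *presented* trial's foreperiod
  within a subject, whether or not that trial itself survives exclusion.
  Online-aborted-and-repeated trials are not modeled.
* SFD z-scaling is pooled across subjects and distribution groups (the
  covariate enters one joint model); per-group scaling is available via
  `compute_sfd(per_group = TRUE)`.

## The synthetic-data generator

`synthesize_gaze()` produces 1000-Hz binocular x/y/pupil traces per trial
segment (−500 ms re cue to +500 ms re target) containing:

* **Drift**: a mean-reverting (toward screen center) random walk shared
  by both eyes (innovation SD 0.002°/sample, reversion 0.002/sample),
  plus independent white measurement noise per eye (SD 0.01°, a typical
  video-oculography noise floor). Mean reversion stands in for the
  combination of slow drift and corrective behavior that keeps fixation
  bounded.
* **Saccades** with raised-cosine displacement profiles. The profile is a
  $C^1$ smooth ramp with zero endpoint velocity; any such profile
  satisfying the main sequence would do, and the raised cosine is
  analytically convenient. Planted peak velocity obeys the main sequence
  $v_{peak} = k\,A^{e}$ exactly (defaults $k = 60$ (deg/s)/deg, $e = 1$),
  and the raised-cosine shape then fixes the duration at
  $D = 1000\,\pi A / (2 v_{peak})$ ms (≈ 26 ms at the defaults). The
  duration is therefore *derived* from the main-sequence law rather than
  specified independently — specifying both would over-determine the
  profile, and the main-sequence relation is the property the detector's
  quality control relies on. Amplitudes are log-normal
  ($\mu = -0.94$, $\sigma = 0.7$ on the log scale), putting about 91% of
  events below 1°, the typical preponderance of microsaccades under
  fixation instructions. Directions bias toward screen center whenever
  gaze is eccentric, which keeps the eye inside the 1.5° fixation-control
  radius that the paradigm's gaze-contingent procedure enforces online.
  Both eyes receive the same planted event plus independent noise, since
  the detector requires binocular agreement.
* **Window saccades**: trials flagged by the planted logistic model
  receive exactly one saccade with onset uniform in $[-300, 0)$ ms;
  background saccades are planted outside the window as a Poisson process
  (default 1.2 events/s) — the background rate is a free, realistic
  default, not a quantity calibrated to any published rate curve.
* **Blinks**: pupil ramps down to a sentinel value of 0 over 20 ms, stays
  there for 100–300 ms with gaze missing, and ramps back — exercising
  both blink criteria. Pupil noise is a modest slow component shared
  between the eyes plus a larger independent per-eye component, so that
  only genuine blinks co-deviate binocularly.

The planted trial-level model (`planted_model()`) uses, as default
effects, a linear SFD coefficient of −0.238 and a quadratic of 0.081 on
the log-odds scale — magnitudes of the size reported for oculomotor
sequential effects — with an intercept of −1.4 (≈ 0.20 baseline window
probability), a distribution effect of −0.2, interactions of 0.038 and
0.022, and subject random SDs of 0.5 (intercept) and 0.23 (SFD slope).
The slope SD is calibrated so that, at the study's 40 subjects, the
simulated standard error of the linear coefficient reproduces the
precision implied by the reported Wald statistic for that coefficient
(SE about 0.039); between-subject slope variability dominates that
standard error at study scale.
The attention cue in the variable-foreperiod design is generated
(valid/invalid/neutral) but carries no effect, mirroring the fact that
pretarget oculomotor behavior cannot depend on post-target contingencies;
it is deliberately not part of the model.

What the generator does **not** emulate: smooth pursuit or post-saccadic
oscillations, calibration drift and head motion, pink-noise drift
spectra, saccade curvature, pupil foreshortening artifacts, or the
response/RT process (out of scope by design). Passing tests on this
generator therefore demonstrate the *internal correctness* of the
pipeline — detection recovers what was planted, the models recover the
coefficients that generated the data — not that any particular real
data set satisfies the detector's assumptions.

## Numerical choices and degenerate inputs

* Velocity thresholding signals a degenerate segment (zero robust SD) as
  a classed error; the detection driver counts such segments and emits no
  events for them.
* The z-scaling of foreperiod differences errors on zero variance rather
  than silently producing NaNs.
* `glmer` convergence is taken from the optimizer's own status plus any
  convergence warnings; failures feed the trimming ladder rather than
  erroring. Quasi-complete separation is flagged when any fixed-effect
  coefficient exceeds 15 in absolute value.
* Ties in binocular pairing are broken by earlier onset; candidate pairs
  are ranked by overlap length.
* All randomness flows through explicit integer seeds; identical seeds
  give bit-identical outputs, and the calling RNG state is restored.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations as
follows (the package's own choices, balancing Monte-Carlo error against
desk-scale runtimes): detection recovery uses 40 synthetic participants
with 16 trials each at default noise; coefficient recovery uses 20
replicates of a 40-subject cohort (20 per distribution group, 1400
trials per subject, the scale of the original design); the type-I-error
study uses 1000 replicates of a reduced 10-subject × 300-trial null
design fitted without random effects; oracle equivalences run on small
randomized inputs with fixed seeds.

## Known limitations

* The exponent of the planted main sequence defaults to 1, so the
  ground-truth amplitude–velocity relation is exactly linear; detection
  scatter comes from noise, not from biological dispersion around the
  main sequence.
* The BIC Bayes factor inherits the usual unit-information-prior
  approximation; it is a model-comparison heuristic, not a posterior
  quantity.
* Wald CIs in the contrast tables are symmetric normal approximations;
  at extreme cell probabilities profile intervals would differ.
* The simulator plants at most one window saccade per trial. The
  presence/absence analysis is insensitive to this, but window saccade
  *counts* would be miscalibrated against real data.
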