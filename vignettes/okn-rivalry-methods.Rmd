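---
title: "Methods: no-report binocular rivalry analysis from optokinetic nystagmus"
author: "oknrivalry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: no-report binocular rivalry analysis from optokinetic nystagmus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Under binocular rivalry (BR), each eye views a grating drifting in the
opposite horizontal direction, and conscious perception alternates between
the two. When the perceived grating moves, the eyes exhibit optokinetic
nystagmus (OKN): slow pursuit phases in the perceived direction, interleaved
with fast resetting saccades. The direction of the slow phases is therefore
a reflexive, no-report readout of which direction the observer currently
perceives — no button presses are needed, which removes response bias and
criterion effects from the rivalry time series.

This package implements the full analysis chain for such experiments:

1. **CSP segmentation** (`csp()`): from a 1 kHz horizontal gaze trace to a
   labelled timeline of left / right / mixed perception,
2. **priming metrics and QC** (`rpd_trial()`, `mixed_fraction()`,
   `ocular_dominance_index()`, `rpd_curve()`),
3. **group-level inference** (`cohort_report()` and the individual test
   functions), and
4. a **generative simulator** (`simulate_cohort()` and friends) that stands
   in for raw eye-tracking data and supports parameter-recovery testing.

## The cumulative smooth pursuit (CSP) estimator

`csp()` proceeds in five steps.

**Validity marking.** Samples flagged invalid by the tracker stay invalid.
Samples whose raw finite-difference speed exceeds a physiological ceiling
(default 800 deg/s) or whose position leaves the stimulus area by more than
1 degree are flagged, and every invalid run is padded by a guard margin
(default 25 ms) to absorb filter contamination at blink and saccade edges.

**Slow-segment detection.** Slow pursuit segments are maximal runs of valid
samples satisfying three criteria: smoothed velocity magnitude at most 60
deg/s, smoothed acceleration magnitude at most 1500 deg/s², and duration at
least 50 ms. The stimulus moves at 33.5 deg/s while saccades exceed
100 deg/s by a wide margin, so the 60 deg/s ceiling separates the phases
cleanly. The criteria are evaluated on a centred local-linear
(Savitzky–Golay order 1) derivative over 25 ms, with acceleration as a
±5 ms central difference of that velocity. Raw 1 kHz central differences
would be useless here: integrated velocity noise of 2 deg/s per sample
yields acceleration noise near 1000 deg/s², which would shred every
segment; the local-linear derivative suppresses this noise by two orders
of magnitude while leaving genuine saccadic excursions visible.

**Cumulative pursuit.** Segments are aligned so that each continues from
the previous one's endpoint, which removes the saccadic displacement
between them. Since alignment makes successive endpoints coincide, the
gaps between segments are constant-valued after interpolation: pursuit is
treated as paused during fast phases, blinks and artifacts.

**Bagged velocity profile.** The slow-pursuit velocity at every time point
is estimated by bootstrap aggregation over segments (B = 200 resamples by
default). Each resample draws segment multiplicities from a multinomial —
segments resampled with replacement — and the velocity at a grid point is
the count-weighted local-linear slope of the cumulative series over a
100 ms window. Interpolated gap filler carries weight zero: it is
deterministic given the neighbouring segments and contains no data of its
own. The per-time-point median and the 2.5/97.5 percentiles across
resamples form the profile and its 95% confidence band.

A structural property of segment-level resampling is worth stating
plainly: wherever the fit window lies inside a single slow segment, every
resample that retains the segment produces the *same* slope, so the CI
collapses to zero width there; the band widens exactly where windows span
segment joins and gaps, i.e. where the estimate genuinely depends on which
segments were drawn. Uncertainty is thus concentrated at saccades, blinks
and percept transitions, which is where classification errors matter.
Windows containing no segment samples at all (long blinks) are undefined
and classified as mixed. With fewer than two segments the whole profile is
degenerate — infinite-width CI, an all-mixed timeline — and the trial is
left for the quality filters to discard ("absence of detectable
nystagmus").

The profile is evaluated every 5 ms and interpolated back to the 1 kHz
grid; the estimate is smooth at the 100 ms window scale, so the stride
loses nothing while cutting cohort-scale runtime five-fold.

**Classification.** A sample is labelled `right` when the entire 95% CI
lies above +5 deg/s, `left` when it lies below −5 deg/s, and `mixed`
otherwise. Adjacent same-label samples merge into intervals; the timeline
tiles the rivalry phase exactly. All intervals are half-open `[start, end)`
in ms, with t = 0 at rivalry-phase onset; positive velocity is rightward.

The velocity and acceleration ceilings, minimum duration, resample count,
derivative window and dominance threshold are engineering defaults exposed
in `run_config()`; they are not claims about any other implementation of
the procedure.

## Priming metrics and quality control

**RPD.** The Ratio of Prime Direction of a trial is the proportion of the
first 1500 ms of *unmixed* perception spent perceiving the primed
direction: mixed intervals are removed, the unmixed intervals are
concatenated in order, and the primed time is divided by the window
actually covered. 0.5 means no modulation. Trials whose unmixed time falls
short of 1500 ms use the covered portion as denominator rather than being
discarded — the validity filter (below) makes such trials rare — and trials
with no unmixed time have no RPD. The complement identity
`rpd(left) = 1 − rpd(right)` holds by construction and is property-tested.

**Validity.** A trial is valid iff its mixed fraction is strictly below
0.70; a participant's condition RPD is the mean over valid trials and is
missing with fewer than 4 of them. Both cutoffs are strict: a trial at
exactly 70% mixed is invalid, a participant at ODI exactly 0.25 is kept.

**ODI.** The Ocular Dominance Index pools all of a participant's valid
baseline trials: `ODI = |t_right − t_left| / (t_right + t_left)` over the
summed dominance times (mixed time excluded). It is missing with fewer
than 3 valid baseline trials, and participants with ODI above 0.25 are
excluded. Eye-to-direction assignment comes from the trial metadata.

**RPD curve.** `rpd_curve()` lays each trial's 0/1 prime-match indicator
over its concatenated unmixed time and averages across trials in 10 ms
windows advancing by 2 ms (8 ms overlap), with a normal-approximation 95%
CI of the mean — the temporal profile of the priming effect over unmixed
perception.

## Group-level inference

VVIQ totals (16 items, 1–5 each, hence 16–80) map to imagery groups:
hypophantasia below 48, neurotypical 48–74, hyperphantasia 75 and above.
The battery in `cohort_report()` mirrors the study design: one-sided
one-sample t tests of each condition RPD against 0.5 (direction is part of
the analysis plan — greater for the imagery and conceptual conditions,
less for stimulus-driven priming — never inferred from data) with Cohen's
d and a JZS Bayes factor; Spearman and Kendall tau-b correlations between
VVIQ and condition RPD; a 2×3 mixed ANOVA (condition within, imagery group
between) with partial eta squared; one-way ANOVA with Tukey post-hocs;
Levene (centre = mean) and Kruskal–Wallis for the heteroscedastic
condition; Shapiro–Wilk checks; and two-condition repeated-measures ANOVAs
within groups.

Design choices that were genuinely open:

* **Imputation.** "Condition mean" imputation for the mixed ANOVA uses the
  grand mean of that condition across all participants; a group-wise
  variant sits behind `impute_by_group = TRUE`.
* **Bayes factors.** The JZS one-sample BF10 (Cauchy prior, scale √2/2)
  is computed by numerical integration of the noncentral-t likelihood over
  the prior and is cross-checked in the tests against an independent
  g-prior quadrature. A default Bayes factor for Kendall's tau is distinct
  published machinery and is deliberately out of scope.
* **Power analysis.** `required_n_one_sample_t()` walks the exact
  noncentral-t power curve to the smallest adequate n (d = 0.5, α = 0.05,
  power 0.90, two-sided gives 44). The correlational analogue uses the
  Fisher-z approximation and is flagged approximate: its answer depends on
  tool and tail conventions, so it is informative, not authoritative.

## The synthetic cohort generator

The generator emulates exactly the latent structure the CSP procedure
assumes, so that recovery can be measured against known truth.

* **Alternation process.** Dominance epochs are gamma distributed
  (shape 3, mean 2 s by default — the classic gamma-like shape of rivalry
  dominance distributions; the defaults are config-overridable and not
  calibrated to any particular sample). Mixed transitions between epochs
  are truncated-normal (mean 300 ms, SD 100 ms). The first unmixed percept
  matches the prime with probability `p_bias`; labels then alternate, and
  a prime-matching epoch starting at time t has its duration scaled by
  `1 + 2(p_bias − ½)·exp(−t/τ)` with τ = 800 ms, so the priming effect is
  concentrated in the early part of the trial and decays smoothly. The
  adaptation flag inverts the bias (stimulus-driven negative priming).
  Baseline trials must be unbiased.
* **OKN rendering.** During dominance the eye pursues at
  `gain × 33.5 deg/s` in the dominant direction; crossing ±6 deg of
  eccentricity triggers an instantaneous single-sample reset to centre
  (CSP discards fast phases anyway, so saccade kinematics need not be
  realistic). Mixed intervals render zero-mean velocity with doubled
  noise — any low-velocity model suffices, since by definition gaze does
  not indicate a dominant percept there. Gaussian velocity noise
  (2 deg/s per sample) integrates into the position trace; blinks arrive
  as a Poisson process (0.2/s, 100 ms) of invalid runs.
* **Paradigm.** Each participant completes three blocks (VISP, CONP, SDP),
  each two 25-s baseline rivalry trials followed by 12 priming trials, six
  leftward and six rightward in random order. Stimulus constants: 33.5
  deg/s at 48 px/deg (1608 px/s), 15.2° × 8.4°, 50% contrast, 8.7
  cycles/s, 0.26 cycles/deg, 1000 Hz sampling.
* **Cohort structure.** VVIQ totals draw from a normal (mean 57, SD 17)
  truncated to the requested group's range; items are distributed to hit
  the total exactly. The default effect map sets the VISP first-percept
  bias linear in VVIQ (0.40 at VVIQ 16 to 0.90 at 80) with flat CONP
  (0.62) and SDP (0.36) biases. The slopes were fixed a priori for high
  recovery power at cohort scale: they reproduce the *pattern* of the
  empirical results — an imagery-vividness gradient confined to imagery
  priming, uniform conceptual facilitation, uniform stimulus-driven
  adaptation — not their exact magnitudes.
* **Reproducibility.** A single cohort seed fans out to per-participant
  and per-trial sub-streams via a counter-based hash
  (`substream_seed()`), so adding a participant or trial never perturbs
  anyone else's data. Identical configuration and seed give bit-identical
  traces.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot show about real data: realistic saccade main sequences,
pupil and vertical gaze dynamics, drift and calibration error, tracker
loss correlated with eye movement, piecemeal (spatially mixed) rivalry,
and serial dependence between trials. Recovery results bound algorithmic
error under the assumed latent model, not measurement error in the wild.

## Numerical choices and degenerate inputs

* Half-open integer-millisecond intervals everywhere; a timeline must tile
  its phase exactly and adjacent intervals never share a label.
* The bagged profile uses prefix-sum local regression; windows at the
  trace edges truncate symmetrically. A window is undefined with fewer
  than two segment samples or a singular design, and undefined stretches
  classify as mixed.
* Classification at exactly the dominance threshold is mixed (strict
  inequality), mirroring the strict QC cutoffs.
* Degenerate statistical inputs fail loudly by design: zero-variance
  samples, all-tied rank inputs, groups with fewer than two members and
  out-of-range VVIQ items raise errors naming the offending quantity.

## Problem sizes used by the test suite

The suite's end-to-end checks run, per fixed seed: 10 000 latent sequences
for the binomial first-percept check; 2 000 sequences per bias level for
monotonicity; 240 CSP trials for null calibration of the RPD; 120 trials
for ground-truth label recovery; 20 replicates of a 90-participant cohort
(22/54/14 per group) for the qualitative priming signature, with 100
bootstrap resamples per trace at cohort scale; and 800–2000 null
replicates per statistical test for type-I calibration. These sizes are
the package's documented operating points for its own validation.

## Known limitations

* Segment-level bagging cannot express within-segment estimation noise;
  the CI is a statement about segment sampling, not about sample noise.
  With very few, very long segments the band is overconfident.
* The mixed ANOVA uses classical split-plot sums of squares via `aov()`;
  with a single between factor this is unambiguous, but unbalanced designs
  with additional between factors would need a Type-III framework.
* The Fisher-z correlational power analysis is approximate by
  construction.
* Timeline resolution is limited by the 5 ms profile stride; transition
  boundaries inherit that granularity.
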