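---
title: "Methods: gait, activity and validation analytics in pedgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait, activity and validation analytics in pedgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pedgait` analyzes tri-axial accelerometry from lumbar- and wrist-worn devices
in children: gait metrics validated against an instrumented-walkway reference
in clinic, and wear-time, activity-intensity and free-living gait summaries at
home. This vignette documents the models, the tunable parameters and the
design decisions, in the package's own words. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The synthetic-data generator

Raw pediatric accelerometry of this kind is not publicly deposited, so the
package ships a generator that emulates the two study settings with planted
ground truth. Its defaults define the conditions under which the pipeline is
tested.

**Walkway passes.** A pass is a constant-cadence walk on a straight mat. The
vertical axis carries

* gravity (+1 g, on a configurable axis and sign — the analyzer must re-detect
  both),
* a center-of-mass (CoM) sinusoid at step frequency whose *displacement*
  amplitude is h/2, with the excursion h chosen so that the planted step
  length L satisfies the same inverted-pendulum chord geometry the analyzer
  uses, `h = l − sqrt(l² − L²/4)` (so recovery is well-posed),
* a half-sine impulse (default 0.2 g, 50 ms) at each initial contact (IC),
  phased so the CoM is lowest at contact,
* additive white Gaussian noise on all axes (default 0.05 g for walkway
  passes, emulating body-contact artifact during active walking).

Anterior-posterior and mediolateral axes carry small sinusoids at step and
stride frequency; the stride-frequency (subharmonic) component is a genuine
gait signature that the bout detector exploits. Per speed class the cadence
and step-length/height fraction are drawn uniformly from class ranges
(natural 80–140 steps/min and 0.35–0.45·height; fast 130–180 and 0.42–0.52;
slow 55–85 and 0.25–0.35), values chosen once as plausible for ambulatory
children aged 3–17 with heights defaulting to 0.86 + 0.05·age (m).

**Free-living days.** A recording spans whole calendar days (midnight-aligned,
half-open intervals). Each day is composed per second: non-wear blocks
(gravity-only before noise), a 07:00–21:00 wake span, activity chunks
(defaults 120/45/15 min of light/moderate/vigorous in 20/15/5-min
minute-aligned chunks), walking bouts with log-normal lengths (right-skewed,
as free-living walking is), and sedentary time elsewhere — including the
sleep period when the device stays on, since a worn device never records
exact zeros. Activity classes are sinusoids with strictly ordered amplitudes
(0.15/0.5/1.2/2.4 g at 0.8/1.5/2.0/2.3 Hz); walking bouts reuse the walkway
signal model at natural-class parameters. The free-living noise default is
0.01 g: at-home signal segments are dominated by at-rest instrument noise
rather than gait-contact artifact.

Three generator details exist so that planted bookkeeping is *exact* rather
than approximate:

* activity segments ramp on/off over ≤ 2 s, so zero-phase filter transients
  do not bleed counts across a non-wear boundary epoch;
* placements keep 60 s clear of every non-wear block and wake boundary;
* distinct walking bouts keep a 10-s sedentary margin on each side, so two
  planted bouts are never fused into one contiguous walking episode.

The generator is deliberately minimal. It does **not** emulate turning,
stairs, joint kinematics, gyroscope channels, device clock drift, or the
broadband spectra of real human activity (classes are narrowband sinusoids).
Passing tests therefore demonstrate algorithmic correctness — event timing,
integration geometry, rule arithmetic, statistical calibration — not clinical
validity on real children.

## Gait analysis

**Vertical axis.** The axis whose mean (gravity component) has the largest
absolute value, with the sign that makes gravity positive.

**Contact events.** Detrend → low-pass (10 Hz) → cumulative trapezoidal
integration → continuous wavelet transform with a Gaussian-derivative
smoothing wavelet. The scale is `0.2 · fs / f_step`, where f_step is the
dominant frequency of the filtered acceleration in the physiologically
admissible band and 0.2 is the wavelet's center frequency. ICs are local
minima of the first-stage transform; final contacts (FCs) are local maxima of
its differentiated (second-stage) transform. Peaks shallower than 25% of the
largest peak are ignored; events implying step times below the bound are
pruned weakest-first. Feet alternate; left/right labels are arbitrary up to a
swap. FC timing in the sinusoid signal model is phase-convention-dependent,
so double-support durations are structurally consistent but not
truth-anchored — no accuracy claim is made for them.

**Physiological bounds.** Stride time in [0.25, 2.25] s and step time in
[0.1, 1.5] s by default, kept constant across walking speeds. Strides whose
duration violates the bound (e.g. spanning a detection gap) are simply not
formed.

**Spatial metrics.** Per step, the vertical displacement is estimated by
double integration of the vertical acceleration with a zero-phase high-pass
after each integration stage; the excursion h is max − min of displacement
within the step, and `step_length = 2·sqrt(2 l h − h²)` with
`l = 0.53 · height` (a standard anthropometric leg-length fraction; only the
height is subject input). Strides with degenerate geometry (h ≥ 2l) are
flagged invalid and dropped. Speed = stride length / stride time, exactly, by
construction.

**Numerical choices.** The displacement high-pass default is **0.5 Hz** and
the pre-integration low-pass **4 Hz**. Measured on the generator's own
conditions, a 0.1 Hz high-pass leaves enough doubly-integrated noise drift to
inflate the per-step excursion by several percent (stride-length median bias
near 9% at 0.05 g noise); 0.5 Hz reduces that to roughly 4% while attenuating
even the slowest admissible step frequency (≈ 0.9 Hz) by well under 1%. Both
cutoffs remain exposed in `gait_params()`. Residual positive bias comes from
the IC-impulse velocity step, whose sawtooth fundamental sits exactly at step
frequency and cannot be filtered without destroying the CoM component; it is
largest for slow walks (small h), which is why slow-class spatial errors are
the largest while remaining bounded.

## Free-living gait bouts

Windows are 3 s with 50% overlap (window count `floor((T−w)/hop)+1`).
Features per window: per-axis mean and SD, signal magnitude area, dominant
frequency of the vector magnitude with its power fraction, vertical
autocorrelation at the estimated step lag, the second-harmonic/fundamental
power ratio of the vertical signal, and the horizontal power fraction at half
the dominant frequency. The last two matter: smooth periodic movement
concentrates power at a single frequency, whereas walking's contact impulses
leave a harmonic comb and its mediolateral sway a stride-frequency
subharmonic.

The classifier is gradient-boosted trees (binary logistic, depth 4, 50
rounds, single-threaded, seed-reproducible). No trained weights ship with the
package — the training data are synthetic and regenerable, so honest use is
to train on generator-labeled windows (see the test suite for the recipe) and
serialize with `save_bout_model()`. A deterministic fallback
(`detect_gait_bouts_bandpower()`) thresholds locomotor-band (1.2–4 Hz) power
and the harmonic ratio, guaranteeing the pipeline runs with no model at all.
Positive windows merge into bouts, bridging gaps up to 3 s; each bout is then
passed through the gait module to populate strides and `n_gait_cycles`.
Window length, overlap, merge gap and thresholds are configuration, not
claims — the underlying study describes none of them.

## Wear time and activity intensity

**Counts.** Per axis: band-pass 0.25–2.5 Hz (4th-order Butterworth,
zero-phase), rectify, subtract a 0.05 g deadband, clip at 2.5 g, sum per 60-s
epoch (units g·s). The deadband makes a motionless, noise-only signal produce
*exactly* zero counts, which the non-wear logic requires; with the deadband
disabled the pipeline is exactly linear in amplitude below the clip. This is
an open surrogate for proprietary device counts, not a reimplementation of
them.

**Non-wear (Choi).** On 1-min epochs of vector-magnitude counts: a zero run
of ≥ 90 min is non-wear; nonzero interruptions of ≤ 2 min are absorbed when
flanked by ≥ 30 min of zeros on both sides. Parameters are the algorithm's
canonical values and sit in `choi_params()`.

**Intensity.** Cut-points on vector magnitude (sedentary < c1 ≤ light < c2 ≤
moderate < c3 ≤ vigorous), defaults c(6.1, 32, 63.5) g·s **calibrated once
against the generator's class energies** (geometric midpoints between
adjacent class count levels, with walking landing in the light band).
Because the counts are a surrogate, these values are configuration entries
with meaning only relative to this generator — they are not population
cut-points. An optional two-regression mode instead selects between two
configured MET regressions by the within-epoch CV of sub-epoch counts and
maps METs through 1.5/3/6 cut-offs. Non-wear epochs are excluded from every
total; daily MVPA = moderate + vigorous minutes; daily total vector magnitude
sums wear epochs only.

## Study rules and aggregation

* Bouts retained iff duration ∈ [10, 3000] s **and** ≥ 4 detected gait
  cycles; boundaries retained; filtering is idempotent and order-free.
* A day is valid at ≥ 10 h wear (lumbar) or ≥ 18 h (wrist); the boundary is
  valid.
* Per gait metric: median per bout, then mean across the day's bouts.
* Daily 95th-percentile gait speed uses linear interpolation between order
  statistics. The percentile's unit is ambiguous in prose descriptions of
  such pipelines ("across all walking bouts"): the default here is the 95th
  percentile of *per-bout median* speeds, consistent with the bout-then-day
  hierarchy; `p95_on = "strides"` gives the pooled per-stride alternative.
* Compliance = 100 × compliant days / observed days; subjects enter group
  analyses with ≥ 4 valid days; no imputation anywhere (complete-case).

## Validation statistics

**ICC(2,1)** — two-way random effects, absolute agreement, single
measurement:

    ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))

computed from explicit mean squares (subjects n, raters k), with the F-based
confidence interval for this form. An all-equal table is defined as perfect
agreement (estimate 1, degenerate CI) with a warning. Benchmarks: ≤ 0.4 poor,
0.4–0.59 moderate, 0.6–0.74 good, 0.75–1 excellent.

**Paired Wilcoxon signed-rank** — zeros dropped, mid-ranks for ties. For ≤ 12
nonzero pairs the p value is exact, from the null distribution of the rank
sum computed by dynamic programming over doubled (hence integer) ranks —
valid under ties, and verified in the tests against full 2^n enumeration.
Larger samples use the normal approximation with tie and continuity
correction.

**Setting contrast (in-clinic vs at-home)** — the study design names a mixed
model for repeated measurements without specifying a covariance structure.
Here it is realized as a linear mixed model with a subject random intercept
and fixed effects for setting and age group, REML-fitted; repeated at-home
days enter through the random effect. The contrast is in-clinic − at-home
with a Wald 95% CI (Satterthwaite p when `lmerTest` is available). The
natural-walk estimate represents the in-clinic value.

**Age-group ANOVA** — one-way ANOVA on per-subject summaries with all three
pairwise comparisons; the multiplicity adjustment is configurable (default
Tukey HSD, switchable to none/Bonferroni) since the study reports pairwise
significance without naming an adjustment.

**Comfort score** — ten 5-level Likert items mapped to 0–4 with 4 most
favorable; negatively-worded items are reverse-keyed via a configurable
logical vector (the published item-level key lives in supplementary material,
so the key is a configuration input, defaulting to no reversal); the total
spans 0 (worst) to 40 (best). Missing items are an error.

## Problem sizes and determinism

The test suite and acceptance script run everything at sizes chosen to give
stable statistics on a single CPU in minutes: 200 walkway passes for gait
recovery; 100 random tables for the ICC oracle; 1000 replicates at n = 40,
k = 2 for ICC recovery; 300–500 replicates for mixed-model coverage; 1000/500
simulations for ANOVA size/power; 14 simulated days at 8 Hz for compliance
bookkeeping (wear-time analysis needs only the count band, so the reduced
rate changes nothing). Free-living fixtures with gait use 32 Hz — above the
20 Hz floor of the event detector — while walkway analyses use the device's
native 64 Hz. Every simulation consumes a private seeded RNG stream and
restores global RNG state; identical configurations are bit-reproducible.

## Known limitations

* Spatial gait metrics inherit the inverted-pendulum assumptions: smooth
  CoM motion and a height-proportional pendulum; real pediatric gait (and
  the generator's own impulse artifact) bias h upward by a few percent.
* The bout classifier and the intensity cut-points are calibrated to this
  generator; transferring either to real recordings requires retraining and
  recalibration.
* Double-support durations are internally consistent but not validated
  against planted truth (the generator does not plant distinguishable FC
  physics).
* Foot laterality is relative; no absolute left/right claim is possible from
  a single lumbar sensor.
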