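---
title: "Motion sharing biomarkers and their investigator repeatability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion sharing biomarkers and their investigator repeatability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineshare)
```

## The measurement problem

Quantitative fluoroscopy (QF) images the lumbar spine continuously while a
motorised table passively flexes the recumbent trunk, and tracks each
vertebral body through the image sequence.  From the per-frame
intervertebral rotations of the four levels L2-L3 to L5-S1 two composite
biomarkers are derived:

* **MSI** (Motion Sharing Inequality): how unequally the four levels share
  the gross L2-S1 rotation, averaged over the bend — an index of uneven
  passive restraint;
* **MSV** (Motion Sharing Variability): how much that sharing pattern
  fluctuates during the bend — an index of uneven motion control.

Both biomarkers require investigator input (manual first-image
registration seeding the automated tracking), so their usefulness depends
on how much of their variance is investigator-induced.  This package
implements the full analytic chain — protocol simulation, optional image
rendering and template tracking, biomarker computation, and the
intra-/inter-investigator repeatability statistics — so that every stage
can be exercised and validated on synthetic data with known ground truth.

## The model, stage by stage

### Table kinematics

The motorised table profile is trapezoidal in velocity: angular
acceleration $a$ (default 6°/s²) for $v/a$ seconds, constant velocity $v$
(default 6°/s) until the gross flexion excursion reaches $G_{max}$
(default 40°), mirrored deceleration, and an optional time-reversed
return.  Sampling is at the frame rate (default 15 Hz), giving 116 outward
frames and 231 frames in total under the defaults.  The profile is
piecewise $C^1$, peaks exactly at $G_{max}$, and the return half mirrors
the outward half.

### Subject kinematics (synthetic ground truth)

A subject is a *sharing profile*: per-level shares $s_l(t)$ of the gross
angle, constructed as base shares plus a slow sinusoidal drift (one cycle
per outward phase by default, random phase per level), re-centred each
frame so $\sum_l s_l(t) = 1$ exactly.  Measured level angles are
$s_l(t)\,G(t) + \varepsilon$, with $\varepsilon \sim N(0, 0.52^2)$ degrees
by default — the instrument precision limit of the QF system.  Noise is
applied to the level angles (the measured quantities), not to the gross
table angle.

No published model of within-subject share dynamics exists for healthy
controls; the sinusoidal drift is this package's own choice.  It is the
simplest smooth model that produces a controllable non-zero MSV ground
truth, and its amplitude is a free parameter, not an estimate.

### Cohorts and calibration

`generate_cohort()` draws per-subject target share ranges from
$N(0.24, 0.09^2)$ and drift amplitudes from $N(0.04, 0.015^2)$ (floored
away from zero).  These defaults are calibrated to the published
healthy-control group scale — MSI mean 0.24, SD 0.09; MSV mean ≈ 0.07 —
and were fixed once, before the test expectations were frozen.  Because
the drift itself widens the instantaneous share range, calibration is done
exactly with a two-pass trick: share trajectories are affine about the
equal-share point 0.25, so rescaling the base spread and drift amplitude
by a common factor rescales the true per-frame range exactly; the second
pass pins each subject's true mean range (the MSI ground truth) at its
target.

What the generator deliberately does *not* emulate: radiographic
appearance (bone texture, scatter, exposure drift), anatomical shape
variation, out-of-plane motion, and trial-to-trial repositioning of the
subject.  A green closed-loop test therefore establishes that the
*analysis chain* is correct and self-consistent at realistic noise levels,
not that the tracker would perform identically on clinical images.

### Rendering and tracking

`render_frames()` draws the five vertebral bodies as soft-edged convex
quadrilaterals (signed-distance rasterisation, linear edge profile over
about 3 px) and moves them through a kinematic chain: each vertebra and
everything cranial to it rotates about the disc centre below it by that
level's angle, with the sacrum fixed.  Inter-body angles therefore equal
the simulated level angles exactly, and the ground-truth pose table closes
the loop for validation.

`track_sequence()` emulates the QF software: first-image registration
(nominal corners perturbed per repeat by isotropic Gaussian noise and
averaged over the default 5 repeats), then frame-to-frame maximisation of
the normalized cross-correlation (NCC) over a rigid pose grid seeded at
the previous frame's pose (coarse ±10 px / ±3°, then a fine grid with
parabolic sub-pixel/sub-degree refinement).  NCC was chosen because it is
invariant to the linear intensity changes typical of fluoroscopy.  Ties
break toward the smallest pose change from the previous frame.  A frame
whose peak NCC falls below 0.5 is flagged as a failure, holds the last
good pose as the seed, and can be re-tracked with a widened window
(`retrack_failures()`); residual flags make angle extraction refuse the
sequence, mirroring the visual verify-and-retrack step of the original
protocol.  How the original software combined the five registrations is
not documented; averaging the corners is this package's choice, and a
single-placement mode (`n_repeats = 1`) is available.

On noise-free default-protocol frames the closed loop (render → track →
extract) recovers the intervertebral angle series with RMS error around
0.24°, inside the 0.52° instrument precision limit, and reproduces the
ground-truth MSI to better than 0.01.

### Biomarkers

For each retained frame $i$, proportional contributions are
$p_l(i) = \theta_l(i) / G(i)$ (signs preserved), their range is
$fRC_i = \max_l p_l(i) - \min_l p_l(i)$, and

$$\mathrm{MSI} = \frac{1}{N}\sum_{i=1}^{N} fRC_i, \qquad
  \mathrm{MSV} = \sqrt{\frac{1}{N}\sum_{i=1}^{N} (fRC_i - \mathrm{MSI})^2}.$$

MSV uses the population denominator $N$, exactly as the defining equation
is printed; a sample-SD variant (`denominator = "sample"`) is exposed but
non-default.

**The middle-80% trim.**  Early and late in the bend the angle changes sit
near the precision limit and the proportional scaling divides two small
noisy numbers.  Only the middle 80% of movement is analysed.  The original
description does not say whether the trim was on amplitude, time or table
angle; this package trims on *gross-angle amplitude* — frames with
$G(i) \in [0.1, 0.9]\,G_{max}$, i.e. [4°, 36°] under the defaults —
because the stated rationale (error amplification from small
denominators) is an amplitude phenomenon.  A time-based trim is available
(`trim = "time"`).  Both outward and return phases are analysed by
default (the published derivation spans flexion and return);
`phases = "outward"` restricts the analysis.

### Repeatability statistics

Readings form a complete subjects × raters matrix per biomarker.  With
two-way ANOVA mean squares $MS_S$ (subjects), $MS_R$ (raters), $MS_E$
(residual), $n$ subjects and $k$ raters, the single-measures two-way
random-effects ICC in its **absolute agreement** form is

$$\mathrm{ICC}(2,1) = \frac{MS_S - MS_E}
  {MS_S + (k-1)MS_E + \tfrac{k}{n}(MS_R - MS_E)},$$

with the F-based 95% CI of McGraw & Wong (Satterthwaite degrees of
freedom).  The source protocol says only "single measures, two-way
random-effects"; the agreement form is the default here because SEM and MD
are agreement statistics, and the consistency form is exposed as an
option.  Further statistics:

* $\mathrm{SEM} = \sqrt{MS_E}$ (default), or the classical
  $SD_{pooled}\sqrt{1-\mathrm{ICC}}$ with the pooled SD of all $n k$
  readings about the grand mean (`method = "sd_icc"`; which pooled SD the
  original analysis used is unstated);
* $\mathrm{MD} = \mathrm{SEM} \times 1.96 \times \sqrt{2}$;
* qualitative bands with inclusive upper edges: slight (0.11–0.40), fair
  (0.41–0.60), moderate (0.61–0.80), substantial (0.81–1.00); estimates
  below 0.11 — including negative ICCs, which are reported as computed,
  not floored — are "below-slight".

A constant observation matrix has no defined ICC; the result carries an
`undefined` flag rather than erroring, so batch analyses degrade
gracefully.  Reported tables round ICC to 2 and SEM/MD to 3 decimals,
matching the precision conventions of the field.

## Numerical choices and degenerate inputs

* All stochastic operations take an explicit seed and restore the
  caller's RNG state; nothing depends on global RNG.
* Table profiles whose ramps exceed the excursion are rejected; the
  boundary case (zero-length plateau) is valid.
* Trim failures (zero gross range, fewer than 2 retained frames) and
  division by a zero gross angle on a retained frame are explicit errors.
* Tracking tie-breaks prefer the smallest pose change; parabolic
  refinement is clamped to one grid step and skipped at grid borders or
  non-concave neighbourhoods.
* The NCC returns 0 (not NaN) on flat patches, which is what makes
  occlusion collapse to a failure flag.

## What the tests establish

The test suite validates each stage against independent oracles: a
numerically integrated velocity profile for the table kinematics;
definition-level (loop-based) ANOVA sums of squares and MSI/MSV
computations; ICC and CI values frozen from an independent reference
implementation; Monte-Carlo recovery of generating variance components,
SEM, and CI coverage; and the render→track→extract closed loop against
simulation ground truth.  Simulation-based checks in the default test run
are scaled to seconds (smaller cohorts, coarser frame rates); the
full-protocol closed loop runs once, in the acceptance tests.

## Known limitations

* The synthetic images are far cleaner than clinical fluoroscopy;
  tracking accuracy here is an upper bound, not a clinical estimate.
* Drift amplitudes (hence MSV ground truth) are free parameters of the
  simulation, not population estimates.
* Out-of-plane motion, image distortion and edge-enhancement choices are
  out of scope; an optional unsharp-mask step was considered and dropped
  because the synthetic frames do not need it.
* Per-level biomarker variants (e.g. single-level proportional-motion
  variability) are not implemented.
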