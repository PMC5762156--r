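---
title: "Methods: evoked-response, CSD, kinematic and behavioral quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-response, CSD, kinematic and behavioral quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokelab)
```

## Scope and model of the data

strokelab quantifies a family of measurements used to study
interhemispheric connectivity and motor recovery after focal cortical
stroke in mice. One hemisphere's forelimb motor cortex is stimulated
optogenetically; a 16-channel laminar probe in the homotopic area of the
other hemisphere records the evoked field potential (FP). The FP has two
components with distinct physiology: an early **negative** wave
(direct transcallosal excitation, peaking 17–26 ms after the stimulus)
and a late **positive** wave (local GABA-B-mediated inhibition recruited
by the callosal volley, peaking 40–60 ms). Stroke shifts the balance of
these components — weaker direct excitation, stronger inhibition — and
strengthens paired-pulse depression; rehabilitation partially normalizes
them. The motor side of such a study scores skilled reaching, a
forelimb-retraction robot, and classical Gridwalk/cylinder tests.

The package implements the measurement rules for all of these, plus
seeded phenomenological generators that produce inputs with known ground
truth for every stage. Nothing in the generators attempts biophysics;
they exist so that every estimator can be validated against injected
values.

## Evoked-response measurement

`epoch_and_average()` cuts a window (default −50 to +200 ms) around each
stimulus and returns the across-trial mean and SEM. Trials whose window
would leave the record are dropped with a warning; an epoch with no
usable trials is an error.

`measure_fp_components()` implements baseline-to-peak scoring:

* baseline = mean over [−50, 0) ms. The baseline window and statistic
  are a package choice; only "baseline-to-peak" is dictated by the
  measurement convention.
* negative amplitude = baseline − minimum over the **negative search
  window** [5, 35] ms; positive amplitude = maximum over [35, 80] ms −
  baseline. Both are clamped at zero (a component that does not deflect
  past baseline scores 0) and both windows are configurable; the
  defaults bracket the expected 17–26 ms and 40–60 ms peak latencies
  with margin for diseased or drugged responses.
* latencies are reported at the extremum samples.

`paired_pulse_ratio()` measures A1 and A2 **peak-trough** (window
maximum minus window minimum) in windows [5, ISI) ms after pulse 1 and
[5, min(ISI, 80)] ms after pulse 2. Peak-trough for A2 is required
because the second response rides on the tail of the first (the altered
baseline); we apply the same rule to A1 for symmetry, with a
`baseline_to_peak` mode for A1 available. Channels whose A1 does not
exceed 3 baseline SDs (configurable) are flagged unreliable and given a
missing ratio rather than an unstable quotient.

`pool_layers()` averages per-channel values into four contiguous groups
(Sup, Sup/Middle, Middle/Deep, Deep — 4 channels each on a 16-channel
probe). The exact layer boundaries under a probe vary with insertion
depth, so the partition is an argument, not a constant.

`build_io_curve()` summarizes responses over increasing light power by
the deep-pool negative amplitude and defines saturation as the first
intensity reaching 95% of the maximum observed amplitude. The 95%
criterion is a package choice for "reaching the plateau"; it is exposed
as an argument.

`irradiance()` is the linear fiber calibration `power × max_irradiance /
max_power`, with defaults for a fiber emitting 79.55 mW/mm² at its
10 mW maximum.

## Current source density

`compute_csd()` offers two estimators.

The **step method** models the CSD as constant within slabs of thickness
*h* (the electrode spacing) centred on each contact, extending over a
disc of radius *R*. The potential at contact depth $z_j$ produced by a
unit CSD in slab $i$ is

$$F_{ji} = \frac{1}{2\sigma}\int_{z_i - h/2}^{z_i + h/2}
  \left(\sqrt{R^2 + (z_j - z')^2} - |z_j - z'|\right)\,dz',$$

which we evaluate in closed form. The CSD estimate is $F^{-1}\phi$ per
time sample. Defaults: conductivity $\sigma = 0.3$ S/m (a standard value
for cortical gray matter) and $R = 500$ µm; both are arguments because
they are rig- and tissue-dependent.

The **second-difference** estimator is
$-\sigma\,(V_{i+1} - 2V_i + V_{i-1})/h^2$ with Vaknin end-channel
duplication so the edge channels get estimates.

Both outputs are sign-inverted so **sinks are positive**, matching the
plotting convention in which warm colors mark sinks. The two estimators
must agree on the depth of the dominant sink for smooth potentials;
this is enforced in the test suite.

## Multi-unit activity

`compute_mua()` band-passes into the spiking band (default
300–10,000 Hz, Butterworth order 3) with `signal::filtfilt`, i.e.
zero-phase forward-backward filtering — a hard contract here, because a
causal filter would shift MUA latencies relative to the FP. "RMS" is
implemented as a centred sliding-window RMS (default 1 ms), computed
per trial and then averaged: rectifying before averaging preserves
spiking power that would cancel in a trial-averaged raw trace. The
optional normalization divides each channel by its maximum in the
first-response window (default [0, 80] ms), which makes laminar profiles
comparable across channels with different unit yields. A band whose
upper edge exceeds Nyquist is an error naming the violation; an edge
exactly at Nyquist degrades to a high-pass.

## Reaching kinematics

`track_paw()` reproduces color-contrast tracking of a green-painted paw:
a pixel belongs to the paw mask when its green dominance
`G − max(R, B)` exceeds a threshold (default 50 on the 8-bit scale); the
paw position is the centroid of the largest connected component
(labelled with `EBImage::bwlabel`); empty-mask frames are linearly
interpolated and flagged, and a trial with more than 25% empty frames
is rejected with a classed error.

`speed_profile()` uses central differences and a 5-sample moving
average (at 120 fps ≈ 40 ms), chosen for noise robustness and exposed
as an argument. `kinematic_metrics()` computes:

* **ArcLen** — summed segment lengths of the whole reach-and-retract
  path (reach and retract together, not reach only);
* **AUC** — absolute shoelace area of the polygon formed by the path
  closed with the endpoint-to-startpoint chord (the closure rule is a
  package choice; for a loop that returns to its start the chord is
  degenerate and harmless);
* **Mean Speed** — mean of the tangential speed profile;
* **Smoothness** — the number of local speed maxima with topographic
  prominence at least 10% of the peak speed. A plain local-maximum
  count is hostage to sampling noise; the prominence floor (exposed as
  `peak_prominence_frac`) makes the count stable while preserving the
  submovement interpretation (more peaks = more corrective
  submovements = less smooth). The peak finder is implemented in the
  package because the metric's definition *is* the prominence rule.

Only correct (pellet-retrieved) trials should enter group analyses;
trajectories carry an `outcome` attribute for this. `baseline_normalize()`
subtracts each animal's mean over baseline sessions, per metric.

## Robotic platform

`platform_metrics()` scores a force/position trace of one retraction
trial: **attempts** are force peaks above a noise floor (default
0.05 N, well under the 0.2 N static friction) with prominence at least
the noise floor — so jitter riding on a peak is not double-counted —
during which the handle moves at most 0.5 mm within ±100 ms;
**t-target** is the time from trial start until the handle position
first returns within 0.5 mm of zero (full 10 mm retraction). The noise
floor, position tolerance and coincidence window are unstated in any
convention we know of and are therefore arguments with the defaults
above. If retraction never completes, t-target is missing but attempts
are still reported.

## Behavioral scores, lesion volume, power

Foot-fault percentage is `100 × faults / (faults + correct)` per limb.
The cylinder asymmetry index is `(unimpaired − impaired) /
(unimpaired + impaired)`: the normalized-difference form, with positive
values meaning preference for the unimpaired limb. The underlying
formula is conventional but its sign is not; ours is documented here
and in the function. Reaching errors are `100 × incorrect / total
attempts`. Lesion volume multiplies the summed damaged areas of every
sixth 50-µm section by the thickness and the spacing factor 6.

`ttest_power()` computes exact two-sample t-test power from the
noncentral t distribution with $df = 2n - 2$ and noncentrality
$d\sqrt{n/2}$. The default is **one-tailed**: a rehabilitation design
states a directional hypothesis (treatment improves outcome), and at
$d = 1.75$, $n = 5$, $\alpha = 0.05$ the one-tailed power is 0.810
(two-tailed would be 0.680). Both modes are available. The test suite
cross-checks the analytic value against a 100,000-replicate Monte-Carlo
simulation.

## The synthetic generators

`gen_evoked_lfp()` builds each evoked response from two raised-cosine
(Hann) bumps: a negative lobe (half-width 8 ms, latency drawn uniformly
in 18–25 ms and snapped to the sample grid) and a positive lobe
(half-width 10 ms, latency in 42–48 ms). Hann bumps were chosen over
Gaussians deliberately: their compact support means the two lobes cannot
perturb each other's extrema, so on noiseless data the measured
amplitudes and latencies equal the injected values *exactly*, which
turns recovery tests into sharp oracles. The positive-lobe latency range
sits inside the nominal 40–60 ms window but below 50 ms so that both
responses of a 50 ms paired-pulse protocol are fully contained in their
measurement windows and the injected depression ratio is recovered
exactly. Amplitudes follow a smooth unimodal depth profile peaking in
the deep (infragranular) quarter of the probe, scaled per condition:

| condition   | neg scale | pos scale | PPD ratio |
|-------------|-----------|-----------|-----------|
| sham        | 1.00      | 1.00      | 0.80      |
| stroke5d    | 0.35      | 1.20      | 0.70      |
| stroke30d   | 0.60      | 1.70      | 0.55      |
| robot_bont  | 0.65      | 1.05      | 0.78      |

These scalings encode only the **direction** of the reported group
effects (early negative dampened after stroke and only partly recovered
by treatment; late positive enhanced at 30 days and normalized by
combined rehabilitation; PPR lowered by stroke and rescued by
treatment); no numeric group amplitudes are published to calibrate
magnitudes against, and we make no claim that the magnitudes are
realistic. Protocol constants are the study's: 15 repetitions spaced
5 s, single pulses or pairs at ISI 50/100/200 ms.

Synthesis runs at 1 kHz (ample for LFP-band content); at sampling rates
of 20 kHz or more the generator additionally embeds biphasic ~1 ms spike
transients at Poisson times whose rate is a Hann bump co-timed with the
negative lobe (baseline 20 Hz, burst peak 600 Hz × depth profile), giving
the MUA estimator a known rate profile to recover. Noise is additive
white Gaussian; real recordings have structured (1/f, line, movement)
noise, so noisy-recovery tests here certify estimator correctness, not
field robustness.

`gen_reach_trajectory()` drives a point around a smooth elliptical loop
(out along the upper arc to the pellet at `path_extent`, back along the
lower arc; semi-minor axis 0.35 × extent). An ellipse rather than an
out-and-back line is essential: at a path corner the centrally
differenced tangential speed collapses to zero, which would split one
injected speed bell into two measured peaks. The speed profile is a sum
of `n_submovements` separated Gaussian bells (centres evenly spaced,
SD = duration/(8n)). The configuration is over-determined (duration,
bell peak, extent cannot all hold simultaneously), so the geometry and
duration are honoured exactly and the bell amplitudes are uniformly
rescaled so the integrated speed equals the loop length; the achieved
peak speed is reported in the ground truth. Frame rate defaults to the
study's 120 fps.

`gen_platform_trial()` places sub-threshold attempt bumps 1 s apart,
then a supra-threshold pull with a linear 1 s retraction ramp, plus
sub-noise-floor force jitter. `gen_behavior_counts()` samples binomial
tallies at specified rates. All generators take explicit seeds, use one
RNG stream per call (restoring global RNG state afterwards), and are
bit-reproducible; every output carries the injected values needed to
score recovery without re-derivation.

## Pipeline

`run_pipeline()` runs a configured multi-group study end to end:
generation, FP/PPR analysis with layer pooling, kinematics, platform and
behavioral scoring, tidy per-subject CSVs, mean ± SEM group summaries
(`summarize_groups()`; single-value groups get SEM 0 and a flag so
tables stay rectangular) and a JSON manifest of seeds and versions.
Inferential statistics (ANOVA, post-hoc tests) are deliberately out of
scope: they are routine and better done in the user's stats environment
on the tidy tables; the package stops at descriptive summaries.

## Problem sizes and numerical choices

The validation suite exercises: noiseless single-subject recordings for
exactness oracles (tolerance 10⁻⁶ mV, met with error 0 up to float
rounding); 100 seeded repetitions at component SNR 10 with 15 trials for
noisy amplitude recovery (deep-pool amplitude within 5% of injected);
paired-pulse depressions {1.0, 0.8, 0.6, 0.4} for exact and noisy ratio
recovery and strict monotonicity; 10 subjects per group for the
direction contrasts (one-sided Welch tests); 16-channel forward-model
round trips (relative error < 10⁻⁸ required, ~10⁻¹⁵ achieved); MUA
validation at 25 kHz with 10 trials spaced 0.6 s to keep memory modest;
and reach trajectories at 120 and 240 fps for discretization bounds.

Degenerate inputs are errors, not guesses: trajectories with fewer than
two distinct points, empty partitions, bands beyond Nyquist, singular
forward matrices, windows outside the epoch, zero usable trials.
Ties in extremum searches resolve to the earliest sample (`which.min`
/ `which.max` semantics), which makes latencies deterministic.

## Known limitations

* All generators are phenomenological; none model cortical biophysics,
  volume conduction beyond the step-method geometry, or realistic noise
  spectra. Passing recovery tests shows the estimators are correct, not
  that they are robust to every artifact of in-vivo data.
* Condition presets are direction-only; absolute effect magnitudes in
  synthetic cohorts are not calibrated to any dataset.
* The paw tracker assumes a single dye-marked paw and a static
  background; it does not handle occlusion beyond frame interpolation,
  and is not a substitute for markerless pose estimation.
* CSD parameters ($\sigma$, $R$) affect amplitudes; depth localization
  of sinks is the robust output.
* Layer-pool boundaries are nominal quarters of the probe, not
  histologically verified laminae.
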