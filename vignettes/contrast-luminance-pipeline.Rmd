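---
title: "Quantifying contrast and luminance encoding in lamina neurons and walking flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contrast and luminance encoding in lamina neurons and walking flies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumicon)
```

## The scientific problem

Photoreceptors report light; downstream circuits need two different things
from that report. Rapid *contrast* — the fractional change of intensity at an
edge or a luminance step — drives motion vision and must be read out within
tens of milliseconds. Background *luminance* varies over five orders of
magnitude between shade and sunlight, and circuits need it to correct
("gain-modulate") their contrast responses so that behavior stays stable when
illumination changes faster than photoreceptors adapt. In the fly lamina, the
large monopolar cells divide this work: L2 is essentially a contrast
transient channel, while L1 and L3 additionally (L3 predominantly) carry
sustained luminance signals, L3 with a strong emphasis on the dimmest range.

`lumicon` implements the measurement side of this story: the calibrated
stimulus protocols, the calcium-imaging quantification, the trackball
behavior quantification, and the bespoke statistics that summarize how much
luminance information a cell carries and how behavior scales with luminance.
Because live recordings are not part of the package, a synthetic-data module
generates model-neuron and model-fly data with known ground truth; it is
first-class, tested code, and every claim the test suite makes is a claim
about pipeline correctness on that ground truth — not about biology.

## Stimulus model

All protocols are containers of *epochs* (static pattern, edge motion,
flash, step, inter-trial interval) with photon-flux luminances, plus an
explicit presentation order. Conventions:

* **Photometry.** The LED arena shows 16 linearly spaced intensity levels;
  requested level fractions are snapped to `k/15`, which moves any fraction
  by at most half a level (1/30). The cd/m² → photons·s⁻¹·photoreceptor⁻¹
  transform is linear, anchored at the measured pair (51.34 cd/m² ↔
  11.77×10⁵ photons·s⁻¹·receptor⁻¹). The neutral-density attenuation
  defaults to the *measured* value 14.71×10⁴ / 11.77×10⁵ ≈ 1/8.0 rather than
  the nominal 10^−0.9 ≈ 1/7.94, because the measured value reproduces the
  published photon-flux tables exactly; `Calibration(nominalNd = TRUE)`
  selects the nominal factor.
* **Timing.** Time is continuous seconds from protocol start; epoch
  intervals are half-open `[t_start, t_end)`. Edge trials are 500 ms static
  pattern, 750 ms motion at 160 °/s, then the inter-trial interval (1 s for
  the arena sets, 4 s darkness for the imaging edge set). Four edges cover
  48° each on the 192° arena; a traversal therefore lasts 300 ms, and the
  pattern resets after each traversal so motion fills the whole window.
  `rfLuminance()` treats each reset as an independent crossing: background
  luminance until the edge reaches the azimuth (distance/speed), edge
  luminance until the reset.
* **Mirroring and randomization.** Motion epochs are interleaved in
  randomized order with both directions appearing equally often
  (`nTrials` must be even). All builders are pure functions of their
  arguments and seed.
* **Staircase OFF-step contrast.** The contrast axis of staircase step
  responses is Weber contrast relative to the preceding epoch; this is a
  package convention (the alternative, Michelson, is available through the
  contrast functions directly).
* **A/B steps.** The seven A levels are an explicit package choice
  (`{0.70, 0.55, 0.42, 0.32, 0.24, 0.17, 0.12}` of I_max, decreasing from
  the bright adapting background); only their ordering and the fixed −25 %
  Weber B step matter to the analyses.

## The synthetic neurons

`simulateLmc()` generates the raw fluorescence of
`polarity · (w_c · T(t) + w_l · S(t))` convolved with a normalized
exponential calcium kernel (τ_ca = 0.3 s — the simplest kernel with a
realistic slow decay; indicator kinetics are out of scope), embedded in an
arbitrary baseline with additive white noise.

* **Transient term** `T(t)`: exponentially decaying impulses (τ_t = 0.25 s)
  at every luminance transition, amplitude equal to the signed Weber
  contrast of the transition. Two numerical guards make this well-defined:
  the denominator has a dark-adaptation floor (`max(I_prev, 0.05·I_max)`,
  since a step out of total darkness has unbounded Weber contrast), and
  amplitudes saturate as `4·tanh(C_W/4)` — near-linear over the contrasts
  the protocols use, compressive for the extreme dark-to-bright steps, as
  real lamina transients are. Strictly linear amplitudes are available with
  `satContrast = NULL`.
* **Sustained term** `S(t) = 1 − (1 − I/I_max)^γ`, increasing in luminance,
  with γ = 1 giving linear tuning and γ > 1 amplifying differences among
  dim levels. With the lamina polarity (−1, hyperpolarizing to light) the
  trace is largest in darkness and correlates negatively with luminance —
  which is what the Spearman polarity filter expects, and what makes the
  dim-amplifying L3 phenotype ("responds most strongly to the darkest
  stimulus") come out of the model.
* **Presets** (qualitative, *not* measured quantities): L1 `w_c = 1,
  w_l = 0.8, γ = 1`; L2 `w_c = 1.2, w_l = 0`; L3 `w_c = 0.3, w_l = 1,
  γ = 3`. A fraction `pOffscreen = 0.1` of ROIs is generated with inverted
  polarity, emulating terminals whose receptive fields fall outside the
  stimulation screen. Mild lognormal fly- and ROI-level gain variability
  (sd 0.1) makes hierarchical averaging non-trivial.

What the generator deliberately does **not** emulate: photoreceptor
biophysics, spatial receptive-field structure beyond a point azimuth,
photon-shot noise, bleaching, or neuropil contamination. Passing tests
therefore show that the *pipeline* recovers what the model put in; they do
not show that real recordings satisfy the model.

## The synthetic flies

`simulateTurning()` makes each trial's yaw trace a half-sine bump scaled by
`amplitude · tanh(2·|C_M|)/tanh(2) · (I_edge/I_max)^β`, in the stimulus
direction, plus a per-fly direction-independent bias and smoothed trial
noise (sd 0.3 rad/s, 200 ms correlation time — white noise would bias the
peak statistic upward unrealistically). The bump lasts 600 ms and peaks
300 ms after motion onset, inside the 750 ms motion window; only the peak
matters downstream. Genotype presets set β: control −0.05 (near-invariant,
slightly larger turns to dim edges), no-luminance-gain 0, and
dim-underestimating +0.25 (turning positively correlated with luminance, the
phenotype of flies lacking the luminance-encoding inputs). Baseline forward
speed is drawn per fly with a fraction `pSlow = 0.25` below the 2 mm/s
rejection threshold, matching the ~25 % rejection rate typical of such
experiments. The trackball forward model (`composeBallSensors()`) and the
analyzer (`velocitiesFromSensors()`) share one linear sensor-geometry map,
so the decomposition is exactly invertible — the cited rig's calibration is
not public, and a self-consistent, testable geometry was preferred over an
approximation of it.

## Imaging pipeline choices

* **Registration** uses integer shifts within ±10 px maximizing normalized
  cross-correlation against the max-intensity projection of the first 30
  frames. This intentionally replaces the HMM-based motion correction used
  in the original analysis chain (a third-party tool) with a simpler,
  exactly testable method. Candidate shifts are scanned small-to-large, so
  ties resolve to the smallest motion; frames of pure noise (zero-variance
  overlaps) fall back to zero shift. Exact recovery of planted shifts
  requires the anatomy (resting fluorescence of the labeled structures) to
  dominate the activity modulation, which the movie generator guarantees by
  default (`anatomyGain = 5`).
* **ΔF/F₀** uses the whole-trace mean as F₀, or the mean of the 30 s
  adaptation window for the A/B protocol. F₀ = 0 is an error, not a NaN.
* **Trial averaging** interpolates linearly onto an epoch-onset-aligned
  10 Hz grid and averages presentations of the same epoch label. "Last 2 s"
  and "last 500 ms" windows are closed on the left, open at the epoch end,
  and evaluated on that grid. The interpolation method and window boundary
  conventions are explicit package choices; the source conventions are
  unstated.
* **Polarity filter**: an ROI is kept iff Spearman ρ between its ΔF/F and
  the frame-wise stimulus luminance is strictly negative; ρ = 0 and
  undefined ρ (constant traces) are rejected and flagged. The frame-wise
  (rather than per-epoch) luminance series is used; for edge epochs it is
  the screen-mean luminance ramp.
* **Normalization** for cross-cell-type step-response comparison is min–max
  (0–1) of each ROI's averaged session trace, applied before step
  extraction. Normalizing per ROI (rather than per cell type) keeps the
  operation well-defined for arbitrary ROI sets; it is monotone-equivalent
  for the comparisons made here.

## Encoding statistics

* **Sigmoid fit** `f(x) = a·(1/(1+e^{kx}) − 0.5)` is implemented exactly as
  printed; `f(0) = 0` for all parameters, and responses that increase with
  contrast get `k < 0`, so steepness comparisons use |k|. For fixed `k` the
  model is linear in `a`, so `a` is profiled out and a 1-D BFGS runs from
  multi-starts k ∈ {±1, ±5, ±20} (no initialization is stated in the source
  conventions; this one is robust on every shape the pipeline produces).
  The model is invariant under `(a, k) → (−a, −k)`; fits are canonicalized
  to `a ≥ 0`, which makes bootstrap distributions unimodal. All-zero
  responses return `a = 0` with `k` flagged unidentifiable. The bootstrap
  resamples units (flies or ROIs) with replacement, 50 times by convention.
* **Mutual information** is the plug-in discrete estimator on the level ×
  binned-response table, with equal-occupancy bins (as many as levels by
  default) — the cited estimator's exact configuration is not reproduced in
  the source conventions, so the estimator is pluggable and a shuffle-based
  bias correction (mean MI over label permutations, clamped at 0) is
  provided. Plug-in MI is biased upward at small sample counts; comparisons
  across cell types at equal n are unaffected, which is how the package
  uses it.
* **Non-linearity index** = Pearson r − Spearman ρ: exactly 0 for strictly
  linear monotone relations, nonzero for curved monotone ones, bounded in
  [−2, 2]; constant inputs are an error.
* **Log-luminance slopes** use the natural log (the base only rescales the
  slope and is recorded in the fit's metadata).

## Behavioral statistics

Peak velocity is `max(yaw − baseline)` over the motion window shifted by a
100 ms response delay, with the baseline the mean over the last 200 ms of
the preceding inter-trial interval; it is invariant to adding a constant to
the whole trace. Mirror aggregation negates leftward trials before
averaging, cancelling direction-independent bias exactly when trial counts
balance. The 2 mm/s rejection rule is strict (`< 2` discarded, exactly 2.0
kept). Rescue efficiency is invariant under common affine transforms of all
three groups. The permutation test shuffles fly labels between the two
rescue groups (1000 draws), uses the add-one two-tailed p-value
`(b+1)/(n+1)` to avoid zero p at finite n, and applies Bonferroni over
luminances. Group comparisons route to t-tests only when *all* groups pass
the Lilliefors test at p > 0.05 (the routing rule is ambiguous in the
source conventions between per-group and joint; the conservative joint rule
is used and recorded in the output), and the comparison family for
Holm–Bonferroni is the per-panel family (experimental vs each control),
configurable by calling the test functions directly.

## Problem sizes and calibration checks

The test suite and acceptance script run everything at desk scale, chosen
to keep the full battery fast while leaving the statistics meaningful:
synthetic cohorts of 5 flies × 8 ROIs on a 300 s flash session, 10–12 flies
with 10–20 trials per epoch for behavior, 200 null replicates × 1000
permutations for the permutation-test calibration, 500 replicates for the
ANOVA calibration, and 20 seeded replicate experiments for the qualitative
pattern battery (MI ordering L1, L3 > L2; |NLI| ordering L3 > L1; turning
slope signs). Parameter-recovery checks demand ≤ 10⁻⁴ relative error on
noiseless data and agreement within 2 SEM across ≥ 10 units on noisy data.

## Known limitations

* The presets are qualitative stand-ins; effect *sizes* from live animals
  are outside what synthetic data can certify.
* The registration is integer-shift translation only — no rotation,
  non-rigid warping, or sub-pixel refinement.
* The point-azimuth receptive field ignores spatial pooling, so edge
  responses sharpen more abruptly than real terminals would.
* The plug-in MI estimate is comparable across conditions at equal n but is
  not an absolute information measure at small n.
* The cd→photons transform is a single anchored linear scale; spectral
  filtering of the light path is folded into the calibration scalar.
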