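# lumicon

Contrast and luminance encoding in fly visual interneurons and behavior.

First-order visual interneurons of the *Drosophila* lamina — the large
monopolar cells L1, L2 and L3 — split what photoreceptors measure into
complementary channels: fast *contrast* transients and sustained *luminance*
signals. `lumicon` re-implements, as a tested and reusable R package, the
complete stimulus-generation and quantification pipeline used to
characterize that split in two-photon calcium imaging and in trackball
optomotor behavior, together with a synthetic-data module (model neurons and
model walking flies with known ground truth) so that every stage of the
pipeline can be exercised and validated without any recordings.

It is aimed at labs analyzing LED-arena / projector visual stimulation
experiments: calcium imaging of visual neurons (ΔF/F₀ ROI traces) and
tethered-walking trackball behavior.

## What the package computes

**Stimuli** (photometrically calibrated, 16-level LED arenas and projector
rigs):

- Michelson contrast `C_M = (I_edge − I_bg) / (I_edge + I_bg)` and Weber
  contrast `C_W = (I_B − I_A) / I_A`, with cd/m² → photons·s⁻¹·receptor⁻¹
  conversion anchored to a measured calibration pair.
- Moving-edge protocols (100 %-contrast ON edges over five luminances, OFF
  edges over five backgrounds, a seven-step mixed-contrast set), the
  luminance staircase, randomized full-field flashes, and adapted A/B
  contrast steps (every B step at exactly −25 % Weber contrast). All
  builders are pure functions of their arguments and a seed, with
  mirror-symmetric randomized interleaving of motion epochs.

**Imaging analysis**: translation registration of image stacks against a
max-intensity-projection reference, background-subtracted ROI trace
extraction, ΔF/F₀ (whole-trace or adaptation-window F₀), 10 Hz epoch-aligned
trial averaging, Spearman-polarity ROI filtering, and the response metrics —
staircase OFF-step responses, flash plateaus, A/B peaks and sustained
responses, ON-edge response amplitudes.

**Encoding statistics**: the sigmoidal contrast-response fit
`f(x) = a·(1/(1+e^{kx}) − 0.5)` with unit-level bootstrap (50 resamples by
convention), plug-in mutual information between luminance level and response
(equal-occupancy binning, optional shuffle correction), the non-linearity
index (Pearson r − Spearman ρ; zero for strictly linear relations), and
straight-line fits `V = a·log(I) + b`.

**Behavior**: exact inversion of the two-sensor trackball geometry into yaw
and forward velocities, mirror-aggregated mean turning, baseline-referenced
peak velocities (100 ms response delay, 200 ms baseline window), rejection
of flies walking slower than 2 mm/s, per-fly log-luminance slopes, rescue
efficiency `E = (rescue − control⁻)/(control⁺ − control⁻)` and its
1000-permutation significance test with Bonferroni correction.

**Statistics conventions**: hierarchical (ROIs-within-flies) averaging,
normality-routed two-control comparisons (t vs Wilcoxon after Lilliefors,
Holm–Bonferroni corrected, significant only against *both* controls), and
one-way ANOVA with Bonferroni pairwise comparisons.

## Worked example

The end-to-end demo builds the protocols, simulates L1/L2/L3 cohorts and
four behavioral genotypes, and runs both analysis arms:

```r
library(lumicon)
res <- runDemo(list(seed = 1L), outDir = "demo-out")
```

```
[imaging] L1: MI 2.322 bits, NLI 0.000 (7 ROIs rejected)
[imaging] L2: MI 0.494 bits, NLI -0.001 (4 ROIs rejected)
[imaging] L3: MI 2.049 bits, NLI 0.091 (6 ROIs rejected)
[imaging] L1 staircase sigmoid: a = 0.596, k = 3.721 (|k| steepness)
[imaging] L2 staircase sigmoid: a = 0.851, k = 1.180 (|k| steepness)
[behavior] control: slope -0.0418 +/- 0.0269 rad/s per log-unit (20% slow flies rejected)
[behavior] dim: slope 0.1434 +/- 0.0218 rad/s per log-unit (40% slow flies rejected)
[behavior] rescue-efficiency endpoints: positive-like 1.000, negative-like 0.000
```

Reading the numbers: the luminance-sensitive model cells L1 and L3 carry
~2.0–2.3 bits of mutual information about the five flash luminances while
the transient-only L2 carries ~0.5 bits (mostly estimator bias); L3's
non-linearity index is positive (its dim-amplifying luminance tuning is
monotone but curved) while L1's is ~0 (linear tuning). The
luminance-invariant control flies show a near-zero, slightly negative
turning slope against log luminance, whereas the dim-underestimating
genotype turns more for brighter edges (positive slope). Rescue-efficiency
endpoints confirm the statistic's calibration: a rescue matching the
positive control scores 1, one matching the negative control scores 0.
Tables (`plateaus.csv`, `step_responses.csv`, `turn_peaks.csv`), a JSON
summary and a log — each stamped with the configuration hash and seed — are
written to `outDir`.

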