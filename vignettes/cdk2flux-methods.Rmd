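---
title: "Models and methods in cdk2flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cdk2flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdk2flux)
```

# The stress-dip trace model

`cdk2flux` simulates single-cell CDK2 activity — the cytoplasmic:nuclear
ratio of a translocation reporter — as a piecewise-linear baseline minus a
sum of Gaussian suppression dips:

$$\mathrm{CDK2}(t) = \mathrm{CDK2}_{\mathrm{linear}}(t)
  - \sum_{i} \alpha_i \, e^{-(t - t_i)^2 / w}.$$

The baseline is zero in G0/early G1 and rises linearly from the G1 rise
time onward (the model treats the ramp as linear through S and G2). Each
stress event `i` suppresses activity by amplitude $\alpha_i$ around its
center $t_i$; with the default shape constant $w = 0.5\ \mathrm{h}^2$ a dip
has a full width at half-maximal suppression of
$2\sqrt{w \ln 2} \approx 1.18$ h, i.e. roughly one hour. Amplitudes are
identical across events by default ($\alpha_i = \alpha$; a per-event
amplitude spread is available but off). In the default configuration 20
event centers are drawn independently and uniformly over the S-phase
window, which produces the characteristic cluster-like fluctuations:
overlapping dips sum linearly, so runs of nearby events carve deep,
irregular valleys into the ramp.

Key parameters, their defaults and their meaning:

| parameter | default | meaning |
|---|---|---|
| `g0_end` | 5 h | time of the initial CDK2 rise; activity is 0 before it |
| `s_start`, `s_end` | 8, 14 h | S-phase window containing the dips |
| `ramp_slope` | 0.2 h⁻¹ | slope of the linear activity ramp |
| `n_events` | 20 | stress events per S phase (uniform mode) |
| `amplitude` | 0.1 | dip depth α, activity units |
| `dip_shape` | 0.5 h² | Gaussian shape constant (≈ 1 h FWHM) |
| `degron_lag` | 3 h | CDK2 rise → APC/C^Cdh1 inactivation |
| `noise_sd` | 0.02 | additive Gaussian noise on the ratio per frame |
| `frame_interval` | 0.2 h | sampling interval (12 min) |

Design choices that the model statement leaves open, and how we resolved
them:

* **Ramp onset.** Only "zero in G0, linear in S/G2" is specified. We start
  the ramp at a configured G1 rise time, by default 3 h before `s_start`,
  so the rise-to-S-entry lag is an explicit, recoverable parameter.
* **No clipping.** The dip sum is applied unclipped (the formula is an
  unclipped difference); a floor-at-zero flag exists for realism but is
  off by default.
* **Noise on the ratio.** Measurement noise is additive Gaussian on the
  ratio (sd 0.02) rather than on raw intensities, because every
  downstream metric operates on the ratio. The dip amplitude (0.1) and
  the noise level are not published quantities; they were chosen once to
  give fluctuations that visibly ride on the ramp without destroying it,
  and both are exposed in the configuration.
* **Reproducibility.** Cell `i` of a run with root seed `s` uses the
  substream seed `(s + 1000003·i) mod (2³¹−1)`, so populations are
  bit-reproducible under any iteration order.

## Regime presets

Continuously cycling cells and cells released from quiescence
(mitogen starvation) differ in S-phase length, fluctuation frequency, and
stress burden. The presets encode this phenomenology as parameters — they
are emulation targets, not measurements:

* `cycling`: 6-h S phase (8–14 h), ramp slope 0.2 h⁻¹, dips on a jittered
  regular grid of period 2.4 h with amplitude 0.1, γH2AX puncta rate 6.
* `quiescence_release`: 9-h S phase (13–22 h), shallower ramp
  (0.15 h⁻¹), denser (1.6-h spacing) and larger (0.13) dips — roughly
  twice the per-hour suppression burden — and twice the puncta rate (12).

The grid-with-jitter event sampler exists because uniformly timed events
carry no dominant period: the documented anticorrelation lags (1.2 h
cycling, < 1 h quiescence release) are half the dip spacing, so the preset
encodes the spacing and the autocorrelation analysis must recover the lag.
The default (non-preset) configuration keeps the uniform sampler, which is
the model used for fluctuation-generation itself.

## Drug pulse and washout

A `washout_protocol` suppresses activity toward
`(1 − f) ×` the pre-pulse level (the last drug-free frame), where `f` is
the dose-proportional suppression fraction. The pull strength saturates at
tiny doses (`stall_saturation = 0.05`): any appreciable dose both drops
the level and stalls the ramp — stalled forks halt the activity buildup —
while `f = 0` is an exact identity. After washout the deficit relative to
the unperturbed trace decays exponentially with a 40-min half-life. The
washout scenario runs without endogenous dips by design: a strong
exogenous pulse dominates the stress response, and the scenario isolates
the drug kinetics that the recovery estimator must return.

## Synthesis-rate coupling and pulse-chase

`couple_synthesis_rate` ties the relative DNA synthesis rate to the latent
activity: zero outside `[APC inactivation, S end]` and
`max(0, 1 + g·(A(t) − A_{apc}))` inside, a monotone map with gain `g`
(constant rate at `g = 0`). EdU/BrdU intensities integrate this rate over
10-min pulse windows. The pulse-chase noise model makes the dominant
variability (cell size, staining efficiency) a per-cell lognormal factor
shared by both stains, with a small independent per-stain factor on top —
paired same-cell measurements mostly cancel the common factor, which is
what makes per-cell Δrate informative at all.

# Image rendering and quantification

The renderer inverts the measurement model: a nuclear disk per cell, the
reporter at intensity `n` in the nucleus and `r·n` in a cytoplasmic
annulus wide enough (15 µm) that the 2–10 µm measurement ring always lies
inside true cytoplasm; constant background everywhere; Poisson shot noise
plus Gaussian read noise applied last. Pixel size defaults to 0.65 µm.
Cell shape is deliberately not modeled — the ring measurement, not the
cell outline, is what the quantification chain specifies.

Quantification follows the standard chain:

* **Segmentation**: Otsu threshold on the log nuclear channel, hole
  filling, distance-transform watershed declumping, area gating. (The
  upstream description defers to prior work; this is a standard,
  deterministic stand-in adequate for rendered and typical real nuclei.)
* **Background**: median intensity outside all nuclear masks dilated by
  50 µm; per channel.
* **Ring measurement**: nuclear median and the 75th percentile (linear
  interpolation between order statistics — the convention matters for
  small rings) of ring pixels that are strictly positive after background
  subtraction; ratio = ring p75 / nuclear median. Ring offsets and the
  10-µm neighbor exclusion use Euclidean pixel distances; µm-denominated
  structuring elements round to whole pixels.
* **Puncta**: white top-hat with a 4-µm disc. Before filtering, pixels
  outside the nucleus are replaced by the nuclear median so the filter
  responds to intranuclear structure only (otherwise the nucleus/background
  step leaves boundary artifacts). The default absolute threshold is the
  median + 5 × MAD of the filtered nucleoplasm — robust as long as puncta
  occupy a minority of nuclear area. No absolute threshold is published;
  ours is reported in output metadata.
* **Tracking**: greedy globally-nearest centroid linking with a
  20 µm/frame displacement gate; implied jumps beyond the gate terminate
  tracks rather than swapping identities.

# Trace statistics

* **Smoothing**: centered 3-point moving mean, truncated at the ends.
* **QC**: cells in the bottom 5 % of mean total reporter intensity are
  dropped (boundary ties kept); traces with any frame-to-frame ratio jump
  above 0.25 are dropped as noisy.
* **Landmarks**: the callers are defined here because the upstream
  algorithms are external. The CDK2 rise is the first sustained crossing
  of baseline + 0.1 (baseline = 10th percentile of the first 5 h),
  back-extrapolated to the baseline along the local slope so the
  detection delta does not bias the call; APC/C^Cdh1 inactivation is the
  first sustained-increase crossing of 5 % of the degron maximum,
  back-extrapolated to zero signal the same way. On noise-free traces
  both calls are exact; with default noise the recovered rise→inactivation
  lag is unbiased to within ~0.1 h.
* **Fluctuation metrics**: a cubic is least-squares fitted to each trace
  from the alignment event onward; the fit domain ends at the trace end
  or where the fitted curve exceeds the 1.3 activity gate (one
  truncate-and-refit pass) — beyond that gate the reporter's ratio
  readout compresses and measurement noise dominates. The per-timepoint
  squared deviation is the fluctuation score; aligned time axes snap to
  the first frame at/after the alignment event so population aggregation
  is well defined. The independent second-derivative score is the squared
  central second difference scaled by `frame_interval⁻⁴`; its absolute
  scale differs from the polynomial metric, so the two are compared only
  by rank concordance across conditions.
* **Washout metrics**: recovery time is the linearly interpolated first
  crossing of half the pre-addition level. The half-life fit extrapolates
  the pre-pulse linear trend forward, forms the per-frame deficit, and
  regresses log deficit on time over frames from washout until the
  deficit first drops below 15 % of its initial value (at least 4
  frames); deeper frames are dominated by measurement noise and would
  bias the slope.
* **Autocorrelation**: each S-phase segment is cubic-detrended (the ramp
  would otherwise mask the oscillation; whether the upstream analysis
  detrended is unstated, so the choice is recorded in output metadata),
  the per-cell autocorrelation normalized to 1 at lag 0, and the profiles
  averaged; the anticorrelation lag is the profile minimum in
  `(0, max_lag]`. Cells with segments shorter than `max_lag + 1` h are
  skipped — per-cell estimates at long lags are noisy but average out
  across hundreds of cells.

# Population analyses

* **Pulse-chase records**: S-phase cells are gated as positive for both
  stains (two-class Otsu on log intensities by default; an absolute
  override exists). Rates are mean-rank percentiles,
  `100·(rank − ½)/n`, invariant under any monotone intensity transform.
  Δrate = BrdU rate − EdU rate; ΔCDK2 = activity at BrdU minus at EdU.
* **Binning**: half-open bins `[left, right)` from −0.10 to 0.25 in 0.05
  steps (7 bins); values outside are excluded; bins under the minimum
  count are flagged. The regression is an unweighted line through bin
  centers vs bin medians (the bin level is what the summary reports;
  noted in output metadata).
* **S duration**: median EdU per 1-h bin of time since APC/C
  inactivation, curve rescaled to unit area (making the estimate
  invariant to global intensity scaling), duration = span of the
  contiguous run of bins, containing the maximum, above 25 % of the curve
  maximum. The threshold fraction is explicit because the upstream
  readout states no rule.
* **Statistics**: timepoint-wise two-sided Mann–Whitney with Bonferroni
  correction by the number of tested timepoints; group comparisons use a
  Shapiro–Wilk check at α = 0.05 per group to select t-test/ANOVA+Tukey
  vs Mann–Whitney/Kruskal–Wallis+Dunn, with a zero-variance group forcing
  the rank branch.

# What the synthetic data do and do not establish

The generator reproduces the features the analyses consume: a linear ramp
with ~1-h Gaussian dips, a degron rising 3 h after the CDK2 rise, 40-min
washout recovery, regime differences in S length, dip spacing and γH2AX
burden, and rate-coupled nucleotide incorporation. It does not model
mitosis, daughter cells, cell motility or shape, photobleaching,
illumination gradients, mechanistic ATR/Chk1/Wee1 signaling, or
correlated (non-white) measurement noise. Passing parameter-recovery
tests therefore shows that the estimators are correct and unbiased under
the stated model — not that the model captures every property of real
microscopy data. Problem sizes in the checks (200 washout cells, 300–500
cells for landmark/autocorrelation recovery, 2000 cells per regime for
S-duration, 500 rendered nuclei per regime) were chosen so that sampling
error is well inside each tolerance.

# Known limitations

* Segmentation is threshold/watershed based and untested on crowded or
  textured real nuclei; no learned segmentation.
* Tracking is nearest-centroid with a gate; no lineage assignment through
  division.
* The second-derivative fluctuation score has no published normalization;
  only its rank behavior is validated.
* The quiescence-release preset encodes the regime phenomenology
  (plateau, denser dips, 2× burden) as parameters; it is not a fitted
  model of quiescence-release biology.
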