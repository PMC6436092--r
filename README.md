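# cdk2flux

Single-cell analysis of fluctuating CDK2 activity during S phase.

In cycling cells, CDK2 activity — read out live as the cytoplasmic:nuclear
ratio of a DHB reporter fragment — ramps up through S phase, but individual
cells show marked transient dips and plateaus. These fluctuations arise from
stochastic replication-stress events that trigger ATR-mediated, transient
repression of CDK2, which in turn throttles the global DNA synthesis rate.
`cdk2flux` packages the full quantitative toolchain for studying this
behavior when no real imaging data are at hand:

* **Trace simulator** — a Monte Carlo model in which CDK2 activity is zero
  in G0/early G1 and otherwise linear, minus a sum of Gaussian suppression
  dips centered at stochastic times within S phase:

  ```
  CDK2(t) = CDK2_linear(t) − Σᵢ αᵢ · exp(−(t − tᵢ)² / w)
  ```

  with identical amplitudes `αᵢ = α`, shape `w = 0.5 h²` (≈ 1 h full width
  at half-maximal suppression) and, by default, 20 events per S phase.
  Variants cover drug pulse/washout kinetics (40-min recovery half-life),
  CDK2-coupled DNA synthesis rates, and cycling vs quiescence-release
  regime presets (6 vs 9 h S phase, 1.2 h vs < 1 h anticorrelation lag,
  2× γH2AX burden).
* **Synthetic microscopy renderer** — multi-channel fields (nuclear marker,
  translocation reporter, degron, γH2AX/EdU/BrdU stains) with Poisson +
  Gaussian noise and exact per-cell ground truth.
* **Image quantification** — nuclear segmentation (Otsu on log intensity,
  watershed declumping), global background from the median outside 50-µm
  dilated masks, perinuclear-ring cytoplasmic measurement (2–10 µm annulus,
  10-µm neighbor exclusion, ring 75th percentile over nuclear median),
  top-hat γH2AX puncta pixel counting (4-µm kernel), and greedy
  nearest-centroid tracking.
* **Trace statistics** — 3-point smoothing, QC gates (bottom-5 % expression,
  0.25 ratio-jump filter), CDK2-rise and APC/C^Cdh1-inactivation landmark
  calling, the cubic polynomial-residual fluctuation metric (squared
  deviation per aligned timepoint, gated at activity 1.3), a
  second-derivative fluctuation score, S-phase slope, drug percent-change
  and washout recovery metrics, and detrended autocorrelation profiles.
* **Population analyses** — EdU/BrdU pulse-chase Δincorporation vs ΔCDK2
  percentile analysis with ΔCDK2 binning (−0.10 to 0.25 in 0.05 steps)
  and bin-level regression, AUC-normalized EdU time-binning for
  S-phase duration, timepoint-wise Mann–Whitney tests with Bonferroni
  correction, and the conventional parametric/rank group-test hierarchy.

## Worked example

Simulate a cycling population, call the landmarks, and measure the
CDK2-rise → S-entry lag and the oscillation lag:

```r
library(cdk2flux)

cells <- simulate_population(300, "cycling", seed = 1)

lag <- vapply(cells, function(cell) {
  call_apc_inactivation(cell$trace) - call_cdk2_rise(smooth_trace(cell$trace))
}, numeric(1))
mean(lag)
#> [1] 3.073866

segments <- data.frame(
  start = vapply(cells, `[[`, numeric(1), "true_apc_inactivation"),
  end   = vapply(cells, `[[`, numeric(1), "true_s_end"))
ap <- autocorrelation_profile(lapply(cells, `[[`, "trace"), segments, max_lag = 4)
ap$anticorrelation_lag
#> [1] 1.2
```

The mean lag recovers the configured 3-h delay between the CDK2 rise and
APC/C^Cdh1 inactivation; the autocorrelation minimum at 1.2 h reflects the
cycling preset's dominant 2.4-h dip spacing.

A full pixel-level round trip (render → segment → ring-measure → track)
is one call:

```r
pos <- expand.grid(row = c(70, 200, 330), col = c(70, 200, 330))
spec <- field_spec(400, 400, positions = pos)
frames <- render_population_frames(cells[1:9], spec, frames = 41:71)
meas <- quantify_frames(frames)   # per-cell, per-frame ratios with track ids
```

Scenario-level runs (`run_experiment`) execute a regime comparison,
washout dose series, or EdU/BrdU pulse-chase end to end and write tidy
CSV/JSON outputs plus a manifest of all parameters and seeds.

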