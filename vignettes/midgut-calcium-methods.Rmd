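---
title: "Quantifying cell-type-specific calcium dynamics in epithelial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-type-specific calcium dynamics in epithelial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midgutCa)
```

## The system and the measurement problem

The acid-secreting middle region of the fly midgut is a mosaic of four
cell classes: large copper cells (CC), interstitial cells (IC) occupying
the space between them, scattered enteroendocrine cells (EE) and basal
progenitors (PROG). Imaged *ex vivo* with genetically encoded Ca²⁺
indicators (GCaMP/RCaMP), each class shows distinctive dynamics: ICs
oscillate fastest (tens of mHz) and support multicellular Ca²⁺ waves that
travel almost exclusively through IC–IC contacts; CCs spike rarely; EEs
oscillate at roughly twice the progenitor rate. Blocking gap junctions
with carbenoxolone (CBX) abolishes both the waves and the single-cell
oscillations, and raises the CC baseline.

midgutCa implements the full quantification path for such recordings —
trace extraction, normalization, peak and frequency statistics, lagged
cross-correlation between cell types, kymograph and wave analysis —
together with a synthetic-tissue simulator that generates movies with
known ground truth, so that every stage of the pipeline is testable
without any microscope data.

## The analysis model

### Normalization and peak statistics

Each cell's trace is the mean fluorescence over its ROI per frame.
Traces are normalized as F/F_min, the ratio to the trace minimum, giving
a dimensionless series ≥ 1. When a trace's minimum is not positive
(offset-subtracted data, or very low SNR), `normalize_trace(offset=)`
shifts the trace first; because the automatic detection threshold is
invariant under affine rescaling, the offset does not change which peaks
are found (this invariance is property-tested).

Peak detection operates on the smoothed ratio (centered moving average,
default 3 frames) and keeps strict local maxima that satisfy three
criteria:

1. topographic prominence ≥ threshold;
2. height above a running-median local baseline ≥ the same threshold;
3. separation ≥ `min_separation` (default 2 frames; the most prominent
   peaks win ties).

The automatic threshold is `k × σ_sm` with `k = 5`, where `σ_sm` is a
robust estimate of the noise on the *smoothed* series:
`mad(diff(ratio))/sqrt(2)` scaled by `1/sqrt(w)`. Two design points are
deliberate. First, the successive-difference MAD is used instead of the
MAD of a detrended trace because at IC-like rates the spike waveforms
occupy a large fraction of samples and inflate any residual-based
estimate; differences only see the (frame-scale smooth) spike edges.
Second, the height criterion exists because prominence alone always
admits the global maximum of a pure-noise trace — its prominence is the
trace's full range — so prominence-only detection has a floor false-positive
rate of about one peak per silent trace. With both criteria the detector
achieves, on simulated spike trains at per-trace SNR 10, recall ≥ 0.99
with zero false positives over 20 seeds, and exact counts on noiseless
trains (these figures are recomputed by the test suite and
`scripts/acceptance.R`).

Per-cell frequency is `1000 × n_peaks / duration` (mHz); recordings
shorter than 290 s are excluded with a warning. Per-gut summaries report
means both including and excluding non-oscillating cells —
"non-oscillating" is taken to mean exactly zero detected peaks — and the
cross-gut summary reports mean ± s.e.m. where the s.e.m. is computed
across gut means (the natural reading of "per gut" statistics; per-cell
aggregation can be obtained from the per-cell table). Box statistics use
type-7 (linearly interpolated) quantiles with whiskers at
`q75 + 1.5·IQR` and `q25 − 1.5·IQR`; the quantile rule is stated because
the whisker positions depend on it.

### Lagged cross-correlation

For two equally sampled series E and p of length n,

$$ r(h) = \frac{\sum_i (E_{i+h} - \mu_E)(p_i - \mu_p)}
{\sqrt{\sum_i (E_i - \mu_E)^2}\sqrt{\sum_i (p_i - \mu_p)^2}}, $$

where the numerator runs over the overlap at lag h (no padding) and the
means and denominators use the entire series. This normalization was
chosen over per-overlap renormalization because it anchors the statistic
at lag zero: r(0) is *exactly* the Pearson correlation of the two series
(verified to 1e−12 against a brute-force double-loop oracle). Per-overlap
renormalization is available as an option. The sign convention is that
positive h shifts the first series later relative to the second
(`E[i+h]` against `p[i]`). Lag grids are symmetric (−H..H): negative
lags carry distinct information and the reference thresholds (|r(0)| < 0.2
for juxtaposed pairs; max |r(h)| < 0.32 over all lags up to 12 s) are
applied over the full grid. Unevenly sampled input is rejected rather
than silently resampled.

For independent series of n white-noise samples the null s.d. of r(0) is
1/√n; the calibration check simulates pairs through the pipeline's own
noise model with intrinsic rate 0, which yields temporally white traces.
This is intentional: traces containing indicator transients are
autocorrelated, which inflates the null spread of r(0) above 1/√n, so a
1/√n calibration is only meaningful on the white null. Consequently,
when interpreting r(0) for real oscillating traces the 1/√n yardstick is
conservative-to-wrong; the package's permutation-free thresholds (0.2,
0.32) are descriptive reference levels, not significance bounds.

### Kymographs and waves

`compute_kymograph()` samples a movie along a polyline at 1-pixel
arc-length steps, averaging `width` nearest-pixel samples perpendicular
to the local direction; a front moving at v µm/s appears as a streak of
slope 1/v. `detect_activations()` discretizes each trace into
above-threshold episodes with hysteresis (on-threshold: median plus the
larger of 5 robust noise s.d. and a quarter of the dynamic range — the
range floor matters for noiseless traces whose kernel tails never reach
zero exactly; off-threshold: halfway back to the median).

`link_waves()` joins activations whose cells share a wave-conducting
contact (adjacency edge with nonzero permeability) and whose onsets
differ by at most `link_window` (a natural choice is 3× the propagation
delay). Waves are the connected components — single linkage — because
observed waves split and collide, which path-based definitions handle
poorly. Each wave reports extent (distinct cells), duration, net
onset-ordered centroid displacement and angle, speed, and per-type
membership composition. Copper-cell involvement is summarized over
multicellular waves only: an isolated intrinsic CC spike is a wave of
extent 1 but not a propagation path.

Two limitations are inherent to onset linking and are worth knowing.
Distinct waves initiated within the linking window in adjacent regions
merge (the linker cannot know they had different causes); membership
ground-truth tests therefore use a single pacemaker cell so cascades are
temporally separated and the expected partition is decidable. And spikes
too close to the final frame produce no detectable activation
(end-censoring), so event counts are compared over observable spikes.

## The synthetic tissue and dynamics generator

The simulator emulates the statistical structure the analysis assumes,
not the biophysics (no IP₃/SERCA dynamics, no 3-D geometry, no
photobleaching):

* **Geometry** (`build_tissue_map()`): CC blobs on a jittered grid, the
  remaining space partitioned into IC cells by nearest-seed (Voronoi)
  assignment, EE/PROG as small discs carved from IC territory; adjacency
  from 4-neighbour mask contact. Defaults (64×64 px at 2 µm/px, 50
  cells) give 8–13 cells per ~3000 µm², the observed packing density,
  and a connected IC–IC contact graph.
* **Spiking** (`simulate_spikes()`): event statistics, not ODEs. Each
  cell fires as a stationary renewal process with refractory dead time D
  and exponential gaps at rate `1/(1/r − D)`, with the first arrival
  drawn from the equilibrium forward-recurrence distribution. The dead-time
  correction makes the realized rate equal the configured rate exactly in
  expectation — plain refractory thinning would converge to `r/(1+rD)`
  instead, and rate-recovery tests compare against the configured truth.
  Spikes trigger propagated spikes in neighbours after a delay, with
  probability (type-pair propagation probability) × (edge permeability);
  cascades share a wave id. Per-cell rate overrides support localized
  initiation sites.
* **Indicator** (`render_movie()`, `render_traces()`): per spike, a
  unit-peak difference of exponentials (rise 1 s, decay 3 s, GCaMP6s
  scale) times an amplitude of 3× baseline, matching the ~3–5-fold
  F/F_min excursions of real recordings; pixels take their cell's value,
  plus per-pixel Gaussian noise and optional rigid per-frame jitter.
* **CBX**: propagation probabilities forced to 0, intrinsic rates
  multiplied by a suppression factor (default 0), CC baseline multiplied
  by a free factor (default 2 — the elevation is qualitatively
  established but no quantitative value exists to calibrate against).

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| duration | 300 s | inclusion threshold for real recordings is 290 s |
| frame_interval | 2 s | within the ≤ 4.7 s acquisition regime; resolves the 1/3 s kernel |
| rates (IC/CC/EE/PROG) | 31 / 5.2 / 15 / 7.1 mHz | the per-gut mean rates reported for the four classes |
| refractory | 12 s | exceeds the detector's resolution limit (smoothing + separation ≈ 10 s at 2 s frames) so consecutive spikes are countable; well below the ~23 s mean interval of the fastest cells |
| propagation prob (IC→IC) | 0.15 | subcritical on the default contact graph (mean IC degree ~4–5), giving multicellular waves of a handful of cells — the longest observed waves cover about five; 0.9 would be supercritical and sweep the whole tissue |
| propagation prob (IC↔CC) | 0.05 | waves only rarely involve copper cells |
| propagation delay | 1 s | ~20 µm cell size at ~20 µm/s front speed |
| tau_rise, tau_decay | 1 s, 3 s | GCaMP6s-scale kinetics |
| amplitude / baseline | 300 / 100 a.u. | 3–5-fold F/F_min excursions |
| noise_sd | 30 a.u./pixel | per-pixel peak SNR ≈ 10 |
| smoothing, separation | 3 frames, 2 frames | one kernel width; minimal separation |
| k (threshold) | 5 | ~zero false positives on silent traces at these lengths |
| link_window | 3 × delay | tolerates frame quantization of onsets |

### What the generator does not emulate

Real recordings include photobleaching, z-drift and non-rigid tissue
motion, indicator saturation, heterogeneous expression levels, and
autofluorescence. None of these are modelled (drift is rigid and
per-frame only). Passing tests therefore demonstrate that the analysis
is correct *given* the assumed signal model — mean-intensity traces with
additive white noise around kernel-shaped events — not that it is robust
to every artifact of live imaging; manual QC of detected peaks
(`plot_peaks()`) remains the substitute for the by-eye verification used
with real data.

## Numerical and I/O choices

* Pixels are 0-based, x rightward, y downward; time starts at frame 0.
  Polygon ROIs rasterize with the half-open top/left rule so abutting
  polygons tile without overlap; circle ROIs include their boundary.
* Movies are written as multi-page TIFF with a JSON sidecar (frame
  interval, pixel size, channel, dimensions, intensity scale). Samples
  are stored as 32-bit values scaled into [0,1] by a power-of-two factor;
  a read-back reproduces intensities to one part in 2³² of the scale.
  CSV tables (traces, spikes) are written with 17 significant digits and
  round-trip exactly.
* Zero-variance series, non-positive F_min, uneven sampling, windows
  shorter than a frame, degenerate polylines, and infeasible tissue
  packings are rejected with explicit errors rather than coerced.
* All stochastic operations take seeds; a pipeline run
  (`run_pipeline()`) is byte-identical under a fixed seed, and its
  manifest records the seed and a hash of the full configuration.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data at
moderate sizes chosen to make the statistical assertions sharp: 100
random series pairs for the correlation oracle; 1000 independent
n = 120 pairs for the null calibration; 13 noiseless spike-count cases
and 20 noisy seeds for detection; 5 guts × 50 cells × 600 s for rate
recovery; a 10×10 coupled lattice (propagation probability 0.9, single
pacemaker) for wave-membership agreement; and two full pipeline runs
(64×64 px, 300 s, two channels) for determinism. The whole suite
completes in well under a minute on one CPU.

## Known limitations

* Onset linking merges genuinely simultaneous nearby waves and cannot
  assign an initiation site (consistent with waves having no obvious
  origin in the data this emulates).
* The cross-gut s.e.m. interpretation and the "non-oscillating = zero
  peaks" convention are interpretations; both aggregations (per gut and
  per cell, including and excluding silent cells) are emitted so either
  reading can be reproduced.
* F/F_min is undefined for non-positive minima; the offset-correction
  escape hatch changes the ratio scale (but not detection outcomes).
* The CC baseline elevation factor under CBX is a free parameter.
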