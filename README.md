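# midgutCa

Cell-type-resolved quantification of intercellular Ca²⁺ dynamics in
epithelial tissue, built around the copper-cell region of the fly midgut:
a mosaic of copper cells (CC), interstitial cells (IC), enteroendocrine
cells (EE) and progenitors (PROG) imaged *ex vivo* with genetically
encoded indicators (GCaMP/RCaMP). The package is aimed at imaging labs
who need reproducible trace-to-statistics pipelines for this kind of
recording, and at methodologists who want a fully simulated ground truth
to validate each stage against.

It provides, end to end:

* **a synthetic-tissue simulator** — typed cell mosaics, gap-junction-
  coupled stochastic spiking with ground-truth wave labels, indicator
  kinetics, TIFF movie rendering, and a carbenoxolone (CBX) condition
  that abolishes propagation and raises the CC baseline;
* **trace extraction** — ROI (circle/polygon) means, max projection,
  intensity-weighted centroid tracking for drifting cells;
* **oscillation statistics** — F/F_min normalization, prominence-based
  peak detection with a robust automatic threshold, per-cell frequencies
  in mHz, per-gut and cross-gut summaries including and excluding
  non-oscillating cells, box statistics;
* **lagged cross-correlation for finite time series** — for series E and
  p of length n and integer lag h,

  $$ r(h) = \frac{\sum_i (E_{i+h}-\mu_E)(p_i-\mu_p)}
  {\sqrt{\sum_i (E_i-\mu_E)^2}\sqrt{\sum_i (p_i-\mu_p)^2}}, $$

  with full-series means and denominators and overlap-only numerator
  sums, so that r(0) is exactly the Pearson correlation;
* **wave analysis** — kymographs along polylines, hysteresis activation
  events, single-linkage wave detection with extent, direction, speed
  and cell-type path composition.

## Worked example

```r
library(midgutCa)

tissue <- build_tissue_map(seed = 1)
tissue
#> <tissue_map> 64x64 px (2 um/px), 50 cells [CC:15 EE:10 IC:15 PROG:10], 101 edges

cfg    <- sim_config(duration = 300, seed = 1)   # rates 31/5.2/15/7.1 mHz
spikes <- simulate_spikes(tissue, cfg)
head(spikes, 4)
#>   cell_id time_s origin     wave_id
#> 1      26   1.86 intrinsic        1
#> 2      22   2.86 propagated       1
#> 3      25   2.86 propagated       1
#> 4      19   3.10 intrinsic        2

movie  <- render_movie(tissue, spikes, cfg)
movie
#> <ca_movie> [150 x 64 x 64] GCaMP, 2 s/frame, 2 um/px

traces <- tissue_traces(movie, tissue)
freqs  <- trace_frequencies(traces)
gut_summary(freqs)$across_guts
#>   cell_type n_guts mean_mhz sem_mhz include_nonoscillating
#> 1 CC             1    10.4       NA TRUE
#> 2 EE             1    16.7       NA TRUE
#> 3 IC             1    38.7       NA TRUE
#> 4 PROG           1     5.67      NA TRUE

acts <- detect_activations(traces)
ws   <- link_waves(acts, tissue, link_window = 3)
wave_report(ws)[c("n_multicellular", "max_extent", "cc_member_fraction")]
#> $n_multicellular [1] 40   $max_extent [1] 13   $cc_member_fraction [1] 0.138
```

Reading the numbers: in one 300 s control gut the detected per-cell
frequencies average 38.7 mHz for interstitial cells (intrinsic 31 mHz
plus propagated wave spikes), 10.4 mHz for copper cells, 16.7 and
5.7 mHz for EE/progenitors; the wave detector finds 40 multicellular
waves, the largest spanning 13 cells, with copper cells making up 14% of
wave-path membership. A single `run_pipeline(run_config(seed = 1))` call
produces the same analysis as a deterministic artifact set (movies,
ground truth, traces, peaks, frequency tables including/excluding silent
cells, correlation tables for direct and non-direct enterocyte–progenitor
pairs, wave reports, manifest). A thin command-line wrapper with
`simulate`/`extract`/`peaks`/`freq`/`xcorr`/`waves`/`report` subcommands
is installed at `inst/cli/midgutca.R`.

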