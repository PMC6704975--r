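# microstater

Resting-state EEG **microstate analysis** in R, with a planted-truth
synthetic-EEG generator so the whole chain is validated by parameter
recovery.

Spontaneous EEG does not wander continuously: the scalp potential topography
stays quasi-stable for ~80–120 ms, then switches abruptly to a new
configuration. These *microstates* are read as signatures of large-scale
brain network dynamics, and their temporal statistics — how long each state
lasts (**duration**), how often it recurs (**occurrence**), and what share
of time it occupies (**coverage**) — are studied as markers of psychiatric
conditions such as depression, where symptom severity has been related to
the occurrence of specific states. The package is aimed at EEG researchers
who want a scriptable, fully seeded version of the standard analysis, and at
methodologists who want each stage testable against known ground truth.

## What it implements

* **Preprocessing** — zero-phase 4th-order Butterworth band-pass (default
  1–40 Hz), integer-ratio decimation with anti-aliasing (e.g. 1000 → 125 Hz),
  average referencing, explicit channel selection.
* **Clustering** — global field power (GFP) computation and peak
  extraction; *polarity-invariant modified k-means* on peak topographies
  (assignment by maximal absolute spatial correlation, prototype update by
  the dominant spatial mode, best-of-restarts by global explained
  variance); selection of the number of classes K by a **seven-criterion
  meta-criterion** (Gamma, Silhouette, Davies–Bouldin, Point-Biserial,
  Dunn, Krzanowski–Lai, cross-validation; median-rank vote); **two-level**
  (per-subject, then group) clustering.
* **Segmentation** — backfitting every sample to the best-correlated map
  (polarity ignored), **Besag-factor temporal smoothing** (window half size
  3, strength 10) so low-GFP noise does not fragment stable segments;
  per-class duration / occurrence / coverage and global explained variance
  (GEV).
* **Statistics** — independent t-tests per parameter and class with
  Benjamini–Hochberg FDR correction within each parameter family, and
  Spearman correlations of every microstate parameter with clinical
  covariates (MADRS, CGI, episode count, medication scales) at α = 0.01.
* **Synthetic data** — 110-channel, 125 Hz, 5-minute recordings in which
  known orthogonal template maps alternate under a semi-Markov process
  (gamma dwell times, mean 100 ms), modulated by a rectified alpha-band
  envelope, plus spatially correlated noise at a controlled RMS
  signal-to-noise ratio; exact per-class ground-truth metrics ride along.
* **I/O** — EDF and headered delimited-matrix readers/writers, model-map /
  segmentation / metrics tables, a one-call `run_pipeline()`, and numbered
  analysis drivers under `analysis/`.

## Worked example

```r
library(microstater)

cfg <- simulation_config(n_channels = 110, fs = 125, duration_s = 60,
                         K_true = 6, mean_dwell_ms = 100, snr = 2, seed = 7)
sim <- simulate_recording(cfg, subject = "S01")
rec <- average_reference(bandpass_filter(sim$recording, 1, 40))

model <- modified_kmeans(peak_maps(rec), K = 6, n_restarts = 20, seed = 1)
print(model)
#> <microstate_model> K = 6, GEV = 0.823 (A 0.149, B 0.144, C 0.127, D 0.129, E 0.142, F 0.132)

seg <- segment_subject(rec, model)        # backfit + smooth + metrics
print(seg$metrics, digits = 3)
#>   subject class duration_ms occurrence_per_s coverage   gev
#> 1     S01     A         111             1.58    0.176 0.124
#> 2     S01     B         124             1.42    0.177 0.120
#> 3     S01     C         116             1.35    0.155 0.103
#> 4     S01     D         105             1.40    0.147 0.106
#> 5     S01     E         113             1.57    0.177 0.117
#> 6     S01     F         122             1.38    0.168 0.115

match_maps(model$maps, sim$truth$templates)$abs_correlation
#> 0.965 0.967 0.968 0.966 0.970 0.967
```

The fitted six maps explain 82% of the squared-GFP-weighted variance of the
peak topographies; each recovered map matches a planted template with
|spatial correlation| ≈ 0.97, and the per-class dwell times land near the
planted 100 ms mean. For a cohort-level run (individual clustering, pooled
group clustering with meta-criterion K selection, group statistics), see
`run_pipeline()` or step through `analysis/01_simulate.R` …
`analysis/05_stats.R`, which write their tables under `results/`.

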