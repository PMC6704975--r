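---
title: "Microstate analysis with planted-truth validation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis with planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Resting-state EEG alternates between brief (~80–120 ms) periods during which
the scalp potential topography stays quasi-stable — *microstates* — separated
by rapid transitions. Because a topography reflects the configuration of all
simultaneously active sources, microstate dynamics are read as the switching
dynamics of large-scale brain networks, and their temporal statistics
(duration, occurrence, coverage) have been examined as candidate markers in
mood disorders and other conditions. `microstater` implements the standard
analysis chain — preprocessing, polarity-invariant topographic clustering at
GFP peaks, selection of the number of classes, backfitting with temporal
smoothing, temporal metrics, and the group/clinical statistics layer — and
pairs it with a synthetic-EEG generator whose planted structure makes every
stage testable by parameter recovery. This vignette explains the models and
the choices behind them; it states no empirical result that the package's
tests and acceptance script do not themselves compute.

## The measurement chain

### Global field power and peak extraction

The GFP at sample $t$ is the *population* standard deviation of the scalp
potential across the $C$ channels (divide by $C$, not $C-1$) — the classical
definition, stated explicitly because either convention would be internally
consistent but they differ by a constant factor. Topographies at GFP peaks
have the best signal-to-noise ratio, so only peak maps enter clustering. A
peak is a strict interior local maximum; a plateau of equal values higher
than its surroundings contributes its first index (a determinism tie-break),
and peak thinning is off by default (`min_distance_samples = 1`). The first
and last second of a filtered recording are flagged as edge transients and
excluded from peak extraction, because forward–backward filtering
contaminates the edges.

### Polarity-invariant modified k-means

Microstate maps are defined only up to sign, so the clustering ignores
polarity throughout. For average-referenced data, assigning a map $x$ to the
prototype $m_k$ (unit norm, zero mean) of highest absolute spatial
correlation is equivalent to maximizing $|x^\top m_k|$, and the update step
replaces each prototype with the first principal direction of its assigned
maps' channel-space scatter. We compute that direction by power iteration
warm-started from the current prototype: each power step is a Rayleigh
quotient ascent, so the global explained variance

$$\mathrm{GEV} \;=\; \frac{\sum_t (x_t^\top m_{L(t)})^2}{\sum_t \lVert x_t \rVert^2}$$

is non-decreasing within every restart — a property the test suite asserts
on the per-iteration trace. Amplitudes are retained (peak maps are not
normalized), which is what makes the objective the squared-GFP-weighted GEV.
An empty cluster is re-seeded from the worst-explained map. Defaults:
100 restarts, iteration cap 1000, convergence at a relative GEV change of
$10^{-6}$; every stochastic step takes an explicit seed, assignment ties go
to the lowest class index, and the returned maps carry a deterministic sign
convention (largest-magnitude channel positive).

The pipeline drivers pass `n_restarts = 20`: on data with well-separated
topographies the optimum is reached in a handful of restarts, and the larger
default is a conservative margin for harder, real-data geometries.

### How many maps? The seven-criterion meta-criterion

No single cluster-validity index is reliable across geometries, so the
number of classes is chosen by combining seven indices computed on the
polarity-invariant dissimilarity $d_{ij} = \sqrt{2\,(1 - |r_{ij}|)}$ (the
chord distance after optimal sign alignment): Baker–Hubert Gamma, mean
Silhouette width, Davies–Bouldin, Point-Biserial, Dunn, Krzanowski–Lai, and
the predictive cross-validation criterion
$\hat\sigma^2 \left(\frac{C-1}{C-1-K}\right)^2$. Each index is oriented so
larger is better, min–max normalized across the candidate range, converted
to ranks, and the $K$ with the best *median rank* wins (ties to the smaller
$K$ — parsimony). The median makes the vote robust to any two indices
misbehaving; the index set is a documented, configurable composition chosen
to pair indices with different failure modes (compactness-based,
separation-based, and fit-penalty-based). Krzanowski–Lai needs fits at
$K\pm1$, so the fitting range is extended by one on each side internally.

### Two-level clustering

The cluster analysis runs first per subject, then at group level over the
pooled subject prototypes. The per-subject level uses a *fixed* class count
(default 6) rather than a per-subject meta-criterion: fixing it gives every
subject equal weight in the pool and stabilizes the second level, at the
cost of assuming the individual map count; it is configurable. Per-subject
clustering seeds are derived from the subject identifier rather than the
list position, so reordering subjects cannot change any per-subject fit —
the group model is then invariant to subject order up to map order and sign.

### Backfitting and Besag-factor smoothing

Every sample (not only GFP peaks) is assigned to the class of highest
absolute spatial correlation. No minimum-correlation rejection is applied —
every sample is labeled — and ties go to the lowest class index. Low-GFP
samples are noisy, so the label sequence is then smoothed by the classical
windowed relabeling: iteratively reassign sample $t$ to the class $k$
minimizing

$$\frac{\mathrm{GFP}_t^2\,(1 - r_{tk}^2)}{2\,e\,(C-1)} \;-\; \lambda\, N_{bkt},$$

where $e$ is the mean residual noise variance of the unsmoothed assignment
(held fixed), $N_{bkt}$ counts the samples labeled $k$ within $\pm b$
samples of $t$, and the defaults are $b = 3$ samples and $\lambda = 10$ (the
Besag factor). Two implementation details matter and are deliberate:

* **Update schedule.** A fully synchronous relabeling sweep can enter a
  2-cycle — a set of samples flipping between two labelings forever — so the
  "no label changes" stopping rule never fires. Samples are therefore
  updated colour by colour (colour $=$ index mod $b+1$): sites sharing a
  colour are more than $b$ apart and do not interact, each update lowers the
  local objective with the rest fixed, and the sweep converges (typically in
  ~10 iterations; cap 1000).
* **The window count includes the sample itself.** A label lends itself one
  vote of support. This mild hysteresis preserves genuinely brief segments —
  at a three-sample segment it takes roughly half the penalty margin to
  overturn the incumbent compared with the self-exclusive count — while a
  single unsupported blip is still absorbed (its one self-vote faces six
  opposing neighbours at $b=3$). With a right-skewed dwell distribution a
  substantial fraction of genuine segments are short, and the self-exclusive
  variant audibly over-merges them, inflating mean durations; the
  self-inclusive count recovers planted durations markedly better under the
  generator's conditions.

With $\lambda = 0$ the penalty vanishes and smoothing is the identity.

### Temporal metrics and GEV

Per class: *duration* is the mean uninterrupted dwell in ms, *occurrence*
the number of segments per second, *coverage* the fraction of labeled time.
Segments truncated by the recording edges are excluded from the duration
mean (truncation only shortens, so including them biases duration downward)
but do count toward occurrence and coverage; hence the identity
$\mathrm{coverage} = \mathrm{occurrence} \times \mathrm{duration}/1000$
holds only up to that edge tolerance, which the tests quantify. A class
absent from a recording reports a *missing* duration, never 0, and
statistics downstream use pairwise deletion. Internally everything is in
samples (0-based, half-open segments at the file boundary); milliseconds and
seconds appear only at the reporting boundary. GEV is computed per class as
the squared-GFP-weighted squared correlation of each sample with its
assigned map, normalized by total squared GFP.

## Preprocessing

Band-pass 1–40 Hz with a 4th-order Butterworth applied forward–backward
(zero phase — any phase distortion would distort topographies), then
integer-ratio decimation with a zero-phase low-pass at $0.4 \times$ the
target rate, then average referencing. The filter family and order are a
standard choice for microstate work. Non-integer decimation
ratios are refused rather than silently interpolated, matching the
1000 Hz $\to$ 125 Hz integer 8:1 path the package targets; channel-set
reduction (e.g. dropping neck/face electrodes) is an explicit user-supplied
list, never hard-coded. ICA artifact removal and bad-channel spline
interpolation are out of scope: the synthetic data contains no such
artifacts, and both steps are interactive, human-in-the-loop procedures in
practice.

## The synthetic-EEG generator

The generator is the package's validation instrument: it plants known
structure and the pipeline must give it back.

* **Templates**: smooth random maps (random combinations of low-order
  spatial cosine modes), centered, orthogonalized and renormalized.
  Orthogonal zero-mean unit maps have pairwise spatial correlation exactly
  0, so any requested separation bound holds; an infeasible request
  ($K \ge C$) is an error, never silently relaxed.
* **Dynamics**: a semi-Markov sequence — segment classes drawn uniformly
  excluding the previous class (no self-transitions), dwell times gamma
  with shape 2 and mean 100 ms (the classical dwell range), rounded to at
  least one sample. Shape 2 is positive and right-skewed without the excess
  of near-zero dwells an exponential would produce.
* **Amplitude**: the active template is scaled by a rectified 10 Hz
  sinusoid (an alpha-band surrogate giving GFP peaks every ~50 ms, so peak
  extraction has structure to find) with a small positive floor (5% of the
  peak) and a fixed phase offset, scaled to unit mean. The floor keeps the
  envelope strictly positive: an exact zero would make the instantaneous
  topography undefined and break the noiseless label-recovery limit.
* **Noise**: spatially correlated Gaussian noise — a random rotation of a
  decaying eigenvalue spectrum — average-referenced and scaled so that
  (RMS of noiseless signal)/(RMS of noise), pooled over channels and time,
  equals the requested `snr`. The definition is stated because "SNR" is
  ambiguous. Spatially *white* noise would be unrealistically easy for
  topographic clustering. `snr = Inf` means no noise; `snr = 0` means pure
  noise at unit RMS.
* **Ground truth** carries the templates, the label sequence, and per-class
  metrics computed from that sequence *with the same segment conventions as
  the analysis side* (edge segments excluded from duration means), so
  recovery errors measure the pipeline rather than a convention mismatch.

What the generator does **not** emulate: biophysical forward modeling (no
head model, no dipoles), ocular/cardiac artifacts, drifting vigilance
states, inter-subject topography variability, or 1/f temporal structure in
the noise. Passing recovery tests therefore shows the chain is correct and
well-calibrated under a fair idealization of resting EEG — not that it would
recover truth from any real recording.

## Statistics layer

Group comparisons are two-sided independent t-tests (pooled variance by
default, Welch by flag) per temporal parameter and class, corrected by
Benjamini–Hochberg within each parameter family across the $K$ classes —
the family structure mirrors reporting one corrected p per class within
each parameter. Clinical associations are Spearman correlations (Pearson of
mid-ranks; two-sided p from the $t$ approximation with $n-2$ df, a standard
choice near $n \approx 19$) of every (parameter, class) cell with every
clinical covariate, patients only, flagged at $\alpha = 0.01$, with the full
table returned rather than only significant rows. Calibration is checked
empirically: under group-label permutation of null metrics the familywise
BH discovery fraction sits at the nominal level, and null Spearman flags at
$\alpha = 0.01$ occur at about 1% (the $t$ approximation runs a shade
liberal at $n = 19$, visible in the calibration numbers).

## Problem sizes and numerical choices

The validation experiments run ten replicate cohorts of ten subjects at the
full study geometry (110 channels, 125 Hz, 300 s, six templates, snr 2) —
large enough that per-class metrics are stable, small enough to rerun
routinely. Unit tests use reduced geometries (10–24 channels, 5–30 s) where
brute-force oracles are affordable. Other fixed choices: assignment and
smoothing ties break to the lowest class index; k-means convergence is a
relative GEV change below $10^{-6}$; zero-variance samples or maps are
errors (correlation undefined), never silently zeroed; EDF export quantizes
to 16 bits and truncates to whole one-second records with a warning.

## Known limitations

* The seven-index composition of the meta-criterion is a documented
  stand-in for the combination used by the reference software ecosystem,
  whose exact index list is not public; the median-rank vote is robust but
  a different defensible set could select differently on borderline data.
* The smoothing recovers dwell statistics well at the generator's
  conditions, but any fixed $(\lambda, b)$ trades blip suppression against
  erasure of genuinely brief states; duration estimates remain mildly
  biased upward (a few percent) and occurrence mildly downward.
* Per-subject clustering at a fixed K misestimates subjects whose true map
  count differs; the pooled second level tolerates some of this but is not
  immune.
* The EDF reader covers continuous, uniform-rate, 16-bit EDF with optional
  annotation channels — not the full EDF+ discontinuous feature set.
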