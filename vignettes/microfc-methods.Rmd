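---
title: "From calcium time-lapse stacks to functional-connectivity graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium time-lapse stacks to functional-connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfc)
```

`microfc` turns time-lapse calcium-imaging recordings of neural
microtissues into weighted functional-connectivity graphs and
community-structure statistics. The chain is: cell-body detection on a
maximum projection, circular-mask trace extraction, ΔF/F with a
sliding-percentile baseline, template-matching event detection, and graph
metrics on the Pearson cross-correlation matrix (average correlation,
Onnela weighted clustering, weighted path length, hierarchical-clustering
module detection, Newman modularity, intra/inter-modular correlation).
Because real recordings of this kind are rarely shareable, the package
ships a synthetic-activity generator with planted module structure; every
pipeline stage is validated against the generator's ground truth.

## The synthetic generator

`generate_activity()` emulates the statistical structure that the analysis
assumes about a spontaneously active microtissue:

* `n_cells` cells, partitioned into `n_modules` latent modules
  (contiguous, equal-sized).
* Each module fires population events as a Poisson process
  (`module_event_rate`, events/min). At a module event, member cells
  participate with probability `p_intra`, non-members with `p_inter`
  (`p_inter <= p_intra`). Intra/inter participation is what creates the
  block structure in the correlation matrix.
* Tissue-wide synchronous bursts (`global_burst_rate`, bursts/min) recruit
  every cell — the substrate of the whole-tissue firing rate.
* Each cell additionally fires independent noise events
  (`noise_event_rate`, events/min).
* Every event contributes a difference-of-exponentials transient
  `A (e^{-t/tau_d} - e^{-t/tau_r})`, rescaled so its peak equals the drawn
  amplitude `A`; defaults `tau_r = 0.2` s and `tau_d = 1.5` s approximate a
  slow indicator such as GCaMP6s. Transients superpose additively
  (linearity is assumed; indicator saturation is out of scope). Amplitudes
  are log-normal with mean `amplitude_mean = 0.5` ΔF/F and CV 0.3. One
  amplitude is drawn per population event and shared by all participating
  cells, so fully coupled cells produce literally identical traces; noise
  events draw per-cell amplitudes.
* Gaussian sensor noise with `noise_sd = 0.02` ΔF/F is added.

Default rates (3 module events/min, 1 burst/min, 0.5 noise events/min per
cell) give each cell roughly four transients per minute, a plausible level
for spontaneously active dissociated cultures in the first weeks in vitro.
No published per-cell event statistics were available to fit against, so
these are stated conditions, not estimates.

`render_stack()` turns traces into a 16-bit image stack: each frame is
`baseline_f + render_gain * sum_i trace_i(t) * blob_i` with unit-peak
Gaussian blobs of sigma `cell_radius / 2` (a Gaussian of that sigma has a
full width at half maximum close to a disk of radius `cell_radius`).
Positions are drawn uniformly with a minimum center-to-center spacing of
`2 * cell_radius` by rejection sampling (`clumped = TRUE` disables the
constraint for merge/splitting experiments). Rendering is deterministic
given the traces; photobleaching, motion, and 3-D effects are not
modelled.

What passing tests on this generator do **not** show about real data:
real somata are not Gaussian blobs, real noise is not white, real
transients vary in kinetics within a cell, and real modules need not be
equal-sized or contiguous. The generator is a correctness oracle for the
pipeline's logic, not a biophysical simulation.

```{r generator}
cfg <- synth_config(n_cells = 60, n_modules = 3, duration = 240, seed = 1)
sim <- generate_activity(cfg)
sim$traces
table(sim$truth$module_labels)
```

## ROI detection

`detect_seeds()` implements the smoothing → adaptive-threshold →
distance-transform → Laplacian-of-Gaussian chain on a maximum projection:

1. Gaussian smoothing with `smooth_sigma = 2.5` px (matched to cell-body
   size at 10x).
2. Adaptive threshold: a pixel is foreground when it exceeds the local
   mean over a `block_size = 5` px square by the fraction
   `threshold_fraction` (default 0.013, the midpoint of the curated
   0.008–0.018 range). The comparison is multiplicative
   (`pixel > mean * (1 + f)`) because the stated fractions are small
   relative to typical intensities; an additive mode is available. The
   local mean uses replicate padding at the borders.
3. Euclidean distance transform of the foreground.
4. Scale-normalized LoG pyramid on the distance map, 10 scales over
   sigma 1–5 px, blob response threshold 0.01; scale normalization can be
   disabled. Peaks within 2 px of the image border are discarded — the
   boundary padding biases the filter response there, and in testing every
   spurious detection sat exactly on the border.
5. Non-maxima suppression: of two detections closer than
   `sqrt(2) * min(scale)`, the weaker is discarded.

Coordinates are 0-based throughout, `x` = column, `y` = row.
`curate_seeds()` replaces interactive curation with two rules (a boundary
mask and explicit removal indices), and `make_masks()` places a 3-px
circular ROI over each seed, resolving overlaps by nearest seed.

Known limitation: two cells at exactly the generator's minimum spacing can
merge into one foreground component and yield a single seed; recall on
clean rendered stacks is 0.9–1.0 per realization. Cells separated by more
than the blob's full width are detected reliably.

## Signal extraction and event detection

`extract_traces()` averages mask pixels per frame. `compute_dff()` uses
the 20th percentile of the raw signal in a centered 10-s window as the
baseline `F0(t)` and returns `(F - F0) / F0`; the window is centered
rather than trailing so the baseline bias is symmetric for slow
indicators (a trailing mode would be a one-line change in
`sliding_quantile`). Non-positive baselines raise an error instructing an
offset, rather than producing silent infinities.

`detect_events()` is a template-matching detector in the FluoroSNNAP
style. The library holds unit-peak difference-of-exponential templates on
a grid (rise 0.1/0.2/0.4 s × decay 0.75/1.5/3.0 s, 5 s long, replaceable
via CSV). Design choices that matter:

* **Matching segment.** Similarity is the maximum Pearson correlation
  between the sliding window and the leading 1.5 s of each template — the
  rise and early decay, which is where a transient is discriminative. Over
  a full 5-s window the slowly decaying tail of the *previous* event
  dominates the correlation and pushes genuine onsets below threshold.
* **Amplitude.** An event's amplitude is the window's peak ΔF/F minus the
  value at the window start (the transient's rise above its local level).
  This makes the `min_amplitude = 0.01` gate meaningful on decaying tails,
  whose windows peak at their first sample and therefore never qualify.
* **Peak picking.** Candidates (similarity ≥ 0.7 and amplitude ≥ 0.01)
  are reduced to strict local maxima of the similarity profile, and
  detections closer than `min_separation = 0.25` s collapse to the
  strongest. Events closer than that separation are merged by
  construction; events in the final matching window of a trace cannot be
  detected.
* Zero-variance windows have similarity 0 by definition (never NaN), and
  Pearson similarity makes detection invariant to positive rescaling of
  ΔF/F.

On noiseless generator output these choices give event recall 0.97–1.0
and precision ≥ 0.99 against ground-truth onsets (±0.5 s) at the default
thresholds. With the default sensor noise (`noise_sd = 0.02`, twice the
amplitude gate) precision drops to ~0.85: the 0.01 gate deliberately sits
below the noise floor because it is a stated analysis convention, not a
tuned value.

The whole-tissue trace is the *mean* ΔF/F across ROIs (so the amplitude
gate keeps its meaning regardless of N); `method = "sum"` reproduces the
summed trace for plotting. The whole-tissue firing rate is the number of
events detected on that trace divided by the recording length in minutes.

## Graph metrics

`correlation_matrix()` computes full-length Pearson correlations between
ΔF/F traces (an event-train alternative can be built by correlating
binarized rasters; ΔF/F is the default because transient shape carries
coupling information at these rates). Zero-variance traces get zero
correlations and a warning; the node is kept.

For the graph-theoretic formulas, negative correlations are clipped to 0
(Onnela clustering and Newman modularity assume non-negative weights);
signed values are retained for the average correlation, connectome edge
lists, and regressions.

* **Onnela clustering**: with max-normalized weights, node i's
  coefficient is the sum of geometric-mean triangle intensities over
  ordered neighbor pairs divided by `k_i (k_i - 1)`; `k_i` counts strictly
  positive weights (an "all N−1 neighbors" mode exists because the
  threshold-free reading is ambiguous). Nodes with fewer than two
  neighbors score 0.
* **Path length**: edge length `1 / w_ij`, exact shortest paths
  (Dijkstra via igraph), averaged over ordered pairs. Unreachable pairs
  contribute `N * max(finite distance)` so fragmented graphs keep a finite
  L; `unreachable = "strict"` returns `Inf` instead.
* **Modularity**: standard weighted Newman
  `Q = (1/2m) * sum_ij [w_ij - s_i s_j / 2m] delta(c_i, c_j)`, self-edges
  zero, the null-model diagonal term retained — this is the convention
  under which a single module scores exactly 0 and two disconnected equal
  cliques score 0.5. (The ratio wording sometimes used for Q describes the
  same quantity loosely; the normalized-difference form is what Newman
  defines.) Verified to 1e−10 against `igraph::modularity` and a
  double-loop oracle.
* **Module detection**: average-linkage agglomerative clustering on
  `1 - w_ij`, cut at k = 1..`max_modules`; the cut maximizing Q wins, ties
  to fewer modules. Average linkage is the conventional choice for
  correlation distances; no linkage was prescribed.
* Intra-modular correlation is reported per module (singletons excluded),
  inter-modular per module pair; connectome edge lists keep pairs above
  0.5 by convention.

```{r graph}
cm <- correlation_matrix(sim$traces, positions = sim$truth$positions)
graph_metrics(cm)[c("avg_correlation", "avg_clustering", "avg_path_length")]
detect_modules(cm)
```

## Contraction

`detect_pegs()` binarizes a phase image (Otsu; a polarity flag is required
because tissue may image bright or dark), traces edges with a
Gaussian+Sobel detector, fills the edge rings, and keeps components whose
equivalent diameter is within ±25% of the expected peg diameter.
`contraction_fraction()` then reports the percent of tissue-positive
pixels inside the circle inscribed in the peg ring (centered at the peg
centroid mean, radius = distance to the nearest peg minus half a peg
diameter). The inscribed-circle geometry is this package's choice of
"center region" and is configurable through the returned layout.

## Orchestration and statistics

`run_recording()` composes the stages deterministically and embeds
provenance (package version, parameters) in its outputs; any stage error
aborts naming the stage. `compare_groups()` delegates to standard
routines — Student or Welch unpaired two-tailed t-tests (paired optional)
for two groups, one-way ANOVA with Tukey HSD for more — because group
inference is routine and deliberately not re-implemented.

## Numerical choices and test scale

Seeds flow from one configuration value; identical configurations are
bit-identical, including rendered stacks. Oracle comparisons (brute-force
triangle enumeration, Floyd–Warshall, double-loop Q) run at tolerance
1e−10 on 5–8-node graphs. The validation suite uses 60-cell, 4-minute
recordings at 15 frames/s for trace-level properties and 20-cell,
30–60-second rendered stacks (128×128 px) for image-level properties —
large enough that recall/precision and recovery statistics are stable at
the asserted thresholds, small enough to iterate quickly.

## Known limitations

* No spike inference, neuropil subtraction, bleach or motion correction.
* The generator's modules are equal-sized and its noise white; pipeline
  performance on real tissue depends on imaging quality in ways the
  synthetic oracle cannot capture.
* Event detection cannot resolve events closer than `min_separation`
  and misses events starting in the last matching window of a trace.
* Hub/rich-club analysis, directed inference, and edge-significance
  testing by surrogate data are out of scope.
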