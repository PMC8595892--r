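# microfc

Functional-connectivity analysis of single-cell calcium imaging in neural
microtissues.

Self-assembled 3-D neural cultures ("microtissues") expressing a
genetically encoded calcium indicator produce 4-minute time-lapse videos
of spontaneous activity. `microfc` implements the full computational chain
from such a video to a weighted functional-connectivity graph and its
community-structure statistics, for researchers studying network
maturation and perturbations (for example neuroinflammatory challenges)
at the microcircuit scale where every node is one cell.

The chain:

1. **ROI detection** — Gaussian smoothing (σ = 2.5 px), adaptive local-mean
   thresholding (5-px neighborhood, fraction 0.008–0.018 above the mean),
   Euclidean distance transform, and a scale-normalized
   Laplacian-of-Gaussian pyramid (σ = 1–5 px, response > 0.01) with
   non-maxima suppression; programmatic curation by boundary mask.
2. **Signal extraction** — 3-px circular ROI masks, per-frame mean
   intensity, ΔF/F with a sliding-baseline
   `F0(t) = P20(F, 10-s window)`, and template-matching event detection
   (difference-of-exponential waveform library, Pearson similarity ≥ 0.7,
   minimum amplitude 0.01 ΔF/F).
3. **Graph analysis** — on the Pearson cross-correlation matrix
   `w_ij = corr(ΔF/F_i, ΔF/F_j)`:
   average correlation (mean off-diagonal `w_ij`); Onnela threshold-free
   weighted clustering
   `C_i = Σ_{jk} (ŵ_ij ŵ_ik ŵ_jk)^{1/3} / [k_i(k_i−1)]` with
   `ŵ = w / max(w)`; weighted path length `L = Σ_{i≠j} D_ij / N(N−1)` with
   edge length `1/w_ij`; module detection by average-linkage hierarchical
   clustering of `1 − w_ij` with the cut chosen to maximize Newman
   modularity `Q = (1/2m) Σ_ij [w_ij − s_i s_j/2m] δ(c_i, c_j)`;
   intra-/inter-modular correlations; connectome edge lists (`w_ij > 0.5`);
   correlation-versus-distance and module-size regressions; whole-tissue
   firing rate (events/min on the mean trace).
4. **Contraction** — percent tissue-positive pixels inside the circle
   inscribed in the ring of agarose pegs detected on a phase image.

Because recordings of this kind are rarely deposited, the package includes
a synthetic-activity generator (`generate_activity`, `render_stack`) with
planted modules, tissue-wide bursts, GCaMP6s-like transient kinetics, and
optional rendering to 16-bit image stacks — every stage of the pipeline is
validated against its ground truth.

## Worked example

Simulate a standard recording (60 cells, 3 modules, 4 min at 15 fps) and
analyze it:

```r
library(microfc)

cfg <- synth_config(n_cells = 60, n_modules = 3, duration = 240, seed = 1)
sim <- generate_activity(cfg)
sim$traces
#> <trace_set: 60 ROIs x 3600 frames @ 15 fps, kind = dff>

cm <- correlation_matrix(sim$traces, positions = sim$truth$positions)
m <- graph_metrics(cm)
sprintf("avg correlation %.3f | avg clustering %.3f | path length %.3f",
        m$avg_correlation, m$avg_clustering, m$avg_path_length)
#> "avg correlation 0.482 | avg clustering 0.476 | path length 2.355"

detect_modules(cm)
#> <module_partition: 3 modules, Q = 0.161, sizes: 20, 20, 20>

firing_rate(detect_whole_tissue_events(sim$traces))
#> [1] 16.5
```

The three planted modules are recovered exactly (adjusted Rand index 1
against `sim$truth$module_labels`). The average correlation of 0.48
reflects strong intra-module coupling (`p_intra = 0.9`) over a weak
inter-module background (`p_inter = 0.05`); the modularity Q of 0.16 is
the strength of that partition against a degree-matched random null; the
firing rate counts population events per minute on the mean ΔF/F trace.

To run from an image stack instead, `run_recording("stack.tif", fps = 15)`
composes ROI detection → traces → ΔF/F → events → graph metrics and
returns (optionally writes) all artifacts; `compare_groups()` applies
t-tests or ANOVA + Tukey HSD to a table of per-recording metrics.

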