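---
title: "Connectopic mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopy)
```

## The problem

Topographically organised cortex — primary visual cortex (V1) being the
canonical case — maps a continuous stimulus space smoothly onto the cortical
sheet: eccentricity (distance from fixation) along one axis, polar angle
around fixation along the other. Functionally similar neurons are expected
to show similar connectivity, so each V1 vertex's *connectivity
fingerprint* — the vector of correlations between its timeseries and
reference timeseries from the rest of the brain — should vary smoothly with
its position in the map. Connectopic mapping inverts this logic: embed the
fingerprints into two dimensions and ask whether the resulting components
(*connectopic maps*) reproduce the retinotopic maps measured by traditional
visual field mapping.

`connectopy` implements the whole evaluation pipeline: fingerprint
construction, a suite of linear and non-linear embeddings, cross-validated
parameter selection, accuracy scoring against ground truth, and the
statistical framework for comparing algorithms — together with a synthetic
generator so that every stage is testable without imaging data.

## The pipeline

For each recording the scan runs are partitioned into odd and even halves
(`split_odd_even()`), giving two independent estimates per subject. Within a
half:

1. **Lossless PCA.** The non-ROI data (`M` sources × `T` timepoints, with
   `M > T`) are compressed by treating timepoints as observations: after
   mean-centering, `T − 1` principal-component score timeseries retain 100%
   of the variance. This is a pure rotation of the timepoint samples —
   pairwise distances between timepoints are preserved — and exists only for
   computational tractability.
2. **Fingerprints.** Each ROI vertex's timeseries is Pearson-correlated with
   every component, and the correlations are Fisher z-transformed
   (`atanh`, after clipping `|r| ≤ 1 − 1e−7` so accidental duplicates stay
   finite). Five *connectivity sources* are supported: the full stack
   (`all`), cortex or subcortex alone, moment-matched Gaussian noise in
   place of the sources (`noise`), and within-ROI correlations
   (`within_roi`, diagonal set to zero; optionally through the ROI's own
   PCA).
3. **Embedding.** The fingerprint rows are reduced to `m = 2` components by
   one of: spectral embedding on five graph variants (k-nearest-neighbour or
   radius neighbourhoods, unweighted or correlation-weighted, plus a
   fully-connected weighted graph), PCA, ICA, kernel PCA (second-order
   polynomial or RBF), modified locally linear embedding, local tangent
   space alignment, Isomap, diffusion maps, and t-SNE.
4. **Scoring.** The 2 × 2 correlations between components and ground-truth
   maps are matched greedily — largest `|r|` first, then the remaining
   pair — so each component predicts exactly one map; accuracy is the
   absolute correlation per matched pair (absolute, because eigenvector-based
   components carry an inherent sign ambiguity).

Free parameters are selected on one half by Gaussian-process Bayesian
optimisation (`crossval_optimize()`) maximising the mean matched `|r|`, then
applied to the held-out half; parameters are never tuned on the data they
are scored on. The default budget is 100 evaluations per free parameter, of
which 10 are space-filling random starts. Trials that produce a
disconnected neighbourhood graph are scored `-Inf` and excluded from the
surrogate, since the graph Laplacian of a disconnected graph has no single
smooth ordering to recover.

## Algorithm notes and numerical choices

* **Graphs.** Neighbourhoods are defined on squared Euclidean distances
  (both the kNN ranking, which is unaffected, and the radius threshold,
  which is therefore in squared-distance units). kNN graphs are
  OR-symmetrized: an edge exists if either sample is within the other's `k`
  nearest. Weights, where used, are `(r + 1) / 2` so a perfect negative
  correlation maps to 0 and weights stay non-negative.
* **Spectral embedding** uses the symmetric normalized Laplacian
  `L = I − D^{−1/2} W D^{−1/2}` and returns the `D^{−1/2}`-rescaled
  eigenvectors of its two smallest non-zero eigenvalues (the random-walk
  eigenvectors, constant on the trivial mode). Zero eigenvalues are counted
  at a relative tolerance of `1e−8`; more than one means a disconnected
  graph and is an error by design.
* **Diffusion maps** weight a kNN graph with the Gaussian heat kernel
  `exp(−‖x−y‖²/ε)` (decaying — an affinity kernel must shrink with
  distance), apply the density correction `K^{(α)} = D^{−α} K D^{−α}` with
  `α ∈ [0, 1]`, row-normalise to a transition matrix, and return
  eigenvectors 2–3 scaled by their eigenvalues at diffusion time `t = 1`
  (no diffusion-time selection is attempted). The kernel is evaluated on
  kNN edges (sparsify first, then weight); self-similarity is kept at 1.
* **Kernel PCA** double-centers the kernel matrix in feature space; the
  polynomial kernel is `(xᵀy + 1)²` (parameter-free), the RBF kernel
  `exp(−γ‖x−y‖²)`.
* **MLLE / LTSA** follow the published algorithms with dense
  eigendecomposition of the alignment matrix (the ROI has ~10² vertices, so
  sparse solvers buy nothing). LTSA solutions are defined only up to an
  affine map of the plane; on symmetric inputs the two components can be an
  arbitrary rotation of the map axes, which is why recovery for LTSA should
  be judged rotation-invariantly.
* **ICA** extracts 2 components after PCA whitening by symmetric FastICA
  with the logcosh contrast from a seeded random orthonormal start —
  deterministic given the seed.
* **t-SNE** runs exact (non-approximated) gradient descent initialised from
  the PCA embedding, five restarts with seeded jitter; the fit with the
  smallest final Kullback–Leibler divergence wins and all divergences are
  recorded.
* **Component signs** are fixed (largest-magnitude entry positive) purely
  for reproducibility; all accuracy and reliability scores are
  sign-invariant.
* **Optimizer search spaces**: `k ∈ [3, n/2]` (integer, log-spaced), radius
  between the 1st and 99th percentiles of the squared distances, kernel
  spreads log-uniform over `[1e−4, 1e4]` × the median squared distance,
  `α ∈ [0, 1]`, perplexity `∈ [5, n/4]`, learning rate `∈ [10, 1000]`. The
  surrogate is a fixed-hyperparameter Gaussian process (squared-exponential
  kernel, lengthscale 0.2 on the unit cube, nugget `1e−4`) maximising
  expected improvement over a random candidate set — small, deterministic,
  and adequate for 1–3-dimensional smooth objectives.

## The statistical framework

Accuracies are compared against zero with one-sample t-tests
(Holm–Bonferroni corrected within algorithm), between map types with paired
t-tests, and across factors with fully within-subject repeated-measures
ANOVAs (`rm_anova()`): sums of squares via orthonormal within-subject
contrasts, one subject-by-effect error stratum per effect, a
Greenhouse–Geisser ε applied to *every* effect (a no-op at 2 levels), and
effect sizes as partial η² (`SS_eff / (SS_eff + SS_err)`) and generalized
η² with all factors treated as manipulated
(`SS_eff / (SS_eff + Σ all error SS)`). Post-hoc comparisons use Tukey's
studentized range on the effect's own error stratum. Power functions use
the exact non-central t and F distributions; the repeated-measures power
takes Cohen's f in the SPSS convention with noncentrality `λ = f²·n` (with
the published inputs — f = 1.33, 10 levels, n = 174 — any standard
convention saturates at power 1 to machine precision, so the choice is
documented rather than consequential). The polar-angle map is a circular
variable but is correlated with the linear Pearson statistic throughout,
deliberately mirroring the standard procedure; no phase unwrapping is
attempted.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_subject()` generate one subject: a rectangular
`n_ecc × n_pol` grid of ROI vertices with eccentricity in `[1, 8]` degrees
and polar angle in `[0, π]` (one hemifield, so no circular wrap inside the
ROI). One latent standard-normal source sits at every grid node — this
guarantees both map axes are recoverable — and vertex `v` mixes them with
Gaussian weights `exp(−d(v,s)² / 2ℓ²)` plus i.i.d. noise, so pairwise
correlation decays monotonically with topographic distance. Runs are drawn
independently, a baseline of 100 raw units is added, and rows are converted
to percent signal change run by run before concatenation. Non-ROI "cortex"
rows are dense random mixtures of the same latents, "subcortex" rows sparse
mixtures (5 latents each) with half as many rows — mirroring the roughly
2:1 cortical/subcortical split of whole-brain grayordinates — and both
blocks exceed the per-split timepoint count, as real whole-brain data do,
so the lossless-PCA path is always exercised.

Defaults are the package's study conditions: a 12 × 10 grid, 4 runs of 300
timepoints, correlation length 1.5 grid units, noise SD 0.5, 1300
cortex-like and 650 subcortex-like sources. `manifold_curvature` (default
0) rolls the latent coordinate sheet onto a cylinder — an isometry, so
intrinsic geodesic distances are untouched while ambient chord distances
contract. At the canonical curved setting of 0.5 rad per grid unit the
11-unit eccentricity axis bends through ≈ 1.75π, far past the half-turn at
which linear methods must fold the sheet; this is what gives manifold
learners (Isomap, spectral, diffusion) their measurable advantage over PCA
in the benchmark suite.

The generator does **not** model haemodynamics, spatial smoothing on a
folded cortical surface, inter-subject anatomical variability, or any
difference between task states: "tasks" in `run_experiment()` are
independently seeded recordings with identical statistics, and `noise_sd`
and `correlation_length` are the only proxies for data quality. Passing
benchmarks on these simulations therefore demonstrates correctness of the
pipeline and the qualitative algorithm ordering under a known ground truth —
not performance on real fMRI.

## Benchmark problem sizes

The package's benchmark suite (and `tests/testthat/test-acceptance.R`) runs
the full pipeline on 10 generator seeds at the default study conditions,
with the optimiser budget set to 25 iterations (8 random starts) per free
parameter; on these grids the accuracy-versus-parameter profiles are broad
and unimodal, so this reduced budget selects parameters equivalent to the
default 100/10 while keeping a complete 10-seed × 3-algorithm ×
3-source-mode sweep to a few minutes. Statistical oracles use Monte-Carlo
references of 10⁵–10⁶ replicates.

## A minimal end-to-end run

```{r example, eval = FALSE}
subj <- simulate_subject(sim_config(seed = 1))
records <- run_subject(
  subj$roi, list(cortex = subj$cortex, subcortex = subj$subcortex),
  subj$truth,
  algorithms = c("spectral_knn_unweighted", "isomap", "pca"),
  source_modes = "all", seed = 1, budget = 25, n_random = 8
)
records |> dplyr::group_by(algorithm, map_type) |>
  dplyr::summarise(abs_r = mean(abs_r), .groups = "drop")
plot_accuracy(records)
```

## Known limitations

* Polar angle is treated as linear; reconstructions of maps that wrap
  across the measured range would be penalised even when topographically
  correct.
* The GP optimizer uses fixed kernel hyperparameters; for objectives much
  rougher than the accuracy surfaces seen here, marginal-likelihood tuning
  would be preferable.
* `within_roi` fingerprints scale as `N²` in the ROI size; the dense
  eigendecompositions scale as `N³`. Both are comfortable at `N ≈ 10²–10³`
  (the regime connectopic ROIs live in) but the code makes no attempt at
  sparse solvers beyond that.
* File I/O is plain CSV + JSON; neuroimaging container formats (GIFTI/CIFTI)
  are out of scope, and inputs from real data must arrive as
  vertices × timepoints matrices with run boundaries.
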