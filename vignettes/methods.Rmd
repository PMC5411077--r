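---
title: "Joint NMF clustering of multi-omics data: model, selection measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint NMF clustering of multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsnmf)
```

## The model and its assumptions

`omicsnmf` clusters `n` samples measured on `m` omics platforms. Each layer
is a non-negative matrix `X^i` (`n × p_i`); the model is the joint
factorization

$$X^i \approx W H^i, \qquad W \ge 0,\; H^i \ge 0,$$

with one basis matrix `W` (`n × k`) **shared across layers** and
layer-specific coefficient matrices `H^i` (`k × p_i`). The fitted criterion
is the weighted squared Frobenius norm

$$Q = \sum_{i=1}^m \theta^i \, \lVert X^i - W H^i \rVert_F^2 .$$

Assumptions worth stating explicitly:

* **Non-negativity is structural, not statistical.** No distribution is
  assumed for any layer; inputs only need to be non-negative and roughly
  comparable in scale. The preprocessing helpers (`shift_nonnegative()`,
  `rescale_unit_max()`, applied per layer by `prepare_collection()`)
  establish exactly that and nothing more. Platform-specific normalization
  (library size, beta/M-values) is assumed done upstream.
* **One clustering explains all layers.** The shared `W` is the integration
  assumption: samples have a single latent group structure expressed, with
  different feature loadings, in every platform. Layers with group structure
  of their own that contradicts the shared one will blur the fit rather than
  be detected.
* **Clusters are read off `W` by row argmax.** This is meaningful only under
  a fixed column-scaling convention (below).

## Fitting: exact alternating NNLS

`Q` is convex in `W` for fixed `{H^i}` and in each `H^i` for fixed `W`, so the
fit alternates exact non-negativity-constrained least-squares solves: each
feature column of `X^i` gives an independent NNLS problem for `H^i` with
design `W`; each sample row of `W` gives an independent NNLS problem with the
vertically stacked design `[√θ^1 (H^1)^T; …; √θ^m (H^m)^T]`. Exact
minimization of each block guarantees the objective trace is non-increasing
(asserted in the test suite to relative `1e-8`), a property multiplicative
update rules only approximate. ALS also needs no initialization of the `H^i`
and cannot suffer the zero-locking of multiplicative updates.

The NNLS kernel is a Lawson–Hanson active-set iteration on the normal
equations, compiled with `RcppArmadillo`. The Gram matrix `A'A` and the
cross-products `A'B` are formed once per multi-column call — the part of the
fast combinatorial (shared-passive-set) strategy that dominates its benefit
at `k ≤ 8` unknowns — and each column is then solved independently, which
makes the multi-column result *identical* to per-column solves by
construction rather than by testing. Rank-deficient passive sets (transiently
empty clusters) fall back to the least-norm solution via the pseudoinverse;
an all-zero design column yields a zero solution row and a warning rather
than an error, because a cluster that empties during early iterations can
refill later.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | number of clusters; scan 2..8 with `scan_k()` if unknown |
| `theta` (layer `weight`) | 1 | layer weight in `Q`; `set_weights(coll, "auto")` uses `max_j meanSS_j / meanSS_i`, so the most energetic layer gets 1 and all weights are ≥ 1 (dimensionless: meanSS averages the squared entries over all `n · p_i` cells) |
| `n_init` | 30 | multi-starts: 1 deterministic NNDSVD + `n_init − 1` U[0,1] random starts; keep the smallest-`Q` run |
| `tol` | 1e-4 | relative change of the absolute reconstruction error `Σ_i Σ |X^i − W H^i|` below which the run stops |
| `stability_count` | 50 | consecutive iterations with an unchanged connectivity matrix that also stop the run |
| `max_iter` | 200 | hard cap; reaching it flags `converged = FALSE` rather than erroring |

The two stopping rules are combined with OR: connectivity stability is the
primary criterion, the reconstruction-error change a cheap secondary one, and
both trajectories are recorded per iteration so a convergence plot can be
reconstructed from the fit object (or from `run_metadata.json` written by
`run_fit()`).

### Numerical conventions

* **Scale indeterminacy.** `(W D)(D^{-1} H^i)` leaves `Q` unchanged for any
  positive diagonal `D`, but changes row argmaxes of `W`. After every outer
  iteration the columns of `W` are rescaled to unit Euclidean norm with the
  inverse scale on the rows of every `H^i`. Any fixed convention would do;
  unit norm makes the columns directly comparable.
* **Ties** in the row argmax break to the lowest column index; an all-zero
  row is assigned to cluster 1 with a warning.
* **Empty clusters** (a `W` column never the argmax) are allowed and logged,
  not repaired; the selection measures downstream penalize them naturally.
* **NNDSVD** is computed on the column-wise concatenation
  `[√θ^1 X^1 | … | √θ^m X^m]` — only `W` is initialized and `W` is common, so
  the concatenation uses all layers symmetrically with the same weighting as
  the objective. Exact zeros in the construction are replaced by
  `epsilon = 1e-6` to avoid degenerate all-zero columns; the mean-filling
  NNDSVD variants are unnecessary because ALS has no locking. For `m > 1` the
  matrix to decompose is genuinely underdetermined by the method description;
  the concatenation is this package's choice.

## Choosing k

`scan_k()` fits every candidate `k` with `n_init` starts and computes, per
run, three consensus statistics plus RSS, and optionally CPI:

* the **consensus matrix** `C̄` averages the binary co-clustering
  (connectivity) matrices over a run's iterations — entry `(i, j)` is the
  empirical probability the two samples co-cluster along the optimization
  path;
* **silhouette width** on the distance `1 − C̄` (singletons score 0);
* **cophenetic correlation** between `1 − C̄` and the merge heights of its
  average-linkage dendrogram (average linkage is the convention of the NMF
  consensus-clustering literature; the choice is otherwise free);
* **dispersion** `ρ = (1/n²) Σ_{ij} 4(C̄_{ij} − ½)²`, 1 exactly when `C̄` is
  binary;
* **RSS** `Σ_i ‖X^i − W H^i‖²` per run, selected by the elbow = maximum
  discrete second difference of the mean curve over k (the visual
  "inflection point" automated; needs ≥ 3 candidate ks);
* **CPI**: repeatedly split samples into train (fraction 2/3 by default) and
  test; fit on train; obtain predicted test labels from one NNLS solve of
  `min_{W≥0} Σ θ^i ‖X^i_test − W H^i_train‖²`; fit the test samples
  independently; score predicted vs observed labels by adjusted Rand index;
  average over repetitions. Defaults: 20 repetitions, 10 starts for each of
  the train and test fits — the reference description says only "repeated
  several times", so these follow common resampling practice; the scaled-down
  tests use 5 × 5/5 to stay inside their runtime budget. The split is over
  samples only; train and test share features, which is what makes the
  transfer in the NNLS step well-posed.

Silhouette, cophenetic, dispersion and CPI select the `k` with maximum mean
value, ties to the smallest `k`.

### Why the consensus has no burn-in

An earlier draft discarded the first 10 iterations before averaging the
connectivity history. That is wrong for an exact ALS solver: runs at a
*wrong* `k` often converge in fewer than 15 iterations, so after burn-in the
remaining history is constant, the consensus is binary, and silhouette /
cophenetic saturate at 1.0 for `k ≠ k_true` (observed directly: a silhouette
tie of 1.000 at `k = 2` and `k = 3` on `k_true = 3` data). The early,
still-moving assignments are precisely the information that distinguishes an
unstable `k` from a stable one, and the iteration-averaged consensus is
defined over the whole path to convergence. Default `burn_in = 0`
(configurable). An across-runs consensus (one matrix per `k` from the final
labels of all starts) is available via `scan_k(consensus_across_runs =
TRUE)` for comparison.

## External validation metrics

`adjusted_rand_index()` implements the chance-corrected pair-counting
formula from the contingency table; the degenerate-denominator case (both
partitions all singletons, or both one cluster) returns 1 for identical
partitions and 0 otherwise, with a warning. `cluster_purity()` is the
proportion of samples in the majority true class of their predicted cluster.
`cluster_entropy()` is the size-weighted mean Shannon entropy (base 2) of
cluster compositions, normalized by `log2(#true classes)` to lie in `[0, 1]`
— the normalization constant is free in the source material (entropy appears
only in figures there); normalizing makes values comparable across `k`.
`0·log 0 = 0` throughout.

## The synthetic generator: what it emulates, what it does not

`simulate_multiomics()` emulates the simulation design used to validate this
class of methods: `k_true ∈ 2..6` clusters shared by all layers, 25% of each
layer's features differential by default, cluster mean shifts of
`effect_size` (in units of the layer's noise SD, grid 0..4 by 0.5 via
`simulation_grid()`), Gaussian noise, then the standard non-negative shift
and unit-max rescale per layer. Choices where the reference design is silent
or deliberately replaced:

* **Shift geometry.** Each cluster gets a random `±1` sign vector over the
  differential features (redrawn until all `k` vectors are mutually
  distinct), so every cluster pair differs somewhere on the differential set.
  Individual features may fail to separate a particular pair; the set always
  does.
* **Cross-layer correlation.** The original design drew correlation
  structure from TCGA ovarian-cancer data via a simulation package built on
  estimated CpG–gene–protein covariances. That external dependency is
  replaced by a parametric per-sample latent factor added to all layers
  through random per-feature loadings, strength `cross_layer_coupling`
  (default 0.2 — mild, realistic inter-layer correlation; 0 disables it).
  Consequently the generator preserves the *statistical shape* the method
  exploits (shared cluster signal plus shared nuisance correlation across
  layers) but not the empirical covariance of any real platform.
* **Sizes.** Defaults are scaled down (`n = 90`, `p = 60` per layer,
  3 layers) from the reference scale (`n = 384`, `p = 367/131/160`) so the
  full test battery runs in minutes. Cluster sizes follow the requested
  proportions by largest-remainder apportionment (deterministic, never an
  empty cluster), not multinomial draws.
* **Baselines** are standard-normal per feature, `noise_sd = 1`, equal layer
  weights (`θ^i = 1`), matching the equal-weight setting of the reference
  simulations.

A green test on this generator therefore establishes that the pipeline
recovers planted, layer-consistent mean-shift structure at realistic
noise — not that it handles platform-specific distributions (counts, beta
values), outliers, batch effects, or missing samples, none of which the
generator produces.

## Degenerate inputs and edge behavior

* All-zero layers are rejected by `compute_weights()`; all-zero matrices by
  `rescale_unit_max()`.
* `filter_features()` uses the sample SD (`n − 1`) and a *strict* `<` on the
  zero proportion ("less than 50% zeros"); removing every feature is an
  error.
* Sample alignment across layers is by ID with an explicit error on
  mismatch after intersection — silent reordering is the classic integrative
  bug.
* `k` must satisfy `2 ≤ k < n`; NNDSVD errors when the concatenated data has
  rank `< k` (suggesting a smaller `k`).
* A CPI split yielding a single-cluster observed partition is kept (ARI
  handles it) with a warning.

## Known limitations

* The RSS elbow is a heuristic; the curve's second difference can be flat
  for weak signal, and the measure is reported mainly for completeness.
* Dispersion often fails to peak at `k_true` (it rewards any highly stable
  clustering, including stable wrong ones); this mirrors the reference
  findings and is why CPI/silhouette/cophenetic drive `select_k()` in
  practice.
* Runtime grows linearly in `n_init` and in the number of CPI repetitions;
  the exact NNLS solves make each iteration `O(n · p · k)` with small
  constants, but very large `p` (tens of thousands of features) should be
  pre-filtered with `filter_features()` as in the real-data workflows.
* No missing-data support: layers must be complete on the shared samples.
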