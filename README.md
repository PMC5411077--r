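# omicsnmf

Integrative clustering of multi-omics data by joint non-negative matrix
factorization.

## The problem

Molecular subtypes of disease — cancer above all — rarely announce themselves
in a single data platform. A study typically measures several omics layers on
the same tumors (mRNA expression, DNA methylation, protein abundance, copy
number), and a weak but *consistent* grouping signal spread across layers is
easily missed when each platform is clustered separately and the results are
reconciled by hand. `omicsnmf` clusters the samples using all layers at once,
with no distributional assumptions about any of them.

## The model

Let `X^i` (`n × p_i`, `i = 1..m`) be non-negative matrices measuring `p_i`
features on the same `n` samples. The model factorizes every layer against a
*common* basis matrix `W`:

```
X^i ≈ W H^i ,   W (n × k) ≥ 0,  H^i (k × p_i) ≥ 0
```

fitted by minimizing the weighted squared Frobenius objective

```
Q = Σ_i  θ^i ‖X^i − W H^i‖²_F ,    θ^i > 0
```

with alternating non-negativity-constrained least squares (NNLS): given `W`,
each `H^i` is an exact NNLS solve; given all `H^i`, each row of `W` is an
exact NNLS solve against the stacked, `√θ^i`-scaled coefficient matrices.
Both half-steps are exact minimizations, so `Q` never increases. Sample `j`
is assigned to cluster `argmax_c W[j, c]`.

Because only `W` needs initializing, the fit runs from one deterministic
NNDSVD start plus uniform-random restarts and keeps the run with the
smallest `Q`.

The number of clusters `k` is chosen by scanning a candidate range and
comparing five statistics: average silhouette width on the distance
`1 − C̄` (where `C̄` is the consensus matrix, the average over the fit's
iterations of the binary sample-co-clustering matrix), the cophenetic
correlation of `1 − C̄`, the dispersion coefficient
`(1/n²) Σ 4(C̄_ij − ½)²`, the residual-sum-of-squares elbow, and a
cross-validated **cluster prediction index** (CPI): train/test-split the
samples, fit on train, transfer the trained `H^i` to predict test labels by
one NNLS solve, cluster the test samples independently, and score the
agreement by adjusted Rand index. CPI peaks where the factors generalize —
at the true `k`.

## Worked example

```r
library(omicsnmf)

# three synthetic layers, 90 samples, 3 true clusters, effect size 3.5
spec <- simulation_spec(k_true = 3, n = 90, effect_size = 3.5, seed = 7)
sim  <- simulate_multiomics(spec)
sim$collection
#> multi_omics: 3 layers on 90 shared samples
#>   [1] 'layer1' 60 features, weight = 1
#>   [2] 'layer2' 60 features, weight = 1
#>   [3] 'layer3' 60 features, weight = 1

fit <- run_multistart(sim$collection, k = 3, n_init = 10, base_seed = 42)
fit
#> nmf_fit: k = 3, 90 samples, 3 layers; 5 iterations (reconstruction_error)
#>   final objective Q = 76.8889
#>   cluster sizes: 30 30 30
adjusted_rand_index(fit$labels, sim$truth)
#> [1] 1

prof <- scan_k(sim$collection, k_range = 2:6, n_init = 10, base_seed = 42,
               cpi = cpi_config(n_repeats = 5, n_init_train = 5,
                                n_init_test = 5))
prof
#> k_profile over k = 2, 3, 4, 5, 6
#>   silhouette  mean: 0.877 0.994 0.936 0.857 0.813 -> k = 3
#>   cophenetic  mean: 0.992 1.000 0.998 0.992 0.988 -> k = 3
#>   dispersion  mean: 0.936 0.986 0.944 0.920 0.915 -> k = 3
#>   rss         mean: 156.366 76.934 73.212 70.607 68.485 -> k = 3
#>   cpi         mean: 0.078 1.000 0.849 0.706 0.582 -> k = 3
```

Reading the output: the fit recovered the planted three-cluster structure
exactly (adjusted Rand index 1 against the generator's truth labels), and
every selection measure attains its maximum (minimum-elbow for RSS) at
`k = 3`. CPI separates most sharply: trained factors transfer to held-out
samples perfectly at the true `k` (1.000) and increasingly poorly away from
it.

Real data enter through delimited text (samples in rows, feature IDs in the
header, sample IDs in column 1):

```r
expr <- read_matrix("expression.csv")
expr <- filter_features(expr, sd_min = 1.5)        # e.g. variable mRNAs
meth <- read_matrix("methylation.csv")
coll <- multi_omics(list(expr, meth))               # aligned on sample IDs
coll <- prepare_collection(coll)                    # shift >= 0, max = 1
coll <- set_weights(coll, "auto")                   # theta from mean squares
fit  <- run_multistart(coll, k = 4, n_init = 30, base_seed = 1)
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "omicsnmf", package = "omicsnmf"))')
Rscript $CLI simulate --k-true 3 --n 90 --p 60,60,60 --effect-size 3.5 \
    --seed 7 --out-dir sim/
Rscript $CLI fit --config run.json --k 3 --n-init 30 --seed 1 --out-dir fit/
Rscript $CLI select-k --config run.json --k-min 2 --k-max 8 --measure all \
    --seed 1 --out-dir selk/
```

`fit` writes `labels.tsv`, `W.csv`, `H_<i>.csv`, `consensus.csv` and
`run_metadata.json`; `select-k` writes a tidy `k_profile.tsv` and a
`k_selection.json` summary. All outputs are byte-reproducible given the seed.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the model, the
selection statistics, what the synthetic generator does and does not emulate,
and the numerical choices (column normalization, stopping rules, burn-in,
tie-breaks).
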