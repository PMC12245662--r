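# forestability

Benchmarking random-forest implementations by the *reproducibility* of
their AUC, not just its mean — for short biomarker signature discovery.

## The problem

Short diagnostic signatures (a handful of genes or miRNAs out of
thousands) are usually developed by comparing classifier implementations
on their mean validation AUC. But two implementations with the same mean
AUC can behave very differently when refitted: one returns the same AUC
every time, the other scatters. For a clinical signature the scattering
implementation is the riskier choice, and the mean AUC alone cannot see
the difference.

`forestability` quantifies that difference. For every candidate signature
*s* and every balanced train/validation resampling *n*, it fits *q*
replicate models that differ only in the ensemble's internal
randomisation, and measures the dispersion of the replicate AUCs by their
coefficient of variation

    CV(s, n) = sd(AUC_1, ..., AUC_q) / mean(AUC_1, ..., AUC_q).

A combination is **hyper-stable** when `CV == 0`, i.e. all *q* models give
bit-identical AUCs, and **relatively stable** at threshold *t* when
`CV <= t`. The S×k binary matrix of stable combinations (the "dot
matrix") is summarised by two scores:

* `HR(n) = S0 / S` — fraction of signatures stable on resampling *n*;
  **HRS** is the mean of the nonzero `HR` values (Resampling Sensitive).
* `HS(s) = k0 / k` — fraction of resamplings on which signature *s* is
  stable; **HSS** is the mean of the nonzero `HS` values (Signature
  Sensitive).

At `t > 0` the same aggregates are called **RRS/RSS**. Both lie in
`[0, 1]`; a deterministic implementation scores 1/1. The pattern of the
dot matrix further classifies an implementation as *signature dependent*
(blank rows), *resampling dependent* (blank columns), *mixed*, or
*unclassified* when almost nothing is stable.

Around the scores the package provides the full pipeline: variance
prefiltering and rank-based feature selection (impurity + permutation
importance, validated by the Kuncheva consistency index and Spearman rank
correlation), random signature planning (`3·(Nv′ − 2)` signatures, three
per size from 2 to `Nv′ − 1`), stratified balanced resampling without
replacement, out-of-bag tree-count tuning, and a pluggable backend
contract with two reference forests (`randomForest`, and `extraTrees` via
ranger) plus deterministic `_fixed` variants. A synthetic generator of
paired, RPKM-like two-class expression data makes everything testable
offline.

## Worked example

```r
library(forestability)

# paired two-class dataset, 4 informative features of moderate effect
ds <- simulate_expression(n_pairs = 10, n_features = 8, n_informative = 4,
                          effect_size = 3, seed = 11)

res <- run_benchmark(ds, c("randomForest_fixed", "randomForest", "extraTrees"),
                     selected_features = paste0("g", 1:4),
                     k = 5, q = 5, ntree = 60, seed = 11)
res
#> BenchmarkResult: 3 backend(s), S=6 signatures, k=5 partitions, q=5 replicates, t=0
#>           backend_id resampling_score signature_score combined_score mean_auc
#> 1 randomForest_fixed           1.0000          1.0000          2.000   0.9973
#> 2         extraTrees           1.0000          1.0000          2.000   1.0000
#> 3       randomForest           0.8667          0.8667          1.733   0.9956
#>   mean_runtime_seconds dependency_class
#> 1            0.0009667            mixed
#> 2            0.0075667            mixed
#> 3            0.0009533            mixed
```

Read: 6 signatures (three each of sizes 2 and 3 from the 4 selected
features) × 5 resamplings × 5 replicates = 150 models per backend. The
deterministic variant is hyper-stable by construction (HRS = HSS = 1).
Plain `randomForest` reaches almost the same mean AUC (0.9956) but
reproduces it exactly on only part of the grid — HRS = HSS = 0.87 — which
is precisely the information the mean AUC hides. Runtime is reported as a
tie-break between equally stable backends and never enters the scores.

Per-backend detail, including the HR/HS vectors and the dot matrix, lives
in `res$reports`; grids persist to TSV and can be re-scored at other
thresholds without refitting:

```r
write_auc_grid(res$grids$randomForest, "grid.tsv")
score_grid_file("grid.tsv", t = 0.002)   # relative stability, RRS/RSS
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/forestability.R` with verbs `benchmark`, `score`, `tune-ntree`,
`select-features`, `plan-signatures` and `simulate`.

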