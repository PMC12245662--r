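---
title: "Hyper-stability benchmarking of random-forest implementations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyper-stability benchmarking of random-forest implementations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Motivation and model

When a short biomarker signature (a few features out of thousands) is
selected by comparing classifier implementations, the usual yardstick is
the mean validation AUC over resamplings. That yardstick is blind to a
second, practically important axis: whether an implementation *reproduces*
its AUC when refitted with a different internal random state. Two
implementations with indistinguishable mean AUCs can differ sharply in
how often a refit returns the same number, and for downstream clinical
use the less reproducible one carries hidden risk.

`forestability` measures that axis directly. The experimental unit is a
**cell**: one candidate signature $s$ (a feature subset) crossed with one
balanced train/validation partition $n$. In each cell, $q$ replicate
forests are fitted that differ *only* in the ensemble's internal
randomisation (bootstrap draws, candidate-split sampling); training rows,
features, and hyper-parameters are held fixed. The replicate validation
AUCs $A_1, \dots, A_q$ are summarised by their coefficient of variation,

$$\mathrm{CV}(s, n) = \frac{\mathrm{sd}(A_1, \dots, A_q)}{\bar A},$$

using the sample standard deviation (denominator $q - 1$). A cell is

* **hyper-stable** when $\mathrm{CV} = 0$ — equivalently, all $q$ AUCs are
  bit-identical (the implementation tests this directly rather than
  comparing a floating-point quotient to zero);
* **relatively stable at threshold $t$** when $\mathrm{CV} \le t$.

Collecting the stable/unstable outcomes over all $S$ signatures and $k$
partitions gives an $S \times k$ binary **dot matrix** $D$. It is reduced
to two scores:

* per partition, $HR(n) = S_0 / S$, the fraction of signatures stable on
  partition $n$; the **resampling-sensitive score** $HRS$ is the mean of
  the *strictly positive* $HR$ values (and defined as 0 when the whole
  matrix is unstable);
* per signature, $HS(s) = k_0 / k$, the fraction of partitions on which
  signature $s$ is stable; the **signature-sensitive score** $HSS$ is the
  mean of the strictly positive $HS$ values.

At $t = 0$ these are the hyper-stability scores $HRS$/$HSS$; at $t > 0$
the same formulas yield the relative-stability scores $RRS$/$RSS$.
Restricting the means to positive entries makes the scores answer "*when*
an implementation is stable somewhere, how consistently is it stable?",
separating the amount of instability from its structure. The structure
itself is classified from the blank rows and columns of $D$ (see
*Dependency classification* below).

Both scores lie in $[0, 1]$. A fully deterministic implementation scores
$HRS = HSS = 1$; a stochastic one typically scores lower at $t = 0$ and
approaches 1 as $t$ grows, and the scores are non-decreasing in $t$ by
construction.

## The benchmarking procedure

For each implementation (backend) under test:

1. **Feature selection.** Features are optionally prefiltered by variance
   of $\log_2(x + 1)$, then ranked by the mean of the rank positions of
   two averaged importance measures — impurity decrease and permutation
   importance — over `n_repeats` fits (`rank_features()`). Ties are broken
   by ascending feature identifier so rankings are total and reproducible.
   `select_stable_size()` picks the smallest candidate signature size
   whose top-$N$ sets are consistent across resamplings, requiring both
   the Kuncheva consistency index and the Spearman correlation of
   aggregate ranks to reach their floors (both default 0.6). If no size
   qualifies, the size with maximal Kuncheva index is returned with
   `met_floors = FALSE` so the caller can see the selection is forced.
2. **Signature planning.** From the $N_{v'}$ selected features,
   `plan_signatures()` draws three distinct random subsets per size for
   every size from 2 to $N_{v'} - 1$, giving $S = 3(N_{v'} - 2)$
   candidate signatures. Size-1 subsets are excluded (a single feature
   has no subset structure to vary) and the full set is excluded (it is
   the selection itself, not a shorter candidate); this range also keeps
   the planned count formula exact for every $N_{v'} \ge 3$. The full
   search space for context is $2^{N_{v'}} - 1$ subsets.
3. **Resampling.** `make_partitions()` builds $k$ balanced partitions:
   within each class, `round_half_up(P × class size)` samples are drawn
   without replacement for training and the rest validate. Rounding is
   explicit round-half-up rather than R's banker's rounding so the split
   sizes are unambiguous. With `pair_aware = TRUE`, tumor/normal pairs
   move as a unit so no pair straddles the train/validation boundary.
4. **Tree-count tuning.** `tune_ntree()` evaluates a grid of ensemble
   sizes by mean out-of-bag error over $k \times q$ fits per grid value
   and picks the smallest value that is within `plateau_tolerance`
   (default 0.005) of the minimum *and stays within it for all larger
   grid values* — the start of the plateau, not a local dip.
5. **The grid.** `run_grid()` fits $S \times k \times q$ models and
   records every AUC and its wall time. `stability_report()` derives the
   CV matrix, dot matrix, $HR$/$HS$ vectors, scores, a threshold sweep
   over $t \in \{0, 0.002, 0.004, 0.008\}$, and the dependency class.
6. **Ranking.** `run_benchmark()` ranks backends by
   `combined_score = resampling_score + signature_score` (descending),
   breaking ties by mean runtime (ascending). Runtime is *only* a
   tie-break; it never enters the scores.

### Dependency classification

With blank-row fraction $r$ and blank-column fraction $c$ of the dot
matrix: a matrix with stable-cell density below `min_density` (default
0.05) is *unclassified*; $r \ge 0.2$ with $c < 0.2$ is
*signature dependent* (instability concentrates in particular
signatures); the reverse is *resampling dependent*; everything else is
*mixed*.

## Backends and determinism

A backend is a pair of functions (`fit_fun`, `importance_fun`) wrapped by
`forest_backend()` and registered by name. Two references ship with the
package: `randomForest` (Breiman–Cutler forests via the randomForest
package) and `extraTrees` (extremely randomised trees via ranger with
`splitrule = "extratrees"`, probability forests, `min.node.size = 1`,
single-threaded). Each has a `_fixed` variant in which every replicate in
a cell receives the *same* seed, making the backend hyper-stable by
construction — a built-in positive control.

Replicate seeds are derived by hashing
`(base seed, backend, signature, partition, replicate)` into
$[1, 2^{31} - 2]$, so every model's seed is a pure function of its
coordinates: reruns of a benchmark reproduce every AUC bit-for-bit, cells
can be computed in any order, and only the measured wall times differ
between runs.

## Synthetic data

`simulate_expression()` emulates paired two-class expression cohorts:
for each of `n_pairs` pairs it draws log-scale Gaussian features with
optional block-equicorrelation (`block_size`, `within_block_corr`), adds
a shared per-pair intercept (`pair_sd`, default 0.25) that correlates the
tumor and healthy member of a pair, shifts the first `n_informative`
features of the tumor member by `effect_size × noise_sd`, and
exponentiates so values are positive and RPKM-like in shape. Three
presets (`brca_like`, `lusc_like`, `thca_like`: 91/48/49 pairs) mirror
cohort sizes at which the planner yields 78/21/108 signatures from
28/9/38 selected features.

The generator is deliberately simple: it captures pairedness, skewed
positive values, correlation blocks, and a controllable class effect. It
does **not** emulate sequencing-depth normalisation artefacts, batch
effects, zero inflation, or heavy-tailed outliers — it exists to make the
benchmarking machinery testable against known ground truth, not to
replace real cohorts.

## Defaults and numerical choices

| Parameter | Default | Rationale |
|---|---|---|
| `t` (CV threshold) | 0 | hyper-stability first; sweep `{0, 0.002, 0.004, 0.008}` shows sensitivity |
| `P` (training fraction) | 0.5 (benchmark), 0.9 (tuning) | half-split stresses stability; tuning wants near-full training data for an honest OOB curve |
| `k`, `q` | 50, 25 | 1250 fits per configuration; small enough per-cell to be cheap, large enough for stable fractions |
| `ntree` grid | 10–100 by 10, then 150–1200 by 50 | dense where OOB error moves fastest, coarse on the plateau |
| `plateau_tolerance` | 0.005 | half a percentage point of OOB error — below practical relevance |
| Kuncheva / Spearman floors | 0.6 / 0.6 | "clearly better than chance-level overlap" on both set and rank consistency |
| blank row/col fractions, `min_density` | 0.2 / 0.2 / 0.05 | classification needs a fifth of rows or columns blank to call a direction, and any call needs ≥ 5% stable cells |
| `pair_sd` | 0.25 | mild within-pair correlation, visible but not dominant |

Tests exercise the pipeline at reduced sizes (e.g. $k = q = 5$,
`ntree` 40–100, cohorts of 10–20 pairs); these are the package's own
choices for fast, seeded verification, and all score definitions are
independently checked against a brute-force counting oracle on random
dot matrices.

## Limitations

* Stability is measured for *AUC under refitting*, conditional on a fixed
  signature and partition; it says nothing about stability under data
  perturbation beyond the $k$ partitions used.
* The CV is undefined for a zero mean AUC; cells with non-positive mean
  are flagged rather than scored (they cannot occur for genuine AUCs).
* Only binary classification with a designated positive class is
  supported.
* Wall-time measurements depend on the host and are therefore excluded
  from all scores and from reproducibility guarantees.

## A minimal run

```{r}
library(forestability)

ds <- simulate_expression(n_pairs = 10, n_features = 8, n_informative = 4,
                          effect_size = 3, seed = 11)
res <- run_benchmark(ds, c("randomForest_fixed", "randomForest", "extraTrees"),
                     selected_features = paste0("g", 1:4),
                     k = 5, q = 5, ntree = 60, seed = 11)
res                               # ranking table
res$reports$randomForest          # scores, HR/HS vectors, sweep, class
write_auc_grid(res$grids$randomForest, "grid.tsv")
score_grid_file("grid.tsv", t = 0.002)   # re-threshold without refitting
```
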