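---
title: "Building and assessing Mutual Rank coexpression platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and assessing Mutual Rank coexpression platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexbuild)
```

## The model

Gene coexpression — correlated expression across many conditions — is the
workhorse proxy for shared function in transcriptome compendia. A
*coexpression platform* is the gene × gene coexpression matrix of one species
measured with one technology. `coexbuild` constructs such platforms with a
PCA-subsampling ensemble and scores them with pathway-based and
cross-platform statistics.

### Preprocessing

RNA-seq count matrices are filtered before anything else:

* **Run depth.** Runs with total mapped counts strictly below
  `min_total_counts` (default 2 000 000) are discarded, because low-depth
  runs measure lowly expressed genes unreliably. A run summing *exactly* to
  the threshold is kept — the discard condition is a strict `<`.
* **Gene expression level.** After the depth filter, genes whose mean count
  across the retained runs is strictly below `min_mean_count` (default 30)
  are removed. The order matters: gene means are computed on the
  depth-filtered samples. The reverse order would let low-quality runs drag
  gene means down; computing means post-filter matches the order in which
  the filters are stated and is what we fix here.
* **Log transform.** `log2(x + pseudocount)` with pseudocount 0.125, mapping
  a zero count to exactly −3.
* **Centering.** Each gene's mean is subtracted, the form PCA expects.

Microarray intensities arrive already on a log scale (e.g. RMA-summarized)
and enter at the centering step; the count filters do not apply. Batch
correction (e.g. ComBat) is an upstream step performed by established tools:
`preprocess_expression(corrected = ...)` accepts a corrected matrix and
substitutes it for the log-transformed one before centering. Missing values
are rejected on construction: the pipeline's inputs are complete
post-normalization matrices, and silently imputing would hide upstream
problems.

### The PCA-subsampling ensemble

With the centered genes × samples matrix $X$, the SVD $X = U D V^\top$
yields principal components; components beyond the 1000th (or beyond the
numeric rank) are dropped — they carry little variance and dominate the
computational cost at compendium scale. Then, for each of `n_repetitions`
(default 1000) repetitions:

1. a fraction (default 10%, i.e. 100 of 1000 kept PCs) of the components is
   drawn uniformly without replacement — we subsample uniformly because no
   variance weighting is part of the design; the draw count is
   $k = \max(1, \mathrm{round}(f \cdot n_{\text{kept}}))$;
2. gene profiles are reconstructed from the drawn subset only,
   $\hat X = U_S D_S V_S^\top$, and Pearson correlation is computed between
   reconstructed profiles. This reconstruct-then-correlate definition is
   fixed by its limit property: selecting *all* kept components of a
   full-rank decomposition reproduces the ordinary Pearson correlation of
   the input exactly;
3. the correlation matrix is converted to **Mutual Rank**:
   $\mathrm{rank}(a \to b)$ is the 1-based position of $b$ among all other
   genes sorted by descending correlation with $a$ (self excluded), and
   $\mathrm{MR}(a,b) = \sqrt{\mathrm{rank}(a \to b)\,\mathrm{rank}(b \to a)}$.
   Ranking is on descending *signed* correlation, so strong anti-correlation
   receives the worst ranks; ties get average (possibly fractional) ranks,
   which is deterministic and independent of gene order.

The repetition-level MR matrices are averaged in logit space: MR is mapped
to $p \in (0,1)$, logit-transformed, averaged entrywise, and mapped back.
The default map is the half-rank-shifted affine map

$$p = \frac{\mathrm{MR} - 1 + 1/2}{(n-2) + 1} = \frac{\mathrm{MR} - 1/2}{n - 1},$$

chosen because the attainable MR range $[1, n-1]$ maps strictly inside
$(0,1)$: the logit is always finite, no clipping is needed, and an ensemble
of identical matrices aggregates to itself *exactly* — the fixed-point
property a sane average must have. The unshifted map
$p = (\mathrm{MR}-1)/(n-2)$ with symmetric $\varepsilon$-clipping
($\varepsilon = 1/(2(n-2))$) is available via `shift = 0`, but it distorts
boundary values (MR 1 and $\sqrt 2$ both clip to 1.5) and is therefore not
the default. Under any affine map, logit averaging is antisymmetric:
$p$-values 0.2 and 0.8 average to exactly 0.5.

The MR diagonal stores a sentinel 0 ("self") that never enters any
statistic. A repetition in which some gene reconstructs with zero variance
under the drawn subset contributes only its defined pairs; affected pairs
are averaged over the remaining repetitions and a warning reports the count.
Reproducibility: one master seed spawns one child seed per repetition, so
the result is identical regardless of execution order.

### KEGG score: weighted partial AUROC

Pathways are restricted to the platform's genes and filtered to sizes
$2 \le s < 50$: only small, specific pathways constitute sharp functional
hypotheses, and the strict `<` mirrors the filter semantics above. Every
unordered pair of annotated genes is labeled positive iff the two genes
share a retained pathway. A positive pair's weight is the *largest inverse
size* among its shared pathways — the most specific shared annotation is the
strongest evidence, and this weighting also makes the statistic robust to
the exact size threshold (`weight_mode = "sum_inverse_size"` is the
additive alternative). Negative pairs (annotated genes sharing no pathway)
weight 1; restricting the negative universe to annotated genes keeps the
null within genes of known function rather than diluting it with
unannotated ones.

Pairs are ranked by ascending MR; the weighted ROC accumulates positive
weight on the TPR axis and negative counts on the FPR axis, ties advancing
both jointly (trapezoidal interpolation). The partial area $A$ from FPR 0 to
`fpr_max` (default 1%) is standardized as

$$\mathrm{score} = \frac12\left(1 + \frac{A - A_{\min}}{A_{\max} - A_{\min}}\right),
\qquad A_{\min} = \tfrac{f^2}{2},\; A_{\max} = f,$$

so a random ranking scores 0.5, perfect separation scores 1, and at
$f = 1$ the score reduces to the plain AUROC. We chose this standardization
over reporting $A/f$ because it gives the statistic a fixed, interpretable
null point: the raw rectangle normalization leaves the random-ranking
expectation at $f/2$ (0.005 at the default cutoff), which changes with the
cutoff and invites misreading. The raw $A/f$ value is also returned
(`pauc_raw`). Because the statistic only consumes ranks, it is invariant
under any strictly monotone transform of MR.

### Cross-platform similarity and supportability

Platforms from different species are compared through a one-to-one ortholog
map. Over the genes common to all platforms, every unordered gene pair's MR
value is collected per platform ($g$ genes give $g(g-1)/2$ pairs; 180 common
orthologs give 16 110), and platform similarity is the Spearman correlation
of those columns — rank-based, hence indifferent to any monotone rescaling
of MR. The similarity matrix is clustered with complete linkage on the
correlation distance $1 - \rho$; leaf order is the deterministic order
`stats::hclust()` assigns for the given input order.

Per-guide-gene reproducibility uses top-list coincidence. For a guide gene,
its coexpressed-gene list (all shared genes ranked by ascending MR, ties
broken lexicographically for determinism) is compared with the orthologous
guide's list in a reference platform over the genes shared by the two
platforms: with $k = \lceil f \cdot |\text{universe}| \rceil$ (default
$f = 1\%$; the ceiling guarantees $k \ge 1$), the statistic is

$$\mathrm{COXSIM} = \frac{\sum_{g \in T_a \cap T_b} w(r_a(g))\, w(r_b(g))}
{\sum_{r=1}^{k} w(r)^2}, \qquad w(r) = \frac{1}{\log_2(r+1)},$$

a log-discounted rank overlap normalized by its self-overlap maximum:
identical top-$k$ rankings score exactly 1, disjoint top-$k$ sets exactly 0,
and agreement at early ranks counts most. The discount function is
pluggable (`weight_fn`); the log discount is the standard choice for
top-weighted list agreement and preserves exactly the extreme-value
behaviour the statistic needs. **maxCOXSIM** is the maximum over reference
platforms, and *supportability* discretizes maxCOXSIM into quartile levels
0–3 across the platform's guide genes; values tied with a quartile boundary
get the lower level, so high levels are conservative. Guides with no
ortholog in any reference are reported `NA` and excluded from the quartiles.

## The synthetic-data generator

`module_spec()` describes a planted-structure dataset: modules of genes
driven by a shared standard-normal latent factor with loading
$a = \sigma\sqrt{\rho/(1-\rho)}$ against noise of sd $\sigma$, so the
expected within-module Pearson correlation is exactly $\rho$
(`within_corr`); background genes are independent with matched total
variance. Per-gene baselines are drawn from $N(7, 1.5^2)$ on the log2 scale,
and the count-scale output draws Poisson counts with mean $2^{x}$ — baseline
counts around $2^7 = 128$ straddle the mean-30 gene filter realistically.
Defaults (5 modules × 10 genes, 50 background genes, 50 samples,
`within_corr` 0.8, `noise_sd` 1) are a desk-scale caricature of a compendium
with a handful of strong transcriptional programs.

`generate_platform_family()` emulates cross-species families: a chosen
fraction of modules keeps identical membership across platforms, the rest
are platform-private regroupings, `divergence` perturbs shared memberships,
and ortholog maps are identity renamings. What the generator deliberately
does **not** model: library-size and dispersion structure of real RNA-seq,
probe effects, batch structure, many weak modules, or correlated background.
Passing tests therefore demonstrate that the machinery recovers planted
rank structure under Gaussian factor noise — not that any particular real
compendium reaches a given score.

One scaling consequence: the production depth threshold (2 000 000 counts)
presumes a transcriptome-sized gene set (~20 000 genes, i.e. ~100 counts per
gene). Synthetic panels of 50–100 genes are held to the same *per-gene*
depth, so examples and tests use `min_total_counts = 100 × n_genes` while
the configuration default remains the production constant.

## Numerical choices and degenerate inputs

* PC truncation keeps `min(max_pcs, numeric rank)` components; the rank
  tolerance is `max(dim) * eps * d[1]`, the standard SVD cutoff. Fewer than
  3 samples is an error.
* Correlation ties in MR ranking: average ranks, then the geometric mean of
  the possibly fractional ranks — deterministic and order-independent.
* `subsample_pcs()` uses the session RNG; `build_platform()` derives one
  child seed per repetition from the master seed, making repetitions
  order-independent, and restores the caller's RNG state afterwards.
* `fraction = 1` with `n_repetitions = 1` collapses the whole ensemble to
  classic Pearson Mutual Rank (verified to 1e-8 in the tests).
* Degenerate reconstructed profiles yield `NA` correlations for their pairs
  in that repetition; other genes are ranked among the valid correlates, and
  aggregation averages each pair over its non-missing repetitions.
* `weighted_partial_auroc()` requires both classes present; an all-tied
  score vector yields the diagonal ROC and score 0.5.
* Quartile levels on fewer than 4 distinct values collapse by the tie rule
  (lower level wins), the documented degenerate behaviour when a platform is
  compared against an exact copy of itself.

## Problem sizes used in tests and the acceptance script

Desk-scale runs use 50–100 gene panels, 25–60 samples, 8–50 repetitions and
subsample fractions 0.3–0.5 — large enough for the planted structure to be
recoverable and for every identity to be checked exactly, while the whole
suite runs in seconds. With low-rank synthetic matrices an aggressive
subsample fraction (10% of ~40 PCs) often misses the few module-carrying
components, diluting MR contrast; production compendia, whose signal spreads
over hundreds of components, are the regime the 10% default is designed
for. Moderate fractions on synthetic data also show the ensemble's point:
at `fraction = 0.5` cross-platform similarity of structurally identical
platforms exceeds the single-shot `fraction = 1` result.

## Known limitations

* The construction is dense (genes × genes): platforms beyond ~20 000 genes
  need blocked or out-of-core computation, which this package does not do.
* The COXSIM rank discount is a documented stand-in for the weighting of the
  coincidence statistic in prior database releases, preserving its extremes
  and rank sensitivity but not claiming numerical equivalence.
* The pAUC standardization is likewise a documented scale choice; scores are
  comparable across platforms evaluated with the same settings, which is all
  the quality comparisons require.
* No annotation fetching: pathway sets arrive as user-supplied GMT files;
  ortholog maps are user-supplied one-to-one tables.
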