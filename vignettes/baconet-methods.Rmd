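---
title: "Methods: balanced correlation networks for buffering prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced correlation networks for buffering prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baconet)
```

## The model

The input is a pair of cell-line-by-gene matrices over a shared panel of
cancer cell lines: expression $E$ on the log2(TPM+1) scale and CRISPR
knockout fitness effects $C$ (Chronos scores; more negative means the
knockout is more deleterious). A *buffering* relationship is an ordered
gene pair: the **buffering** gene contributes its expression column of
$E$, the **buffered** gene its fitness column of $C$. If cell lines that
have lost (or lowly express) gene $A$ compensate through partner $B$,
then knocking out $B$ hurts exactly those lines, so across the panel
$\mathrm{cor}(E_{\cdot B},\, C_{\cdot A})$ — and symmetric variants —
carries the signal. The package scores every ordered (buffering,
buffered) pair through the cross-correlation matrix
$R = \mathrm{cor}(E, C)$ with rows indexed by buffering (expression)
genes and columns by buffered (fitness) genes.

### Preprocessing

`preprocess_pair()` applies fixed, argument-free rules:

* expression genes with panel mean $< 1$ are removed (a mean of exactly
  1.0 is retained — the boundary is strict);
* missing fitness values are imputed with the gene-wise mean;
* the cell-line panels are intersected and ordered lexicographically, so
  every downstream computation (including Cholesky whitening, which
  depends on variable order) is deterministic;
* fitness genes absent from the (filtered) expression matrix are dropped.

## The balancing transform

For each coefficient $r = R_{ij}$ with row $i$ of length $m$ and column
$j$ of length $n$ (so $n + m$ comparator slots including the focal entry
itself, once per axis):

$$
\mathrm{score}_{ij} \;=\; 1 - \frac{\#\{R_{i\cdot} > r - k\} + \#\{R_{\cdot j} > r - k\}}{n + m}
\qquad (r \ge 0)
$$

$$
\mathrm{score}_{ij} \;=\; -1 + \frac{\#\{R_{i\cdot} < r + k\} + \#\{R_{\cdot j} < r + k\}}{n + m}
\qquad (r < 0)
$$

with strict inequalities and slack $k = 0.05$ by default. A pair scores
near $\pm 1$ only when its coefficient is extreme *relative to both its
own row and its own column*; genes with many similarly extreme partners
(lineage co-expression modules, pan-essential fitness profiles) drag
each other's scores down without any batch annotation. Design notes:

* **The focal entry counts itself** in both its row and its column. This
  adds a constant $2/(n+m)$ to every count, so it cannot change any
  ranking; keeping it makes the formula literal and the reference
  implementation trivial.
* **The negative branch is implemented with $-1 + \cdots$** so that
  scores are sign-symmetric: a strongly negative outlier maps near $-1$,
  a typical negative coefficient maps near $0$. Written with a minus the
  branch would map *unexceptional* coefficients to $-2$ and exceptional
  ones to $-1$, destroying the sign symmetry and the interpretation of
  $|score|$ as exceptionality, so the $+$ reading is used.
* **Increasing $k$ shrinks every score toward 0** (in magnitude): more
  slack means more comparators clear the threshold. $k = 0$ reduces to a
  pure two-sided rank statistic; $k$ around the noise scale of the
  coefficients (0.05 for correlations over hundreds of cell lines)
  stops near-ties from being counted as distinct.
* `bacon_balance()` sorts each row and column once and counts via binary
  search (`findInterval`), so the cost is $O(nm\,(\log n + \log m))$
  rather than the literal $O(nm(n+m))$. The literal triple loop is kept
  as `bacon_balance_reference()` and the test suite checks exact
  agreement (tolerance $10^{-12}$) on hundreds of random matrices.

## A priori alternatives

For comparison the pipeline supports normalizations applied *before*
correlation:

* **Whitening across cell lines** (`whiten_cells()`): cell lines are the
  variables, genes the observations; the $k \times k$ cell-line
  covariance $\Sigma$ is estimated over genes and a transform $W$ with
  $W \Sigma W' = I$ is applied. Three standard choices: Cholesky
  ($W = L'$ where $\Sigma^{-1} = LL'$), PCA ($W = \Lambda^{-1/2}U'$,
  with the sign of each eigenvector fixed by its largest-magnitude
  loading so results are deterministic), and ZCA ($W = \Sigma^{-1/2}$).
  When there are fewer genes than cell lines $\Sigma$ is singular and a
  ridge must be added (`whiten_spec(ridge = ...)`); this is the normal
  situation for the desk-scale synthetic panels (hundreds of genes),
  while DepMap-scale matrices (about 19,000 genes, about 1,000 lines)
  are full rank.
* **ComBat** (`combat_adjust()`): delegated to `sva::ComBat`, over
  cell-line batches (lineage, growth pattern) or gene batches
  (chromosome, chromosome arm).
* **Covariate-controlled regression** (`linreg_scores()`): the signed
  $-\log_{10} p$ of the expression slope with categorical covariates
  (e.g. lineage) projected out of both matrices; implemented by
  residualizing both sides against the covariate design
  (Frisch–Waugh), so the full matrix costs two QR projections and one
  cross-correlation.

## Evaluation stack

* **Ranking** (`top_pairs()`): by balanced score, ties broken by the
  original Pearson coefficient, then lexicographically — fully
  deterministic. Every prediction carries its original coefficient and
  the global z-score of that coefficient, so the *transformation
  strength* (how far balancing promoted a mediocre correlation) is
  always visible (`low_z_counts()`).
* **Diversity index**: the minimum number of distinct genes whose
  occurrence counts cover the $N$ pairs, divided by $N$; 1 means all
  pairs are disjoint, small values mean a hub dominates.
* **False-positive flags**: genomic proximity (same chromosome arm,
  midpoints strictly closer than 10 Mbp — a known artifact of CRISPR
  cutting), and co-expression (a buffering gene strongly co-expressed —
  z > 3 over the off-diagonal co-expression population — with a
  better-ranked gene predicted for the same buffered gene).
* **Empirical FDR** (`cumulative_fdr()`): walking the ranking,
  $\mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$ among labeled pairs only;
  TP = membership in any reference pair set or self-addiction,
  FP = flagged proximal or co-expression pairs. The high-confidence set
  (`high_confidence_set()`) nominates every pair up to the deepest rank
  still at or under the FDR threshold (default 0.5), then removes
  flagged pairs from the nominated set.
* **Enrichment** (`set_enrichment()`): upper-tail hypergeometric test of
  reference-pair density among the top $N$ against the testable
  universe, with BH adjustment across chromosome-pair density cells.

## The synthetic test bed

`synthetic_config()` emulates the paired-matrix structure at desk scale:
500 cell lines in four equal lineages, 300 expression and 300 fitness
genes, gene-level means drawn once (expression $\mathcal U(2,8)$,
truncated at 0; fitness $\mathcal N(-0.2, 0.3)$), i.i.d. noise (sd 1 for
expression, 0.2 for fitness). Twenty planted pairs: in a random 30% of
lines the buffering gene's expression is scaled to 5% of its mean and the
buffered gene's Chronos score drops by 1.0. The confounded variant adds a
30-gene co-expression module (+3 expression shift in one lineage) and 30
lineage-responsive fitness genes (−0.5 in the same lineage), yielding a
truth table of 30 known confounder false positives that raw correlation
ranks highly and balancing should suppress.

All generator defaults were fixed as study conditions before any method
was run against them and are never adjusted to outcomes. What passing
shows: balancing removes lineage-module false positives and preserves
planted recovery *under this generative model* — additive lineage shifts,
i.i.d. noise, binary loss events. What it does not show: performance
under correlated noise, copy-number artifacts, non-linear buffering, or
real-screen error structure; no claim at DepMap scale is tested here.

## Problem sizes and numerics

The test suite runs matrices up to 500 cell lines by 300 genes and
balancing oracles up to 50 by 40; the acceptance script finishes in well
under a minute. Numerical conventions: sample covariance and z-scores use
$n-1$ denominators; constant vectors correlate as 0 with a warning
(rather than NA) so downstream rankings stay total; regression p-values
are floored at $10^{-300}$ before $\log_{10}$; whitening requires strict
positive definiteness and refuses rather than silently regularizing.

## Limitations

* The balancing score is rank-based within rows and columns; it has no
  probabilistic calibration, and the empirical FDR depends entirely on
  the labeling rules (reference sets and flags), not on a null model.
* Whitening assumes the cell-line covariance estimated over genes is
  meaningful; with few genes it must be ridged and its effect shrinks.
* The synthetic generator is intentionally simple; it is a correctness
  harness, not a benchmark of biological performance.
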