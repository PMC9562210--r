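---
title: "Rank-based Random Forest analysis of heterogeneous expression cohorts"
author: "rankRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based Random Forest analysis of heterogeneous expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankRF)
```

# The problem

Public transcriptome cohorts measure the same biology on incompatible
scales: microarray generations, RNA-seq pipelines, and normalisation
choices each apply their own (approximately monotone) distortion to the
underlying signal. A decision-tree model learns explicit per-gene
thresholds, so a forest trained on one platform's values is meaningless on
another's. `rankRF` implements the standard remedy in a fully tested
pipeline: replace each sample's expression vector with its **within-sample
ranks**. Ranks are invariant under any strictly increasing per-sample
transform, so cohorts from different platforms become directly mergeable,
at the cost of discarding absolute expression magnitude.

On this representation the package provides the complete analysis chain
used in pathway-focused tumour classification studies: consensus Boruta
gene selection, Random Forest classification (binary tumour/normal and
four-subtype), minimal-panel search, exact Shapley attribution, and a
two-stage differential-expression follow-up, together with a synthetic
multi-platform generator that makes every stage testable without any
external download.

# The rank transform and its universe

`rankWithinSamples()` assigns rank 1 to the lowest value, average ranks to
ties. Two conventions matter and are fixed deliberately:

* **Ascending direction.** The forest is direction-agnostic; fixing
  ascending ranks makes every downstream artifact reproducible.
* **Ranking universe.** Ranks are computed over the *intersected* common
  gene universe (`intersectGeneUniverse()`) **before** any panel
  subsetting, and `subsetToPanel()` never recomputes them. If each
  platform ranked over its own full universe, rank magnitudes would be
  platform-dependent and the forest's thresholds would again fail to
  transfer; ranking over the shared universe keeps the scales comparable.
  Users who prefer panel-only ranking can rank an already-subsetted
  dataset.

Average-rank tie handling preserves the column-sum identity
$\sum_g r_{gs} = G(G+1)/2$, which the test suite uses as a structural
invariant.

# Consensus Boruta selection

`borutaRun()` implements shadow-feature selection from first principles.
Each cycle: every gene column is copied and independently permuted (the
*shadow* block), a forest is fitted on the merged matrix, and a gene scores
a hit when its importance strictly exceeds the **maximum** shadow
importance. Under the null a hit occurs with probability at most 1/2 per
cycle, so after $N$ cycles hit counts are dominated by
$\mathrm{Binomial}(N, 1/2)$. A gene is accepted when its count exceeds the
exact 99.5% quantile $k^\ast = \min\{k : P(\mathrm{Bin}(N, 1/2) \le k) \ge
0.995\}$, computed by exact CDF summation (`binomialAcceptanceThreshold()`;
no normal approximation). Because beating the maximum of hundreds of
shadows is far rarer than a fair coin flip, the binomial null is very
conservative — the measured null acceptance rate on 200-gene pure-noise
cohorts is far below the nominal 0.5% (the test suite allows up to 2% to
absorb importance correlation).

Design choices where the method description is open:

* **Importance measure:** out-of-bag permutation importance (mean decrease
  in accuracy), the classic Boruta choice; impurity importance is available
  as a faster switch.
* **Rejection rule:** only acceptance is specified by the method; the
  symmetric lower binomial tail marks "rejected", and tentative genes count
  as not selected. Consensus frequencies depend only on acceptance, so this
  cannot change headline outputs.
* **Within-cycle forest size:** 100 trees (the final classifier uses 450).
* **Seeds:** a master seed deterministically spawns per-run and per-cycle
  seeds (`spawnSeeds()`), so any single run is reproducible in isolation.

`consensusSelect()` repeats the run $R$ times (default 100) and keeps genes
accepted in at least $\tau R$ runs (default $\tau = 0.90$, boundary
inclusive).

# The rank forest and its metric panel

`fitRankForest()` fits a majority-vote forest (default 450 trees,
$\sqrt{M}$ features per split, unlimited depth, no class weighting or
resampling — imbalance is reported, not corrected). Predicted
probabilities are vote fractions, so they are exact rationals summing
to 1. `computeMetrics()` reports balanced accuracy (unweighted mean of
per-class recalls), ROC-AUC and PR-AUC by threshold sweep (PR interpolated
linearly in recall), and F1. For four classes ROC-AUC/PR-AUC are
macro-averaged one-vs-rest on the vote-fraction scores — the convention
that is well defined without class-prior weighting — and F1 is reported
both macro (primary, because test sets are imbalanced) and
support-weighted.

# Minimal panels by floating forward selection

`sffs()` grows a panel greedily by cross-validated ROC-AUC (stratified
5-fold, fold assignment fixed once per call and seeded; ties between
candidate genes break lexicographically). After each addition, any
already-selected gene (never the one just added) whose removal *strictly*
improves the CV score is dropped, repeatedly — the floating step that
rescues greedy selection from jointly-redundant features. The reported
uncertainty is the normal-approximation half-width
$1.96\,\mathrm{sd}(\text{fold scores})/\sqrt{k}$. Inner forests use 100
trees for tractability; re-score the final panel with 450 trees via
`cvScore()` when reporting. `xorRedundancyFixture()` constructs the
canonical failure case — two genes informative only jointly, plus a noisy
single predictor that greedy selection picks first and floating later
removes — and the test suite verifies both behaviours.

# Exact Shapley attribution

`computeAttributions()` computes per-sample, per-class Shapley values of
the fitted forest under the tree-path conditional-expectation game: for a
feature coalition $S$, each tree is traversed following the sample on
features in $S$ and splitting by in-bag cover fractions elsewhere; leaf
values are one-hot class votes. Per leaf the traversal probability
factorises over the distinct path features, so the Shapley sum reduces to
elementary-symmetric polynomial coefficients, evaluated exactly in
compiled code in $O(\text{leaves} \times \text{depth}^2)$ per sample —
no sampling, no approximation. Consequences that the tests assert:

* **Local accuracy** holds exactly: base value plus attribution sum equals
  the predicted vote fraction for every sample and class.
* A gene never used in any split receives exactly zero.
* On forests small enough to enumerate ($\le 12$ features),
  `bruteForceShapley()` — an independent coalition-enumeration oracle —
  agrees to $10^{-9}$.

Attributions are computed on the evaluation cohort by default (class
separation is an evaluation-time question); passing the training cohort
works identically. Per-class importance is the mean $|{\phi}|$ over
samples; `topInfluential()` orders genes by the summed per-class means.
For *fitted* forests two identical gene columns share attribution only as
evenly as the ensemble happens to split its usage between them, so the
symmetry check in the suite is tolerance-based rather than exact.

# Differential expression and over-representation

DE runs on platform-native expression values, not ranks, and should be run
within a single cohort where values are comparable (the pipeline uses the
largest test cohort). `binaryDe()`: per-gene two-sided Mann-Whitney,
Benjamini-Hochberg at FDR 0.05, direction by group medians. `subtypeDe()`:
classical one-way ANOVA F-test filter (BH < 0.05), then one-sided
(greater) Mann-Whitney of each subtype against the pooled rest for passing
genes, BH-adjusted jointly across the whole gene-by-subtype family (the
conservative reading of an unspecified family), each gene assigned to at
most one subtype (smallest adjusted p wins). One-vs-rest was chosen over
all-pairwise because it yields structurally disjoint subtype lists;
`mannWhitney()` also exposes the pairwise building block. The
Mann-Whitney wrapper uses exact enumeration for combined $n \le 12$
without ties and the tie- and continuity-corrected normal approximation
otherwise; two identical constant groups return $p = 1$ by convention.

`ora()` replaces web-service enrichment with the standard exact
hypergeometric upper-tail test against a user-stated background (the panel
present in all cohorts), BH-adjusted across sets, significant at adjusted
$p < 0.001$. Annotation collections are user-supplied GMT files; fetching
GO/KEGG/WikiPathways is out of scope.

# The synthetic cohort generator

`simulateCohorts()` draws a latent additive-Gaussian log-scale signal
$x_{gs} = \mu_g + \beta_{g,c(s)} + \varepsilon_{gs}$ with $\mu_g \sim
N(6, 2^2)$ (a typical log2-expression scale), $\varepsilon \sim N(0,
\sigma^2)$, $\sigma = 1$, and planted effects $\beta$ in latent-SD units,
then pushes it through each platform's strictly increasing transform
(affine, exponentiation, softplus, or a random monotone spline). This is
the minimal structure under which the rank transform is provably correct
and a raw-value cross-platform model provably degrades — exactly the
contrast the validation suite measures. Per-platform gene dropout
(default 10%) emulates partially overlapping gene universes; dropout is
sampled from the *non-informative* genes so that planted markers survive
intersection and recovery criteria are well defined. Unbalanced
`nSamplesPerClass` emulates skewed test cohorts.

The standard study conditions are frozen in `binaryFixtureConfig()` (200
genes, 10 informative at 1.5 latent SD in tumour, 150 samples/class/
platform, affine vs exponential platforms), `subtypeFixtureConfig()` (four
subtypes, 4 markers each at 2 SD — or 1 marker each for the recovery
checks), and `noiseFixtureConfig()`. What passing these tests does *not*
show: real cohorts have correlated genes, non-Gaussian tails, batch
structure within platforms, and imperfectly monotone cross-platform
relationships; the generator demonstrates correctness of the machinery,
not clinical performance.

# Problem sizes and numerical choices

The test and acceptance computations run the scaled study conditions:
consensus over $R = 20$ runs of 40 cycles (the acceptance threshold adapts
to the cycle count by construction), 20 pure-noise seeds for the type-I
check, 200 replicates for the empirical-FDR check, 450-tree final forests,
and 100-tree inner forests for selection. Degenerate inputs are contracts,
not crashes: all-equal samples rank to $(G+1)/2$ with a warning,
zero-variance genes are skipped by the ANOVA stage with a warning, empty
intersections, single-class labels, and missing panel genes raise errors
naming the offender. Floating selection caps its step count to preclude
add/remove cycling on pathological score surfaces.

# Limitations

Ranks discard magnitude: two samples with identical orderings are
indistinguishable however different their dynamic range. The binomial
Boruta null is conservative by design. The generator's independence across
genes makes selection easier than on real co-expressed panels; treat
recovery rates as upper bounds. DE on values assumes within-cohort
comparability and gene-level input (probe collapsing and normalisation are
the user's responsibility, and missing values are rejected rather than
imputed).
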