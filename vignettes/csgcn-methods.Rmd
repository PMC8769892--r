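---
title: "Constructing context-specific co-expression networks with csgcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing context-specific co-expression networks with csgcn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgcn)
```

## The problem

A traditional gene co-expression network (GCN) scores every gene pair with a
single correlation computed across all samples of an expression matrix. In
multi-condition experiments — several genotypes, treatments, time points —
that single number is often a poor summary. A pair may be tightly correlated
only inside one treatment and uncorrelated elsewhere; two subpopulations may
form separate modes that neither Pearson nor Spearman describes; and a shared
covariate such as time can manufacture correlation that has nothing to do
with the condition the samples carry. Correlation tests also assume bivariate
normality and homoscedasticity, which multi-modal expression data routinely
violate.

`csgcn` builds *context-specific* GCNs (csGCNs): each gene pair is decomposed
into sample clusters, each cluster is tested on its own, and a surviving
cluster becomes an edge annotated with the experimental condition in which
the co-expression holds. A pair may therefore contribute several edges, each
for a different context.

## The per-pair workflow

For every gene pair $(i, j)$, with genes on the rows of a log-scale
expression matrix:

1. **Missing-data exclusion.** Samples missing in either gene are excluded
   (state code `9`). Expression may be missing because a gene was silent in
   a condition or removed by an upstream low-count filter; either way the
   pair cannot be compared there.
2. **Outlier removal** (code `6`). Tukey fences
   $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by
   linear interpolation (type-7), applied to each gene's pairwise-complete
   values separately; the union of flags is removed. Whether the original
   procedure fences each margin or the joint scatter is not specified
   anywhere we could find; per-margin fencing is the natural reading of the
   Tukey method and is what we implement.
3. **Mixture clustering.** Full-covariance bivariate Gaussian mixtures with
   $k = 1..5$ components are fitted by EM (k-means++ initialization,
   tolerance $10^{-6}$, at most 300 iterations) and $k$ is selected by BIC.
   Samples are assigned by maximum posterior responsibility; components
   smaller than the minimum cluster size (default 30) are dropped. The
   engine is compiled code with its own deterministic generator, so results
   are identical for a given seed regardless of execution order.
4. **Cluster outlier removal** (code `7`). Tukey fences again, inside each
   cluster and per gene; clusters falling below the size floor are dropped.
   Samples of any dropped cluster also carry code `7` — the state alphabet
   has no separate "unclustered" symbol, and the context tests treat `7` as
   "complete for the pair but not in an emitted cluster", which is exactly
   the disposition of such samples.
5. **Similarity.** Pearson (default) or Spearman correlation per surviving
   cluster. Clusters with $|r|$ below 0.5 are discarded; the floor trims
   output size, not significance — that is the next filter's job.
6. **Power filter.** A cluster of $n$ samples supports a correlation of
   magnitude $r$ only if
   $n \ge \lceil ((z_{1-\alpha/2} + z_{pw}) / \operatorname{atanh} r)^2 + 3 \rceil$,
   the Fisher-z minimum sample size for a two-sided test of $\rho = 0$ at
   $\alpha = 0.001$ and power $0.8$. At those defaults $r = 0.85$ requires
   14 samples, so a 5-sample cluster at $r = 0.85$ is discarded as
   underpowered. The two-sided quantile is required to reproduce that
   operating point.
7. **Context association.** For each categorical variable and each label
   present in the comparison set (the samples complete for the pair after
   step 2): two one-proportion z-tests against the label's prevalence —
   enrichment inside the cluster (one-sided greater) and depletion outside
   it (one-sided less); both must reject at $\alpha = 0.001$. For each
   quantitative variable: each gene's in-cluster expression is regressed on
   the covariate, and both genes must reach $R^2 > 0.3$ with slope
   $p < 0.001$. Regressing expression on the covariate (rather than the
   reverse, or some joint model) is our reading of "linear regression" in a
   dose-response setting; it is symmetric across the two genes, matching
   the both-genes rule of the confound screen.
8. **Missingness screen.** A gene observed only in one condition correlates
   with *every* ubiquitously expressed partner on the surviving samples,
   and step 7 annotates all of those pairs with that condition — a "spoke"
   of artifactual edges. A pooled-variance Student t-test compares the two
   genes' binary missingness indicators; by default the pair is kept only
   when the test does *not* reject (p ≥ 0.001), i.e. when the genes have
   statistically similar missingness. The opposite retention direction is a
   defensible reading of the procedure's shorthand description, so
   `miss_direction = "significant"` implements it; the default is the
   direction that actually removes spokes.
9. **Confound screen.** If gene $i$ responds to a covariate shared with
   gene $j$ (say, time) and only one of them responds to the category under
   test, the category association is spurious. Welch's one-way ANOVA
   (equivalently Welch's t-test for two groups) compares each gene's
   expression between the cluster and an out-group — by default all
   comparison samples outside the cluster, optionally the category
   complement. Both genes must be differentially expressed
   ($p < 0.001$) for the annotation to stand. Zero-variance groups of three
   or more samples receive a variance floor of $10^{-12}$ rather than an
   error, so a perfectly flat in-group still yields a (tiny) p-value.
10. **Ranking.** Each surviving (cluster, context) record becomes an edge
    with score
    $|r| \cdot \min(-\log_{10} p_{ctx}, 20)/20 \cdot q$, where $p_{ctx}$ is
    the record's worst context p-value and $q$ is the mean per-gene $R^2$
    for quantitative contexts (1 for categorical). The underlying valuation
    idea — combine the similarity score, the test p-values and the $R^2$ —
    does not pin down a formula, so this composite is **this package's own
    stand-in**: monotone in each ingredient, capped at $p = 10^{-20}$ to
    keep scores finite, with deterministic lexicographic tie-breaking. No
    global correlation threshold is applied: with several edges per pair
    the similarity matrix is multidimensional, and spectral thresholding
    methods built for a single global matrix do not apply.

All thresholds above are exposed as parameters (`min_abs_correlation`,
`alpha`, `power`, `assoc_alpha`, `min_r2`, `miss_alpha`, `confound_alpha`)
with the defaults just quoted. No multiple-testing correction is applied
across variables or labels: the fixed per-test thresholds are part of the
procedure being reproduced.

## The assumption audit

`audit_edges()` quantifies why single-correlation networks are fragile: for
each edge of any network it tests the pairwise-complete (optionally
Tukey-cleaned) scatter for

* bivariate normality — Royston's extension of Shapiro-Wilk. Each margin's
  $W$ is transformed to an approximately standard-normal $z$ (the
  Shapiro-Wilk normalization used by `stats::shapiro.test`), each $z$
  becomes $\psi = \Phi^{-1}(\Phi(-z)/2)^2$, and $\sum \psi \cdot e/2$ is
  referred to $\chi^2_e$ with equivalent degrees of freedom
  $e = 2/(1 + \bar c)$, where $\bar c$ is a function of the margins'
  absolute correlation. No installed package provides this test, so it is
  implemented here and validated by type-I calibration simulation;
* homoscedasticity — the Breusch-Pagan Lagrange-multiplier statistic
  $n R^2_{aux}$ from regressing squared OLS residuals on the predictor;
* multimodality — the same mixture engine as step 3; $K \ge 2$ flags the
  edge as multi-modal. The audit's default size floor is 10 (not 30) so
  that smaller secondary modes still register as modes.

The report aggregates the fractions failing each assumption, either, and the
multimodal fraction among non-normal edges. On the real compendia that
motivated this workflow those fractions are dramatic; reproducing those
numbers requires the original datasets, which this package deliberately does
not ship. What the test suite verifies instead is that the operators behave
as theory predicts on known generators: nominal type-I error on bivariate
normal data and near-certain detection of well-separated mixtures.

## The synthetic benchmark

`generate_dataset()` emulates a multi-condition plant-stress experiment: 300
samples over 4 genotypes × 5 treatments (15 per combination), a 0–8 h time
covariate on a half-hour grid, log-scale expression around a base level of
5 with noise sd 0.5, uniform 1% missingness, and 20 planted pairs per
archetype over 200 genes. The archetypes and what the pipeline should do
with them:

| archetype | construction | expected outcome |
|---|---|---|
| `bimodal_split` | one genotype: $\rho = 0.8$, center 4 noise-sd away; others: uncorrelated at base | edge labeled with that genotype |
| `category_specific` | one treatment: $\rho = 0.9$, center +2.8 noise-sd, dispersion 0.7 noise-sd; others independent | edge labeled with that treatment |
| `confounded` | gene A tracks time everywhere; gene B tracks time only in `heat` (plus offset) | **no categorical edge** (confound screen) |
| `basal_pair` | both genes track time in every sample | no edge: the single cluster spans all samples, leaving no out-group for the confound screen — ubiquitous co-expression is by definition not context-specific |
| `null` | independent noise | no edge |

Two generator choices deserve their reasoning spelled out:

* *Category-specific pairs carry a mean shift.* The confound screen demands
  differential expression of both genes between cluster and out-group, so a
  condition-specific cluster with no expression shift would be filtered as
  confounded by construction. A shift is also the biologically typical
  case: co-expression that switches on in a condition almost always comes
  with condition-responsive expression levels.
* *The in-category dispersion is tighter than the noise sd.* A minority
  condition (20% of samples) with a broad, strongly shifted cluster gets
  its most informative tail clipped by the pooled Tukey fences of step 2 —
  the 75th percentile stays inside the bulk, so the fences sit close — and
  the truncated cluster's correlation attenuates below the 0.5 floor. At
  25% (the genotype split used by the bimodal archetype) the upper quartile
  jumps into the second mode and the fences widen, which is why that
  archetype tolerates a wider, further-shifted cluster. A compact
  condition cluster (0.7 noise-sd at +2.8 noise-sd) is both realistic and
  fence-stable. These interactions between pooled outlier removal and
  minority-condition structure are worth knowing about when interpreting
  real data, not only synthetic ones.

`spoke_triples` (default 0) additionally plants the missingness pathology:
two genes observed only inside one treatment plus a ubiquitous partner
sharing their latent signal, exercising the step-8 screen.

What the generator does **not** emulate: count-level noise (everything is
Gaussian on the log scale), batch effects, library-size artifacts,
correlated missingness beyond the spoke construction, and any real
regulatory topology. Passing the recovery tests therefore shows that the
workflow's filters do what they claim on data matching their own
assumptions; it does not certify performance on raw RNA-seq compendia,
whose preprocessing (normalization, batch correction, low-count filtering)
is explicitly out of scope here.

## Numerical choices and degenerate inputs

* Mixture EM: covariance matrices are regularized by
  $10^{-6} \cdot \overline{\mathrm{var}}$ on the diagonal whenever nearly
  singular; a $k$ whose fit degenerates to a non-finite likelihood is
  skipped. BIC ties resolve to the smaller $k$. Clusters are indexed
  $0..K-1$ by decreasing size, ties by lower mean $x$.
* Per-pair seeds are derived arithmetically from the run seed and the pair's
  row indices, so any execution order (or future parallel scheduling)
  yields byte-identical output.
* Proportion tests are untestable (never retained) when the label's
  prevalence is 0 or 1 in the comparison set; quantitative associations
  when the covariate is constant or fewer than 5 in-cluster values exist.
* The missingness t-test handles the all-equal-indicator case directly
  (p = 1 when both genes have identical missingness rates with zero
  variance, p = 0 when both are constant but different).
* Zero-variance clusters are excluded from correlation; correlations of
  exactly $\pm 1$ are power-filtered with the minimum attainable n (4).
* `min_samples_for_correlation` is monotone in all three arguments and
  never below 4.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run the complete workflow on
the default 300-sample, 200-gene scenario (19 900 pairs), twice for the
byte-identity check; calibration suites use 500–1000 null replicates per
test and the Monte-Carlo power checks 200 000 replicates. These sizes give
the binomial error bands quoted in the tests while keeping a full run on a
single CPU in the minutes range.

## Known limitations

* The edge-ranking formula is a documented stand-in (see step 10).
* The missingness screen is conservative: genuinely co-regulated pairs with
  dissimilar detection patterns are discarded, and the confound screen
  likewise discards time-specific relationships inside a responding
  category (the confounded archetype is excluded for *both* its category
  and time readings). These are properties of the procedure, not bugs.
* Quantitative association fits each gene separately against one covariate;
  no joint or interaction models across variables.
* The mixture engine caps at 5 components and was designed for the
  pairwise (2-D) case only.
* Royston's approximation bounds the audit to $4 \le n \le 2000$ samples
  per edge.
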