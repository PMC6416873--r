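---
title: "Methods: subtype classification and responder estimation for diffuse-type gastric cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype classification and responder estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffuseGC)
```

## Overview

diffuseGC implements the computational analysis chain used to argue that a
subset of diffuse-type gastric cancers (GCs) — those falling in an
expression cluster dominated by microsatellite-unstable (MSI) and
chromosomally unstable (CIN) tumors — are plausible responders to immune
checkpoint inhibitors and mTOR-pathway inhibitors. The chain is: normalize
expression within and across cohorts, select differentially expressed
genes, cluster samples, classify each sample into one of the four TCGA
gastric subtypes (EBV, MSI, GS, CIN) with a Bayesian compound covariate
predictor, summarize mutation profiles and burden per cluster, and convert
subtype composition and driver-mutation frequency into expected responder
fractions. A synthetic-cohort generator provides data with known ground
truth so that every stage can be validated quantitatively.

## Normalization

Two chains are provided, mirroring the two situations they serve.

**Within-cohort RNA-seq chain** (`normalize_rnaseq()`): counts per million
(every sample column rescaled to sum to $10^6$), quantile normalization,
$\log_2(x + 1)$, then median centering across genes and samples. The stage
order is deliberate and literal — quantile normalization acts on the CPM
scale before the log transform; a `log2_first` flag provides the other
order for sensitivity analysis, because the two differ numerically and the
convention is a genuine choice. The pseudocount defaults to 1 on the CPM
scale. Median centering alternates gene-median and sample-median
subtraction until every row and column median is within $10^{-6}$ of zero
or 10 iterations have run; one pass does not generally zero both margins,
and the iteration cap guards against the rare cycling of exact medians on
even sample counts (the result then carries a
`median_center_converged = FALSE` attribute rather than failing).

**Cross-cohort integration chain**: each cohort is z-standardized per gene
(sample standard deviation, $n-1$; constant genes are set to zero with a
warning rather than producing NaN), cohorts are pooled over the
intersection of their gene identifiers with cohort-prefixed sample names,
and the pooled matrix is quantile-normalized. Standardizing before pooling
removes per-cohort location/scale (platform) differences, which is exactly
the batch structure the simulator plants.

**Quantile normalization** is implemented directly: the reference
distribution is the mean of the column order statistics, every column is
mapped onto it rank-by-rank, and tied values receive the mean of the
reference values at their tied ranks. On tie-free input this is exactly
idempotent and leaves every column with an identical sorted value vector.
With ties neither property can hold exactly under any tie-averaging
convention — averaging alters the column's value multiset — so the
package's invariant tests use continuous fixtures and a separate test pins
the tie convention on a hand-computed example. (The limma implementation,
when installed, serves as an independent cross-check on tie-free data; it
is not used in the computation because its interpolation-based tie
handling is not idempotent.)

## Differential expression

`two_sample_ttest()` computes per-gene pooled-variance Student t statistics
(df $= n_1 + n_2 - 2$) with two-sided p-values — the classical
microarray-era convention of the BRB-ArrayTools family this analysis style
comes from; Welch's test is available behind `var_equal = FALSE`.
Zero-variance genes report $t = 0$, $p = 1$ rather than NaN. Fold
differences are computed on the linear scale as the orientation-free ratio
$\max(m_1, m_2)/\min(m_1, m_2)$ of group means (log2 input is exponentiated
first), because the ≥3-fold rule is stated without direction. Selection
(`select_genes()`) applies raw thresholds — no multiple-testing correction,
matching the original procedure — though a Benjamini–Hochberg column is
emitted for information. Ordering is by ascending p, then descending
$|t|$, then gene ID, so gene lists are reproducible to the byte.

## Clustering

`centered_correlation_distance()` is $d(i,j) = 1 - r(i,j)$ with $r$ the
Pearson correlation of two sample profiles over a chosen gene list; range
$[0, 2]$. A constant profile has no defined correlation; its distances are
set to the maximum (2) with a warning, which quarantines the sample at the
top of the dendrogram instead of aborting the run.

`centroid_linkage()` defines centroid linkage the way the Cluster-3.0
lineage of tools does under a correlation metric: each cluster is
represented by its per-gene mean profile and the distance between clusters
is $1 - r$ between centroids, recomputed after every merge. The
Lance–Williams centroid update is *not* applicable — it presumes squared
Euclidean distances — hence the direct implementation; the test suite
checks it step-for-step against a naive agglomerator that recomputes all
pairwise centroid distances from scratch at every merge. Ties in the merge
distance are broken toward the lexicographically smallest pair of cluster
creation indices, making the dendrogram deterministic. Centroid linkage
can produce height inversions; these are recorded in an `inversions`
attribute, never hidden, and `cut_clusters(k)` therefore cuts by undoing
the last $k - 1$ merges (merge order, not height order). The default
$k = 2$ reflects the two-cluster structure of interest; no automatic model
selection is implied.

## The Bayesian compound covariate subtype classifier

**Gene panels.** For each subtype $s$, every gene is tested against each of
the other three subtypes separately; a gene qualifies if all three
pairwise p-values are below $\alpha = 0.001$ *and* the t statistics agree
in sign (consistently up or down in $s$). Sign consistency is not spelled
out in the original description of "significant in all three comparisons";
we require it by default — a gene up against one subtype and down against
another is not a subtype marker — and expose
`require_sign_consistency = FALSE` for the literal reading. The ranking
for the top-200 truncation is also unstated upstream; we rank by the
maximum of the three p-values ascending (the most uniformly significant
genes first), ties by descending mean $|t|$, then gene ID.

**Model.** The compound covariate score of sample $j$ is
$c_j = \sum_i t_i x_{ij}$, where $t_i$ are the training t statistics
(subtype vs rest) of the panel genes. Class-conditional densities are
$\mathcal{N}(\mu_+, \sigma)$ and $\mathcal{N}(\mu_-, \sigma)$ with class
means of $c$ and pooled within-class SD, priors $(0.5, 0.5)$ by default,
and the posterior follows by Bayes' rule. The computation runs on the log
scale, so extreme scores give posteriors that saturate gracefully instead
of dividing underflowed densities.

**Decision tree.** One-vs-rest models are evaluated in a fixed node order —
EBV, then MSI, then GS, with CIN as the fall-through remainder — accepting
the first posterior $\ge 0.5$. Both the order and the threshold are
parameters: the source material shows the tree only graphically, and the
high posteriors it quotes (>93.3%, >90.7%) are observations, not
thresholds. A node whose panel came back empty (possible on null data at
$\alpha = 0.001$) is skipped with an NA posterior rather than inventing a
score.

**Validation.** `loocv()` repeats gene selection *and* model fitting inside
every fold. This is the load-bearing design point: selecting genes once on
the full data and then cross-validating only the model fit leaks
information and yields wildly optimistic accuracy. The regression test for
this is a pure-noise simulation in which LOOCV accuracy must stay within
binomial bounds of the 25% chance rate — a leaked implementation scores
far higher. On strong-signal fixtures (signature effect 2.0 log2 units,
30 samples per subtype, 2000 genes) accuracy exceeds 0.90; both thresholds
were fixed by a 20-seed Monte-Carlo sweep before the tests were frozen
(observed: recovery ≥ 99.9% of planted genes, LOOCV accuracy 1.0,
noise accuracy 0.19–0.33 around 0.25).

## Mutation statistics

The 2×2 chi-square (`chi_square_2x2()`) is the uncorrected Pearson
statistic $N(ad-bc)^2/[(a+b)(c+d)(a+c)(b+d)]$ on df 1. No Yates continuity
correction is applied by default because the uncorrected statistic
reproduces the published p-values (0.029, 0.028, 0.030) to three decimals
and the corrected one does not; `correction = "yates"` is available.
Burden is mutations divided by the targeted region size in Mb — the region
size is a required configuration value, not a constant, since panel
footprints differ. Group comparison offers a Wilcoxon rank-sum test (tie
corrected; a fully tied comparison reports $p = 1$) and a binned r×2
chi-square with configurable breakpoints (default 0–100, 101–500, >500
mutations; the original binning is not recoverable from the source, so
both flavors are reported). MSI-H is called when strictly more than 30% of
microsatellite markers show instability — the boundary case 3/10 is
non-MSI-H by the stated ">".

## Responder estimation

Expected checkpoint-inhibitor responders in a group:
$\sum_s f_s \rho_s$ with $f_s$ the group's subtype fractions and $\rho_s$
the per-subtype response rates (defaults 1.0, 1.0, 0.12, 0.05 for MSI,
EBV, GS, CIN, taken from published trial observations; all configurable).
Expected mTOR-inhibitor responders: driver (PIK3CA) mutation frequency
times the 35% pathway-inhibitor response rate. Percentages are rounded
half-away-from-zero (0.0907 → 9%, 0.0385 → 4%), which reproduces the
published integer figures; unrounded fractions are always carried
alongside. When every driver-mutant tumor lies in a fully responsive
subtype, the mTOR estimate is necessarily contained in the checkpoint
estimate, and `summarize_groups()` can attach that containment note.

## The synthetic-cohort generator

`simulation_config()` fixes the study conditions: 2000 genes, four
disjoint 200-gene subtype signatures, a signature effect of 2.0 log2 units
(up-shift only), per-gene baseline log2 means $\mathcal{N}(3, 2)$,
negative-binomial counts with dispersion 0.1, per-cohort per-gene batch
shifts $\mathcal{N}(0, 0.5)$ on the log2 scale, library sizes uniform in
$[5 \times 10^5, 2 \times 10^6]$, and a default cohort of 6 EBV + 7 MSI +
12 GS + 17 CIN samples matching the published composition of the
diffuse-type cases available for subtype analysis. Mutation totals are
Poisson with per-subtype means (40/Mb for MSI, 10 for EBV, 5 for GS and
CIN over a 1 Mb region), and driver genes carry group-dependent Bernoulli
frequencies shaped like the published pattern (PIK3CA/ARID1A concentrated
in MSI/EBV, CDH1 in GS, TP53 in CIN). The negative-binomial count model
and all distributional settings are our own fixtures — the original
analysis used real cohorts and states no generative model — chosen once as
field-typical values and not tuned afterwards. A single master seed drives
one substream per cohort, so adding a cohort never perturbs the others and
identical configurations are byte-reproducible.

What the generator does *not* emulate: gene–gene correlation beyond the
block signatures, down-regulated signatures, gene-length effects,
copy-number or methylation structure, read-level noise, and survival.
Passing the planted-recovery tests therefore demonstrates the
implementation is correct under the assumed model, not that the classifier
would reach the same accuracy on real TCGA data.

## Numerical choices and degenerate inputs

* Zero-variance genes: $t = 0, p = 1$ (t-test); zeroed with warning
  (z-score); distance 2 with warning (constant sample profiles).
* Both group means zero: fold difference 1; a pseudocount of $10^{-9}$
  guards single zero means.
* Empty BCCP panels: node skipped in the tree, NA posterior recorded.
* Merge ties: lexicographically smallest creation-index pair.
* All assertions on posteriors use the log-scale computation; the sum
  $p + (1-p)$ identity is exact to $10^{-12}$ in absolute terms.

## Problem sizes

The validation suite simulates cohorts of 80–120 samples and 2000 genes,
runs 20-seed null LOOCV sweeps, 1000-case posterior-oracle comparisons,
and 1000 burden simulations; these sizes give stable Monte-Carlo estimates
(binomial standard errors below 1.5 percentage points) while keeping a
full run in the minutes range on one CPU.

## Limitations

The package reproduces the *procedures* and the in-text worked numbers of
the analysis; the cohort-level published results (the 1048-gene list, the
718/499/1965/241 subtype panels, the cluster memberships of the 61 TCGA
diffuse GCs, the PDX posteriors) require the original external cohorts and
are out of scope. Responder estimates are arithmetic expectations under
quoted response rates, not clinical predictions.
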