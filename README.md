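# diffuseGC

Computational subtyping and treatment-responder estimation for diffuse-type
gastric cancer expression cohorts.

Diffuse-type gastric cancer (GC) is usually considered genomically stable
(GS) and a poor candidate for checkpoint or mTOR-targeted therapy. Recent
work instead splits diffuse-type tumors into two expression clusters: one
dominated by the GS subtype, the other by microsatellite-unstable (MSI) and
chromosomally unstable (CIN) tumors with high mutational burden, frequent
*PIK3CA* mutations, and therefore an appreciable expected response to both
immune checkpoint inhibitors and PI3K/AKT/mTOR pathway inhibitors. This
package implements the full computational arm of that analysis for anyone
who wants to run it on their own (or simulated) cohorts:

* **Normalization** — the RNA-seq chain CPM → quantile normalization → log2
  → iterative median centering, and the cross-dataset chain per-gene
  z-standardization within each cohort → pooling over the shared gene set →
  quantile normalization.
* **Differential expression** — per-gene pooled-variance Student t-tests
  (Welch optional), orientation-free linear-scale fold differences, and
  threshold-based gene-list selection (`P < 0.05`, optional ≥3-fold rule).
* **Clustering** — agglomerative clustering of samples with
  centered-correlation similarity (`d = 1 − r`) and centroid linkage in the
  Cluster-3.0 sense: a cluster is its mean profile and distances are
  recomputed between centroids after every merge.
* **Subtype classification** — the Bayesian compound covariate predictor
  (BCCP). For each of the four TCGA gastric subtypes (EBV, MSI, GS, CIN), a
  gene panel is selected by requiring `P < 0.001` in all three pairwise
  comparisons against the other subtypes (top 200 by uniform significance),
  and a one-vs-rest score `c_j = Σ_i t_i x_ij` is formed with the training
  t statistics as weights. Class-conditional densities of `c` are Normal
  with pooled SD, so the posterior is
  `π₊ φ(c; μ₊, σ) / [π₊ φ(c; μ₊, σ) + π₋ φ(c; μ₋, σ)]`.
  One-vs-rest models are composed into a decision tree (EBV → MSI → GS →
  CIN fall-through) and validated by leave-one-out cross-validation with
  gene selection repeated inside every fold.
* **Mutation statistics** — per-group mutation frequencies, uncorrected
  Pearson 2×2 chi-square tests, mutations/Mb burden with rank-sum and
  binned chi-square group comparisons, and the MSI-H rule (unstable in
  >30% of markers).
* **Responder estimation** — expected checkpoint-inhibitor responders as
  Σ subtype-fraction × subtype response rate (defaults MSI = EBV = 100%,
  GS = 12%, CIN = 5%), and expected mTOR-inhibitor responders as *PIK3CA*
  mutation frequency × 35%.
* **Synthetic cohorts** — a negative-binomial simulator with planted
  subtype signatures, per-cohort batch shifts, library-size variation, and
  subtype-dependent mutation burden, so the whole pipeline is testable
  without access to the original cohorts.

## Worked example

```r
library(diffuseGC)

# The published 2x2 tables: PIK3CA mutations in diffuse-type cluster II
# (7/27) versus intestinal-type tumors (7/76)
chi_square_2x2(7, 20, 7, 69)
#>        mutated not_mutated
#> groupA       7          20
#> groupB       7          69
#> chi2 = 4.7369, df = 1, p = 0.02952 (correction: none)

# Expected mTOR-inhibitor responders among cluster-II tumors:
# 26% PIK3CA-mutant x 35% response rate
mtor_responder_rate(7 / 27)
#> group / mtor_inhibitor: estimated responder fraction 0.0907 (~9%)

# End-to-end run on a simulated 42-sample cohort
res <- run_pipeline(simulation_config(seed = 7), out_dir = "demo", top_n = 50)
#> [simulate] 1 cohort(s), 2000 genes, 42 samples
#> [normalize] pooled matrix 2000 x 42
#> [de] 528 genes at p < 0.05
#> [subtype] LOOCV accuracy = 1.000
res$loocv_accuracy
#> [1] 1
```

The chi-square p-values 0.029 (and 0.028, 0.030 for the companion tables)
match the published contingency analyses to three decimals; the 9%
mTOR-responder figure, with 4% for cluster I (11% mutant) and 4% for
intestinal-type tumors (10.5% mutant), reproduces the published "about 4,
9, and 4%" estimate. The LOOCV accuracy of 1.0 reflects the strong planted
signature effect (2 log2 units) in the simulated cohort.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "diffusegc.R", package = "diffuseGC")` with subcommands
`simulate`, `normalize`, `de`, `cluster`, `subtype`, `mutstats`, `chisq`,
`responders`, and `run`.

## Vignette

`vignettes/methods.Rmd` documents the statistical model behind every
stage, the defaults and why they were chosen, what the simulator does and
does not emulate, and known limitations.
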