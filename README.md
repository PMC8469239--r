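# accumap

Transcriptome-only molecular subtype discovery for adrenocortical tumors,
as a tested, reusable analysis workflow.

Adrenocortical carcinoma (ACC) splits into two transcriptional subtypes
with sharply different prognosis. This package re-implements, from first
principles, a pipeline that finds those subtypes from nothing but a bulk
RNA-seq FPKM matrix and then characterizes them:

1. **A bespoke UMAP variant** for unsupervised two-cluster discovery.
   High-dimensional similarities use squared Euclidean distances between
   samples with a per-sample local connectivity `rho_i` (distance to the
   first nearest neighbor) and a bandwidth `sigma_i` calibrated by binary
   search so that the smooth neighbor count `2^(sum_j p_(j|i))` equals
   `k = 15`. The graph is symmetrized as the plain mean
   `P = (P_cond + P_cond^T) / 2` (deliberately not the canonical fuzzy
   union), the low-dimensional kernel `g(d) = (1 + a d^(2b))^-1` is fitted
   from `min_dist = 0.25`, and the normalized-Q cross-entropy
   `CE = sum_(i!=j) [P log(P/Q) + (1-P) log((1-P)/(1-Q))]` is minimized by
   full-batch (non-stochastic) gradient descent with an exact analytic
   gradient.
2. **A consensus random-forest marker ranking**: 100 forests of 1,000
   trees, each trained on an independent stratified 50/50 split of the
   *raw* FPKM matrix (the embedding uses log2(FPKM+1); the forests do
   not — the asymmetry is intentional), per-model top-100 impurity
   importance lists aggregated by occurrence count and mean rank into a
   consensus top-100 gene list, plus 5-fold cross-validation and a
   per-gene direction audit between the clusters.
3. **Survival and mutation statistics**: Kaplan–Meier curves with median
   overall survival, log-rank test, univariate Cox hazard ratio for the
   poor-prognosis cluster, Kruskal–Wallis association of driver-gene
   mutation status (TP53, CTNNB1, NF1, APC, ZNRF3, MEN1, GNAS, ATRX) with
   the clusters, and per-gene expression comparisons across cluster /
   adenoma / normal-adrenal groups.

Patient-level data cannot be redistributed, so the package ships a
**synthetic cohort generator** (`simulate_cohort()`) that plants the
structure the analysis assumes — two log-normal expression subtypes, 40
informative genes, cluster-dependent exponential survival (hazard ratio
6) with uniform censoring, cluster-dependent mutation rates, and benign
samples adjacent to the good-prognosis subtype — and every stage is
tested against that planted truth. See the methods vignette
(`vignettes/subtype-discovery-methods.Rmd`) for the model, parameter
choices, and limitations.

## Worked example

The numbered drivers under `analysis/` run the whole study at desk scale:

```sh
Rscript analysis/01_simulate.R        # synthetic cohort -> results/cohort/
Rscript analysis/02_embed_cluster.R   # embedding + cluster calls
Rscript analysis/03_consensus_rank.R  # 100-forest consensus ranking
Rscript analysis/04_survival_mutations.R
Rscript analysis/05_end_to_end_check.R
```

A run of stages 2–4 prints:

```
Embedding: cross-entropy 2025.3 -> 1690.7 over 300 epochs
Outliers flagged: 0 | cluster sizes: 36 40
Concordance: 0/76 mismatched (0.00%), ARI = 1.000
Ensemble test accuracy: min 100.00%, max 100.00%, mean 100.00% (100/100 perfect)
5-fold CV accuracy: 100.00% +/- 0.00%
Planted informative genes recovered in consensus top-100: 40/40
Cluster 1: n = 36, median OS = 2.7 years
Cluster 2: n = 40, median OS = 12.3 years
Log-rank chi-square 26.15, p = 3.16e-07
Cox HR (cluster 2 vs 1) 0.20 (95% CI 0.10-0.39, p = 2.5e-06)
```

Reading: the embedding separates the two planted subtypes perfectly
(ARI 1.0 against truth over the 76 tumor samples); every planted marker
gene is recovered in the consensus top-100; and the cluster that carries
the planted 6-fold death hazard shows the short median survival (here it
landed on the left and was therefore named cluster 1, so the cluster-2
vs cluster-1 hazard ratio is below 1 — cluster naming is positional,
left = 1, by design). The mutation table shows the planted TP53/CTNNB1
enrichment in the poor-prognosis cluster with Kruskal–Wallis p-values of
8.2e-4 and 2.4e-6.

In code, the same end to end:

```r
library(accumap)
chk <- end_to_end_synthetic_check(default_paper_like_spec(),
                                  config = pipeline_config(seed = 1))
chk$recovery
```

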