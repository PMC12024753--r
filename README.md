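# immsubtype

Immune-profile subtyping of bulk tumor expression cohorts.

## The problem

Lung adenocarcinoma carries two largely mutually exclusive driver mutations,
in *EGFR* and *KRAS*, that look alike at diagnosis but respond very
differently to immune-checkpoint inhibitors. The idea implemented here is to
cluster patients not on raw bulk RNA-seq expression — where immune-unrelated
variance dominates — but on **inferred immune-cell content**, and then to ask
whether the resulting clusters are biologically meaningful: driver-mutation
enrichment, survival differences, immune-checkpoint expression, and a
resampling test for whether a small mutation-positive subset was misassigned
to its cluster.

## The method

The central fit is one function returning a classed model object:

1. **Rank-z signature scoring.** For each sample, genes are ranked
   ascending; a signature of *G* genes among *N* measured scores

   *s* = (r̄ − (N+1)/2) / √((N+1)(N−G)/(12G)),

   a Wilcoxon-type z: mean 0, variance 1 under random placement, invariant
   to any monotone transform of a sample's expression.
2. **Feature z-scoring → PCA (2 components) → k-means**, with the number of
   clusters *K* chosen by Kneedle knee analysis on the inertia-vs-k curve
   (k-means++ starts, 10 restarts, Lloyd iterations, seed 42 by default).
3. **Small-cluster filtering**: clusters with fewer than 5 members are
   discarded; survivors are renamed `sub0, sub1, …` in decreasing size.

Downstream: cluster × mutation contingency tests (uncorrected Pearson
chi-square; Fisher's exact for sparse 2×2), Kaplan–Meier + pairwise log-rank
survival comparison, a simplified negative-binomial Wald differential
expression test (median-of-ratios size factors, method-of-moments
dispersion, BH q-values), a Welch-t immune-checkpoint panel comparison
(TIGIT, CD274/PD-L1, CTLA4, PDCD1/PD-1), and the resampling misassignment
test (*m* = 4 random draws, *R* = 18 repetitions, significance rule
p < 0.05 and FDR q < 0.25, z-test of the observed count against the
replicate null).

A synthetic-cohort generator (`simulate_cohort()`) plants immune subgroups,
subgroup-dependent mutation probabilities and survival hazards, and
hypermutated outliers, so the whole pipeline is testable without any
external download.

## Worked example

```r
library(immsubtype)

cohort <- simulate_cohort(cohort_config(n_samples = 300, seed = 11))
fit <- immune_cluster(cohort$expression,
                      signature_gene_sets(cohort$signatures))
fit
#> Immune-profile clustering (immune feature space)
#>   samples: 300  features: 8  components: 2
#>   knee-selected K = 3 over k = 1..10
#>   retained clusters: 3 ( sub0=156, sub1=99, sub2=45 )

adjusted_rand_index(cluster_labels(fit), cohort$truth)
#> [1] 1
```

The knee analysis picked *K* = 3 and the clusters reproduce the planted
subgroups exactly (adjusted Rand index 1). Mutation distribution across the
fitted clusters, with per-cluster mutated fractions and chi-square tests:

```r
egfr <- setNames(cohort$mutations$egfr_status, cohort$mutations$sample_id)
kras <- setNames(cohort$mutations$kras_status, cohort$mutations$sample_id)
table2_report(cluster_labels(fit), list(EGFR = egfr, KRAS = kras))
#> EGFR distribution across clusters
#>                       sub0        sub1        sub2
#>             WT         143          74          45
#>        mutated   13 (8.3%)  25 (25.3%)    0 (0.0%)
#>   overall chi-square p = 8.5e-06
#>   sub1 vs sub0: p = 0.000218
#>   sub2 vs sub0: p = 0.0452
#>   sub2 vs sub1: p = 0.000209
#>
#> KRAS distribution across clusters
#>                       sub0        sub1        sub2
#>             WT         105          58          34
#>        mutated  51 (32.7%)  41 (41.4%)  11 (24.4%)
#>   overall chi-square p = 0.114
#>   sub1 vs sub0: p = 0.158
#>   sub2 vs sub0: p = 0.291
#>   sub2 vs sub1: p = 0.0494
```

In this cohort EGFR mutations concentrate in one cluster (25.3% vs 8.3% and
0%, overall p ≈ 10⁻⁵) while KRAS mutations are spread more evenly
(p = 0.11) — the pattern the method is designed to expose. Survival,
differential expression, checkpoint-panel and misassignment analyses are
available through `logrank_pairwise()`, `nb_wald_test()`,
`checkpoint_panel_test()` and `misassignment_analysis()`; the whole chain
runs end to end, with a JSON manifest, via `run_pipeline()` (a thin CLI
wrapper lives in `inst/scripts/pipeline.R`).

## Package layout

* `R/` — generator, readers/writers (TSV/GMT), preprocessing, rank-z
  scorer, PCA/knee/k-means, association, survival, DE, misassignment,
  pipeline and reporting.
* `tests/testthat/` — unit and property tests per module, brute-force
  oracles for the core statistics, and end-to-end acceptance tests.
* `vignettes/immune-subtyping.Rmd` — the methods vignette: model,
  assumptions, numerical choices, generator design, limitations.
* `inst/extdata/` — the printed mutation-distribution counts, a demo GMT
  and a demo pipeline configuration.
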