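# canprio

Prioritizing cardiovascular-risk genes as neuropsychiatric candidates from
their brain expression over the central autonomic network (CAN).

## The problem

Heart and brain disease co-occur far more often than chance, and one shared
substrate is the brain's central autonomic network — the cortical/limbic
regions that drive autonomic output in a *feedforward* fashion (prefrontal,
cingulate and insular cortex, amygdala, hippocampus, hypothalamus,
periaqueductal gray) and the brainstem nuclei that close the *feedback*
baroreflex loop (nucleus of the solitary tract, parabrachial nucleus, dorsal
motor vagus, nucleus ambiguus). Mouse knockout screens annotate hundreds of
genes with electrocardiogram (ECG) phenotypes — heart rate (HR), heart-rate
variability (HRV), RR/PQ/ST/QTc intervals — but say nothing about *where in
the brain* those genes act. `canprio` implements a stepwise refinement that
turns an ECG gene set plus a gene × brain-region expression-energy matrix
into a ranked, annotated shortlist of neuropsychiatric candidate genes.

The pipeline, for practitioners in systems genetics / neurogenomics:

1. **Ingest** — read a gene × region expression-energy TSV (in situ
   hybridization energies; one profile per gene after replicate collapsing),
   subset to a CAN region panel with feedforward/feedback role tags, and
   report genes without data.
2. **Bicluster** — z-score each gene row
   (`z_gr = (x_gr − mean_g) / sd_g`), build Ward minimum-variance
   (`ward.D2`) linkage trees over genes and over regions on Euclidean
   distances, and choose each axis's cluster number k by maximal mean
   silhouette width. Gene clusters are named `FF-ANS` / `FB-ANS` by their
   mean expression contrast across feedforward vs feedback regions.
3. **mSVM-RFE** — multiclass linear support-vector-machine recursive feature
   elimination: regions are samples, region clusters the classes, genes the
   features. Per training set (stratified 4-fold split, all combinations of
   3 folds, 50 repeats ⇒ 200 runs), features are scored by
   `s_g = Σ_pairs w_{g}²` over all one-vs-one linear SVMs (cost 0.01) and
   the lowest-scoring 10% are removed per iteration until 15 remain.
   Genes are ranked by how often they survive to a final set.
4. **Enrichment** — one-sided hypergeometric over-representation of each
   gene cluster against GMT libraries,
   `p = P(X ≥ k), X ~ Hypergeom(N, K, n)`, with Benjamini–Hochberg
   adjustment; no web service involved.
5. **Phenotype filter** — parse per-gene ECG phenotype strings
   (`"HR ↑ HRV↓"`, sex-specific `"HR ↑ (M)"`, …), select candidates with
   increased HR and/or decreased HRV, and split them by
   neuropsychiatric-disease annotation status.

A synthetic-data module generates expression matrices with planted region
classes, gene clusters and class-discriminative genes (log-normal energies),
plus matching region panels, phenotype tables and GMT libraries, so the full
pipeline is testable offline with known ground truth.

## Worked example

The packaged 32-gene candidate table (feedforward-expressed ECG genes) and
the heart-rate filters:

```r
library(canprio)
tab <- read_phenotype_table()              # 32 rows
filter_by_phenotype(tab, "HR", "up")       # 11 genes, e.g. Psmc6, Gsg1l, Zfp395
filter_by_phenotype(tab, "HRV", "down")    # 2 genes: Psmc6, 1700086L19Rik
annotate_npd(tab, c("Psmc6", "Grm7"))      # limited_or_none / annotated
```

An end-to-end run on simulated data with 7 planted region classes:

```r
cfg <- synthetic_config(n_genes = 120, n_regions = 47, k_region_clusters = 7,
                        k_gene_clusters = 2, signal = 2.5, noise_sd = 0.5,
                        seed = 42)
paths <- write_synthetic_bundle(cfg, "study", n_terms = 10)
summary <- run_pipeline(pipeline_config(
  matrix = paths$expression, regions = paths$regions,
  gmt = c(synthetic = paths$gmt), phenotypes = paths$phenotypes,
  out_dir = "study/out", rfe = rfe_config(n_folds = 4, n_repeats = 5),
  top_hub = 30, seed = 42))
#> ingest: 120/120 genes retained over 47 regions
#> bicluster: gene k = 7, region k = 7
#> rfe: 20 runs, top 30 hub genes (...)
#> enrichment: 70 term rows across 7 library x cluster queries
#> phenotype filter: 45 candidate genes
```

`region k = 7` is the recovered planted region-cluster count; the RFE stage
ran 4 folds × 5 repeats = 20 elimination runs; the candidate count reflects
the simulated HR/HRV annotation rates. Results are tibbles throughout:
`tidy(summary$rfe)` gives the per-gene ranking
(`gene_id, selection_frequency, mean_elimination_step, rank, cluster`),
`glance(summary)` the stage counts, `autoplot()` the silhouette and
selection-frequency diagnostics, and every stage writes plain TSV/JSON
artifacts under `out_dir`.

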