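---
title: "Methods: CAN-expression prioritization of ECG genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAN-expression prioritization of ECG genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canprio)
```

`canprio` prioritizes genes that carry mouse electrocardiogram (ECG)
knockout phenotypes into neuropsychiatric candidates, using their expression
across the brain's central autonomic network (CAN). This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The data model

The central object is a gene × brain-region matrix of *expression
energies* — non-negative in situ hybridization intensities per anatomical
structure, in arbitrary ISH units. Genes are rows, regions columns; the CAN
panel tags each region as **feedforward** (cortical/limbic structures that
drive autonomic output: prefrontal, cingulate and insular cortex, amygdala,
hippocampus, hypothalamus, periaqueductal gray) or **feedback** (brainstem
reflex nuclei: solitary tract, parabrachial, dorsal motor vagus, ambiguus).
Several ISH experiments can exist per gene; ingestion keeps the experiment
with the largest total energy across regions (ties to the lexicographically
smallest experiment id). This rule is the package's own choice — it is
deterministic and favors high-signal experiments — since the upstream
protocol only requires *unique* expression data per gene without stating how
uniqueness is achieved. Missing cells are not imputed: downstream clustering
and SVMs need complete rows, so an incomplete gene row is dropped with a
warning rather than filled.

## Biclustering

Each retained gene row is standardized to mean 0 and sample (n−1) standard
deviation 1; a zero-variance row has no defined z-score and is set aside
(and reported). Both axes are then clustered with Ward's minimum-variance
criterion on Euclidean distances — the `ward.D2` variant, which squares
dissimilarities internally and is equivalent to classical Ward on the raw
observations, with merge heights on the distance scale. Euclidean distance
on z-scored rows is the conventional default for expression heat maps; no
alternative metrics are offered as defaults.

The number of clusters on each axis is chosen by the average silhouette
width: for k in 2–10 (the customary search range of silhouette helpers) the
tree is cut, the mean silhouette over items is computed with the same
Euclidean distances, and the maximizing k wins with ties going to the
smallest k. Cutting removes the k−1 highest merges; cluster indices are
assigned 1..k in order of first appearance along the dendrogram's leaf
ordering so labels are platform-stable. Gene clusters are optionally named
by their feedforward-vs-feedback contrast: the cluster with higher mean
z-scored expression in feedforward regions is `FF-ANS`, its counterpart
`FB-ANS` (suffixes disambiguate when an axis has more than two clusters).
The naming is a deterministic post-hoc labeling; in the original analysis
the two gene clusters were named by inspection.

## Multiclass SVM-RFE

The feature-selection stage asks: which genes' expression patterns most
consistently discriminate the region clusters? Regions are the samples,
their cluster labels the classes, genes the features. The protocol
constants are the package defaults: 4 stratified folds, all combinations of
3 folds as training sets (leave-one-fold-out), 50 repetitions — 200 runs —
with linear C-classification SVMs at cost 0.01, 10% of remaining features
eliminated per iteration, and a stop size of 15.

Choices the protocol leaves open, resolved as follows:

* **Fold construction.** Within each class, samples are shuffled (seeded)
  and dealt round-robin to folds, continuing a single global fold pointer
  across classes. This keeps overall fold sizes within 1 of each other
  (47 samples → 12/12/12/11) *and* per-class occupancy within 1. A
  singleton class is an error: with all-but-one-fold training it could
  vanish from a training set.
* **Ranking criterion.** The standard SVM-RFE importance score: for every
  class pair, a one-vs-one linear soft-margin SVM is fitted and each
  feature scores the sum of squared weight coefficients over the pairwise
  classifiers. SVMs are fitted without internal rescaling — features are
  already row-standardized upstream, and this keeps constant features in
  small training folds well-defined (they simply receive zero weight).
* **Elimination arithmetic.** Per iteration,
  `m = min(max(1, ceil(f · n_remaining)), n_remaining − stop_n)` features
  are removed, so elimination always progresses and lands exactly on the
  stop size (418 → … → 15 in 30 iterations at f = 0.10). Score ties are
  broken by removing the lexicographically larger gene id first, making
  every run fully deterministic.
* **Aggregation.** The protocol yields "200 gene selections" without an
  aggregation rule. Genes are ranked by *selection frequency* (how many
  runs' final sets contain them), then by *mean elimination step* — where
  surviving a run counts as one past the last iteration, so surviving is
  "latest possible" — then by gene id. The frequency total obeys the
  conservation law `Σ_g freq(g) = n_runs × stop_n`, which the tests assert
  on every configuration.
* **Hub-gene count.** The top-99 cut is a parameter (`top_n = 99`), not a
  derived quantity; no rule generating 99 exists upstream.

## Enrichment

Over-representation of a gene cluster in a GMT term is the one-sided
hypergeometric upper tail `P(X ≥ k)` with `X ~ Hypergeom(N, K, n)`: `N` the
universe size, `K` the term size within the universe, `n` the query size,
`k` the overlap. The default universe is the union of the library's genes
with the query; in the pipeline it is the union of library genes with the
clustered gene set — a web-based enrichment service never exposes its
universe, so this is configurable. Adjustment is Benjamini–Hochberg, the
conventional default for this readout; rank-deviation and combined scores
used by some web services require precomputed background ranks and are out
of scope. Gene symbols are case-folded to upper case; no ortholog mapping
is attempted. Terms are ranked by p ascending, ties by larger overlap then
term name.

## Phenotype filtering

ECG phenotype strings follow the knockout-table dialect: comma-separated
parameter lists, each closed by an up/down arrow that applies to every
parameter in the list (`"HR, RR ↑"`), with optional `(F)`/`(M)` sex
markers after the arrow and the literal `No` for no phenotype. The
vocabulary is closed (HR, HRV, rMSSD, RR, PQ, PR, ST, QTc, QRS,
QTc Dispersion, HR_TTE, LVIDd, LVIDs); anything else is a parse error
naming the fragment.

Two filter-level groupings reflect measurement physiology:

* the **HRV-decrease** criterion matches `HRV ↓` or `rMSSD ↓` — rMSSD is a
  vagally mediated HRV statistic;
* the **HR-increase** criterion matches `HR ↑` or `HR_TTE ↑` — heart rate
  measured on the surface ECG or during transthoracic echocardiography is
  the same physiological quantity. On the packaged 32-gene table this is
  what makes the count of HR-increased genes eleven (the eleventh carries
  its heart-rate increase in the echo column).

Sex-specific tokens match under the default `sex_mode = "any"`, so a
male-only HR increase counts — required for *Gsg1l* to be among the
HR-increased genes. A gene's neuropsychiatric-disease status is classified
from the verbatim annotation column: `limited_or_none` exactly when it
equals "Limited or no NPD annotations". The 32-row table ships as a
versioned fixture file (`inst/extdata/table1_phenotypes.tsv`), so
transcription corrections are data changes, not code changes. One source
cell (*Fbxl16*) is garbled in the available transcription and is stored
verbatim; its tokens include both `HR_TTE ↑` and `HR_TTE ↓`, which does not
affect the HR/HRV filters beyond the grouping above. A literal reading of
the annotation column also gives an NPD-novelty count among the HR-increased
genes that differs from the prose summary accompanying the original table;
the fixture records the column verbatim and the package does not attempt to
resolve that discrepancy.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
configurable scale, with known ground truth:

* **Energies** are log-normal, `exp(μ + ε)`, `ε ~ N(0, noise_sd)` — chosen
  because ISH expression energies are non-negative and right-skewed; no
  distribution is prescribed upstream.
* **Planted structure.** Regions fall into `k_region_clusters` contiguous
  classes and genes into `k_gene_clusters` groups, both as even as possible
  (sizes differ by ≤ 1). Each *informative* gene is "on" (log-mean shifted
  by `signal`, default base μ = 1) in exactly one region class — the
  simplest pattern that makes the classes linearly separable for the SVM
  stage; non-informative genes share one mean everywhere. Region classes
  are split across gene clusters, so a gene's on-class is tied to its
  cluster, and the classes owned by the first gene cluster are tagged
  feedforward.
* **Defaults are the study conditions**: 418 genes × 47 regions, 7 region
  classes, 2 gene clusters. `signal = 2`, `noise_sd = 0.4` (log-scale) are
  the package's notion of a clearly structured but noisy atlas; the
  stochastic recovery tests use the ratios they state explicitly
  (signal/noise 5 for silhouette recovery; signal 3 / noise 0.3 for
  feature recovery).
* **Seeding.** One integer seed fans out to named substreams (matrix,
  phenotypes, GMT, folds), so each artifact can be regenerated
  independently and byte-identically.

A consequence of the one-on-class design worth stating plainly: at low
noise the gene axis genuinely contains one group per on-class, so with 7
region classes the silhouette criterion correctly reports 7 gene groups,
not the 2 planted cluster labels; the 2-cluster structure is their
higher-level merge. Gene-cluster recovery (adjusted Rand index 1 at zero
noise) is therefore demonstrated on configurations where gene clusters and
on-classes coincide (k = 2 on both axes), while the 7-class configurations
demonstrate region-cluster and informative-feature recovery.

What passing synthetic tests shows — and does not. The generator plants
block means with independent noise; real atlas data have spatial
autocorrelation between neighboring structures, heavy-tailed section
artifacts, and non-even cluster sizes. Recovery on synthetic data validates
the machinery (the clustering, selection and ranking logic), not the
biological claim that any particular real dataset contains 7 region
clusters or a 212/206 gene split; those depend on a pinned atlas snapshot
and library versions and are reproducible only against that exact input,
for which the pipeline exposes the full protocol configuration as its
defaults.

## Problem sizes and determinism

The test suite exercises: Ward linkage against a brute-force
minimum-WSS-increase agglomerator on all fixtures with ≤ 8 items (heights
within 1e-9); hypergeometric p-values against a `choose()`-based tail-sum
oracle on 50 random universes up to N = 200 (1e-12 relative); silhouette
recovery of k = 7 over 20 seeds (80 genes × 47 regions); and recovery of
10 planted informative genes among 100 over 20 seeds (30 samples,
3 classes, 5 repeats × 4 folds per seed — aggregate ranks stabilize with
few repeats, and this keeps the suite fast). End-to-end pipeline runs with
a fixed seed are asserted byte-identical; wall-clock timing is deliberately
excluded from the serialized run summary so that identical configurations
produce identical files.

## Known limitations

* Linear kernels only; no cross-validated accuracy reporting — the ranking
  is purely weight-based elimination frequency.
* The hub-gene cut (99) and the k search range (2–10) are conventions, not
  estimated quantities.
* The enrichment universe is an explicit modeling choice; results move with
  it, as with any over-representation analysis.
* No live atlas client: files in, files out.
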