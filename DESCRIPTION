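Package: canprio
Title: Prioritizing Cardiovascular-Risk Genes as Neuropsychiatric Candidates via Brain Autonomic-Network Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stepwise pipeline that refines a set of genes with mouse
    electrocardiogram (ECG) knockout phenotypes into neuropsychiatric
    candidate genes using brain expression over the central autonomic
    network (CAN). Stages: ingestion of gene-by-brain-region expression
    energy matrices, Ward minimum-variance biclustering of z-scored
    profiles with silhouette-based cluster-number selection, multiclass
    linear SVM recursive feature elimination (mSVM-RFE) over repeated
    stratified folds to rank hub genes, local hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction, and heart-rate /
    heart-rate-variability phenotype filtering. Includes a synthetic-data
    generator with planted cluster and feature structure so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
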