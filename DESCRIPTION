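Package: cardiocomm
Title: Integration QC, Disease Scoring and Ligand-Receptor Crosstalk for
    Two-Condition Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing healthy and
    hypertrophic heart single-nucleus RNA-seq atlases: batch-mixing
    correction with Local Inverse Simpson's Index (LISI) scoring,
    shared-nearest-neighbor graph clustering, artificial-nearest-neighbor
    (pANN) doublet scoring, Tukey-fence cluster-level quality exclusion,
    a ten-gene cardiomyocyte disease score, bimodal likelihood-ratio
    differential expression with Bonferroni correction, per-patient
    clustered t-tests, and permutation-based ligand-receptor crosstalk
    counting between cell types per condition. Ships a negative-binomial
    synthetic-atlas generator with planted cell types, batch shifts,
    condition effects, heterotypic doublets and ligand-receptor structure
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
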