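# cardiocomm

Integration quality control, cardiomyocyte disease scoring, and
ligand–receptor crosstalk comparison for two-condition single-nucleus
RNA-seq — built for comparing healthy and hypertrophic (pressure-
overloaded) human heart atlases, and fully testable without any external
data through a built-in synthetic atlas generator.

## Who this is for

Analysts with gene × cell UMI count matrices from two conditions
(e.g. healthy vs. disease), possibly from two merged datasets (batches),
who want a reproducible, statistically explicit pipeline for:

* **Integration QC** — per-nucleus **Local Inverse Simpson's Index**
  (LISI) over batch labels: a neighbourhood populated by a single dataset
  scores exactly 1, an equally mixed neighbourhood scores exactly 2.
* **Cluster-level exclusion** — per cell, the ratio of genes expressed to
  LISI; per cluster, the mean ratio; clusters outside the Tukey fence
  `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` of the cluster means are excluded
  (quartiles by linear interpolation).
* **Doublet scoring** — pANN: the proportion of artificial doublets among
  each cell's nearest neighbours after jointly embedding real cells with
  simulated pair-averages.
* **Disease scoring** — per-cell mean log2-normalized expression over ten
  cardiomyocyte stress markers (NPPA, NPPB, MYH7, MYH7B, XIRP2, CMYA5,
  ANKRD1, TNNI3, ACTA1, PFKP).
* **Differential expression** — a bimodal likelihood-ratio test (zero
  with probability 1 − π, Normal(μ, σ²) when positive; shared σ; χ² with
  2 df) with Bonferroni correction over **all** genes, plus per-patient
  pseudobulk t-tests that respect within-sample clustering.
* **Crosstalk** — CellPhoneDB-style mean-of-means ligand–receptor scores
  with label-permutation p-values (add-one smoothing, p ≥ 1/(n_perm+1)),
  directed significant-interaction counts per donor→receiver cell-type
  pair, condition deltas, and a sensitivity reanalysis that removes genes
  expressed only in healthy cells.

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` ggplot2 helpers.

## Worked example

The synthetic generator emulates the study design the pipeline was built
for: 14 healthy + 5 disease samples, two batches, seven cardiac cell
types, planted disease effects in cardiomyocytes (MYH6→MYH7 switch,
stress-panel upregulation, EPHB1/EPHA4/VEGFB down, VEGFA up), healthy-only
ephrin signalling into cardiomyocytes, 5% heterotypic doublets, and one
planted low-quality population.

```r
library(cardiocomm)
run <- run_pipeline(list(seed = 3), out_dir = "my_run")
run$summary
#> # A tibble: 14 × 2
#>    metric                        value
#>    <chr>                         <chr>
#>  1 n_genes                       2000
#>  2 n_cells                       2856
#>  3 n_clusters                    8
#>  4 n_clusters_excluded           1
#>  5 n_cells_kept                  2520
#>  6 pann_threshold                0.103448
#>  7 disease_score_mean_healthy_cm 1.448184
#>  8 disease_score_mean_disease_cm 3.029742
#>  9 top_downregulated_gene        EPHB1
#> 10 top_upregulated_gene          PFKP
#> 11 interactions_healthy_total    257
#> 12 interactions_disease_total    239
#> 13 interactions_total_delta      -18
#> 14 delta_incoming_cm             -25
```

Reading the output: clustering at resolution 0.25 on 12 principal
components found 8 clusters; exactly one — the planted low-quality
population (high genes/LISI ratio, one batch) — fell outside the Tukey
fence and was excluded. Disease cardiomyocytes score about twice as high
on the ten-gene stress panel as healthy ones; the most downregulated gene
in disease cardiomyocytes is EPHB1 (planted at −2 log2); and the disease
condition loses interactions overall, with the strongest loss in signals
incoming to cardiomyocytes (`delta_incoming_cm = -25`), reflecting the
switched-off endothelial/fibroblast ephrin axes.

Individual stages compose just as well:

```r
cm   <- generate_atlas(atlas_config(seed = 3))
norm <- normalize_log2(cm)                      # log2(1 + 1e4 * count/nUMI)
emb  <- reduce_dimensions(norm, n_hvg = 2000, d = 12) |>
        correct_batches(norm$cell_meta$batch)
lisi <- compute_lisi(emb, norm$cell_meta$batch, perplexity = 30)
cl   <- cluster_graph(emb, k = 20, resolution = 0.25)
qc   <- exclude_outlier_clusters(norm, lisi, cl)
autoplot(qc)                                    # mean ratios + fences
```

Stage outputs are written as TSV (lisi, clusters, cluster_qc, doublets,
annotations, disease_score, de_results, interactions and count matrices
per condition, deltas) plus `manifest.json`; identical config + seed
reproduce every file bit-identically.

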