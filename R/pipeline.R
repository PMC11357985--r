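run_config_defaults <- function() {
  list(
    input_dir = NULL,            # read a triplet directory instead of simulating
    atlas = list(),              # overrides for atlas_config()
    scale = 1e4,
    n_hvg = 2000,
    dims = 12,
    k_neighbors = 20,
    resolution = 0.25,
    perplexity = 30,
    batch_groups = 10,
    batch_iters = 5,
    artificial_fraction = 0.25,
    pann_quantile = 0.9,
    n_perm = 1000,
    alpha = 0.05,
    min_frac = 0.1,
    drop_healthy_unique = FALSE,
    lr_db = NULL,                # path; NULL = shipped database
    marker_panel = NULL,         # named list; NULL = default_marker_panel()
    seed = 1
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list of overrides; fills defaults, rejects
#' unknown keys (suggesting the nearest known key), and range-checks every
#' parameter, reporting all violations at once.
#'
#' @param config YAML path, list of overrides, or `NULL` (all defaults).
#' @return A validated `run_config` list with every parameter populated.
#' @export
validate_config <- function(config = NULL) {
  defaults <- run_config_defaults()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config) && length(config) == 1) {
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a YAML path, a list, or NULL.")
  }
  errors <- character()
  unknown <- setdiff(names(user), names(defaults))
  for (key in unknown) {
    dist <- adist(key, names(defaults))
    hint <- names(defaults)[which.min(dist)]
    errors <- c(errors, sprintf("Unknown key '%s'; did you mean '%s'?", key, hint))
  }
  cfg <- utils::modifyList(defaults, user[intersect(names(user), names(defaults))])

  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  frac01 <- function(v) is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1
  posint <- function(v) is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v)
  chk(is.numeric(cfg$scale) && cfg$scale > 0, "scale must be > 0")
  chk(posint(cfg$n_hvg), "n_hvg must be a positive integer")
  chk(posint(cfg$dims), "dims must be a positive integer")
  chk(posint(cfg$k_neighbors), "k_neighbors must be a positive integer")
  chk(is.numeric(cfg$resolution) && cfg$resolution > 0, "resolution must be > 0")
  chk(is.numeric(cfg$perplexity) && cfg$perplexity > 1, "perplexity must be > 1")
  chk(posint(cfg$batch_groups), "batch_groups must be a positive integer")
  chk(posint(cfg$batch_iters), "batch_iters must be a positive integer")
  chk(frac01(cfg$artificial_fraction) && cfg$artificial_fraction > 0 &&
        cfg$artificial_fraction < 1,
      "artificial_fraction must lie in (0, 1)")
  chk(frac01(cfg$pann_quantile), "pann_quantile must lie in [0, 1]")
  chk(posint(cfg$n_perm) && cfg$n_perm >= 100, "n_perm must be an integer >= 100")
  chk(frac01(cfg$alpha), "alpha must lie in [0, 1]")
  chk(frac01(cfg$min_frac), "min_frac must lie in [0, 1]")
  chk(is.logical(cfg$drop_healthy_unique), "drop_healthy_unique must be logical")
  chk(posint(cfg$seed), "seed must be a positive integer")
  if (!is.null(cfg$atlas)) {
    chk(is.list(cfg$atlas), "atlas must be a list of atlas_config() overrides")
    if (is.list(cfg$atlas)) {
      bad <- setdiff(names(cfg$atlas), names(formals(atlas_config)))
      for (key in bad) {
        dist <- adist(key, names(formals(atlas_config)))
        hint <- names(formals(atlas_config))[which.min(dist)]
        errors <- c(errors,
                    sprintf("Unknown atlas key '%s'; did you mean '%s'?", key, hint))
      }
      if ("doublet_rate" %in% names(cfg$atlas)) {
        chk(frac01(cfg$atlas$doublet_rate) && cfg$atlas$doublet_rate < 0.5,
            "atlas$doublet_rate must lie in [0, 0.5)")
      }
    }
  }
  if (length(errors) > 0) {
    abort(paste0("Invalid configuration:\n",
                 paste0("- ", errors, collapse = "\n")))
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: simulate/read, preprocess, QC, score, crosstalk
#'
#' Executes all stages in order — atlas generation (or reading), depth
#' normalization, PCA, batch-mixing correction, LISI, SNN clustering, pANN
#' doublet scoring, Tukey-fence cluster exclusion, marker annotation,
#' disease scoring, differential expression, Eph-family ranking, and
#' per-condition ligand-receptor permutation analysis with condition
#' comparison — writing every stage output plus `summary.tsv` and
#' `manifest.json` into `out_dir`. A single global seed is expanded into
#' fixed per-stage seed offsets, so identical config and seed reproduce
#' every output bit-identically.
#'
#' @param config A `run_config` (see [validate_config()]), a list of
#'   overrides, a YAML path, or `NULL` for defaults.
#' @param out_dir Output directory (created).
#' @return A `cardiocomm_run` list with all stage results, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("cardiocomm_run_")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  log_stage <- function(...) inform(sprintf(...))

  cm <- if (!is.null(cfg$input_dir)) {
    read_matrix(cfg$input_dir)
  } else {
    generate_atlas(do.call(atlas_config, c(cfg$atlas, list(seed = seed))))
  }
  log_stage("atlas: %d genes x %d cells", nrow(cm$counts), ncol(cm$counts))

  norm <- normalize_log2(cm, scale = cfg$scale)
  emb <- reduce_dimensions(norm, n_hvg = cfg$n_hvg, d = cfg$dims)
  emb_c <- correct_batches(emb, norm$cell_meta$batch,
                           n_groups = cfg$batch_groups,
                           n_iter = cfg$batch_iters, seed = seed + 10L)
  lisi <- compute_lisi(emb_c, norm$cell_meta$batch, perplexity = cfg$perplexity)
  clusters <- cluster_graph(emb_c, k = cfg$k_neighbors,
                            resolution = cfg$resolution, seed = seed + 20L)
  pann <- score_doublets(norm, artificial_fraction = cfg$artificial_fraction,
                         n_hvg = cfg$n_hvg, d = cfg$dims, seed = seed + 30L)
  qc <- exclude_outlier_clusters(norm, lisi, clusters)
  log_stage("qc: %d clusters, %d excluded", nrow(qc), sum(qc$excluded))

  # doublet removal threshold: pann quantile among known singlets when the
  # truth flag exists (synthetic data), otherwise among all cells
  singlet_mask <- !norm$cell_meta$is_doublet
  ref_pann <- pann$pann[if (any(singlet_mask)) singlet_mask else TRUE]
  pann_thr <- quantile(ref_pann, cfg$pann_quantile, names = FALSE)
  kept_clusters <- qc$cluster[!qc$excluded]
  cell_tbl <- norm$cell_meta |>
    left_join(as_tibble(clusters), by = "barcode") |>
    left_join(as_tibble(pann), by = "barcode") |>
    mutate(kept = .data$cluster %in% kept_clusters & .data$pann <= pann_thr)
  log_stage("filter: %d / %d cells kept (pann threshold %.3f)",
            sum(cell_tbl$kept), nrow(cell_tbl), pann_thr)

  panel <- cfg$marker_panel %||% default_marker_panel()
  panel <- panel[vapply(panel, function(gs) any(gs %in% rownames(norm$values)),
                        logical(1))]
  kept_cells <- cell_tbl$barcode[cell_tbl$kept]
  ann <- annotate_types(norm,
                        cell_tbl |> filter(.data$kept) |>
                          select("barcode", "cluster"),
                        panel)
  cell_tbl <- cell_tbl |> left_join(ann, by = "cluster")

  cm_cells <- cell_tbl |> filter(.data$kept, .data$type == "CM")
  score <- disease_score(norm, cells = cm_cells$barcode)
  score_by_cond <- score |>
    left_join(cell_tbl |> select("barcode", "condition"), by = "barcode") |>
    group_by(.data$condition) |>
    summarise(mean_score = mean(.data$score), .groups = "drop")

  de <- de_table(norm,
                 healthy_cells = cm_cells$barcode[cm_cells$condition == "healthy"],
                 disease_cells = cm_cells$barcode[cm_cells$condition == "disease"])
  eph_genes <- intersect(grep("^EPH", de$gene, value = TRUE), de$gene)
  eph_rank <- if (length(eph_genes) > 0) rank_gene_family(de, eph_genes) else NULL

  lr_db <- read_lr_db(cfg$lr_db)
  kept_singlets <- cell_tbl |> filter(.data$kept, !.data$is_doublet)
  run_crosstalk <- function(cond, seed_off) {
    sub <- kept_singlets |> filter(.data$condition == cond)
    score_interactions(subset_cells(norm, sub$barcode), sub$type, lr_db,
                       condition = cond, n_perm = cfg$n_perm,
                       alpha = cfg$alpha, min_frac = cfg$min_frac,
                       seed = seed + seed_off)
  }
  res_h <- suppressWarnings(run_crosstalk("healthy", 40L))
  res_d <- suppressWarnings(run_crosstalk("disease", 41L))
  counts_h <- count_interactions(res_h)
  counts_d <- count_interactions(res_d)
  delta <- compare_conditions(counts_h, counts_d)
  log_stage("crosstalk: %d (healthy) vs %d (disease) significant interactions",
            counts_h$total, counts_d$total)

  sensitivity <- NULL
  if (isTRUE(cfg$drop_healthy_unique)) {
    sub_h <- kept_singlets |> filter(.data$condition == "healthy")
    sub_d <- kept_singlets |> filter(.data$condition == "disease")
    sensitivity <- sensitivity_remove_unique(
      subset_cells(norm, sub_h$barcode), subset_cells(norm, sub_d$barcode),
      sub_h$type, sub_d$type, lr_db,
      n_perm = cfg$n_perm, alpha = cfg$alpha, min_frac = cfg$min_frac,
      seed = seed + 42L)
  }

  top_down <- de$gene[order(de$mean_diff, de$gene)][1]
  top_up <- de$gene[order(-de$mean_diff, de$gene)][1]
  summary_tbl <- tibble(
    metric = c("n_genes", "n_cells", "n_clusters", "n_clusters_excluded",
               "n_cells_kept", "pann_threshold",
               "disease_score_mean_healthy_cm", "disease_score_mean_disease_cm",
               "top_downregulated_gene", "top_upregulated_gene",
               "interactions_healthy_total", "interactions_disease_total",
               "interactions_total_delta", "delta_incoming_cm"),
    value = c(nrow(norm$values), ncol(norm$values), nrow(qc), sum(qc$excluded),
              sum(cell_tbl$kept), round(pann_thr, 6),
              round(score_by_cond$mean_score[score_by_cond$condition == "healthy"], 6),
              round(score_by_cond$mean_score[score_by_cond$condition == "disease"], 6),
              top_down, top_up,
              counts_h$total, counts_d$total, delta$total_delta,
              delta$types$delta_incoming[delta$types$type == "CM"])
  )

  # stage outputs
  write_tsv(as_tibble(lisi), file.path(out_dir, "lisi.tsv"))
  write_tsv(as_tibble(clusters), file.path(out_dir, "clusters.tsv"))
  write_tsv(as_tibble(qc), file.path(out_dir, "cluster_qc.tsv"))
  write_tsv(as_tibble(pann), file.path(out_dir, "doublets.tsv"))
  write_tsv(ann, file.path(out_dir, "annotations.tsv"))
  write_tsv(score, file.path(out_dir, "disease_score.tsv"))
  write_tsv(as_tibble(de), file.path(out_dir, "de_results.tsv"))
  if (!is.null(eph_rank)) write_tsv(eph_rank, file.path(out_dir, "eph_ranking.tsv"))
  write_tsv(as_tibble(res_h), file.path(out_dir, "interactions_healthy.tsv"))
  write_tsv(as_tibble(res_d), file.path(out_dir, "interactions_disease.tsv"))
  write_counts <- function(cc, name) {
    df <- as_tibble(cc$counts, rownames = "donor")
    write_tsv(df, file.path(out_dir, name))
  }
  write_counts(counts_h, "counts_healthy.tsv")
  write_counts(counts_d, "counts_disease.tsv")
  write_counts(counts_h, "circos_matrix_healthy.tsv")
  write_counts(counts_d, "circos_matrix_disease.tsv")
  write_tsv(delta$pairs, file.path(out_dir, "delta.tsv"))
  write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"))

  manifest <- list(
    package = "cardiocomm",
    version = as.character(utils::packageVersion("cardiocomm")),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), "marker_panel")],
    stage_counts = list(
      n_genes = nrow(norm$values), n_cells = ncol(norm$values),
      n_clusters = nrow(qc), n_clusters_excluded = sum(qc$excluded),
      n_cells_kept = sum(cell_tbl$kept),
      n_cm_cells = nrow(cm_cells),
      n_interactions_healthy = counts_h$total,
      n_interactions_disease = counts_d$total
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  out <- list(config = cfg, out_dir = out_dir, counts = cm, norm = norm,
              embedding = emb_c, lisi = lisi, clusters = clusters,
              doublets = pann, cluster_qc = qc, annotations = ann,
              cells = cell_tbl, disease_score = score, de = de,
              eph_rank = eph_rank, interactions_healthy = res_h,
              interactions_disease = res_d, counts_healthy = counts_h,
              counts_disease = counts_d, delta = delta,
              sensitivity = sensitivity, summary = summary_tbl)
  class(out) <- "cardiocomm_run"
  invisible(out)
}

#' @export
print.cardiocomm_run <- function(x, ...) {
  cat("<cardiocomm_run>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
glance.cardiocomm_run <- function(x, ...) {
  tibble(
    n_cells = ncol(x$norm$values),
    n_clusters = nrow(x$cluster_qc),
    n_clusters_excluded = sum(x$cluster_qc$excluded),
    total_healthy = x$counts_healthy$total,
    total_disease = x$counts_disease$total,
    total_delta = x$delta$total_delta
  )
}
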