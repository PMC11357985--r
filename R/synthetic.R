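#' Default cell-type marker panel
#'
#' Marker genes used both to plant cell-type structure in the synthetic
#' atlas and to annotate clusters: cardiomyocytes (CM), endothelial cells
#' (EC), fibroblasts (FB), pericytes (PC), smooth muscle cells (SMC),
#' leukocytes (LC) and monocytes (MC).
#'
#' @return Named list mapping cell-type name to a character vector of
#'   marker genes.
#' @export
default_marker_panel <- function() {
  list(
    CM  = c("TNNT2", "TTN"),
    EC  = c("CDH5", "PECAM1"),
    FB  = c("PDGFRA", "LAMB1"),
    PC  = c("RGS5", "ABCC9"),
    SMC = c("MYH11", "TAGLN"),
    LC  = c("PTPRC", "CD2"),
    MC  = c("CD14", "CD68")
  )
}

#' Cardiomyocyte disease/stress marker panel
#'
#' The fixed ten-gene panel of established cardiomyocyte disease and
#' stress markers whose per-cell mean log-normalized expression defines
#' the disease score.
#'
#' @return Character vector of ten gene symbols.
#' @export
disease_panel <- function() {
  c("NPPA", "NPPB", "MYH7", "MYH7B", "XIRP2", "CMYA5",
    "ANKRD1", "TNNI3", "ACTA1", "PFKP")
}

#' Default planted condition effects
#'
#' Log2 fold changes applied to disease-condition cardiomyocytes in the
#' synthetic atlas: the MYH6 to MYH7 isoform switch, upregulation of the
#' ten disease-score genes, downregulation of Eph receptors (EPHB1 most
#' strongly) and VEGFB, and upregulation of VEGFA.
#'
#' @return Tibble with columns `gene`, `cell_type`, `condition`, `log2fc`.
#' @export
default_effect_table <- function() {
  bind_rows(
    tibble(gene = disease_panel(), cell_type = "CM",
           condition = "disease", log2fc = 1.5),
    tribble(
      ~gene,    ~cell_type, ~condition, ~log2fc,
      "MYH6",   "CM",       "disease",  -2,
      "EPHB1",  "CM",       "disease",  -2,
      "EPHA4",  "CM",       "disease",  -1,
      "EPHA3",  "CM",       "disease",  -0.5,
      "EPHB6",  "CM",       "disease",  -0.25,
      "VEGFB",  "CM",       "disease",  -1,
      "VEGFA",  "CM",       "disease",  1
    )
  )
}

#' Default planted ligand-receptor truth
#'
#' Ligand-receptor axes planted in the synthetic atlas. Endothelial/
#' fibroblast ephrin signalling into cardiomyocytes is active in healthy
#' tissue and switched off in disease; a set of control axes stays active
#' in both conditions.
#'
#' @return Tibble with columns `pair`, `ligand`, `donor`, `receptor`,
#'   `receiver`, `healthy_on`, `disease_on`.
#' @export
default_lr_truth <- function() {
  tribble(
    ~pair,           ~ligand,  ~donor, ~receptor, ~receiver, ~healthy_on, ~disease_on,
    "EFNB2_EPHB1",   "EFNB2",  "EC",   "EPHB1",   "CM",      TRUE,        FALSE,
    "EFNB2_EPHA4",   "EFNB2",  "EC",   "EPHA4",   "CM",      TRUE,        FALSE,
    "EFNA5_EPHA4",   "EFNA5",  "FB",   "EPHA4",   "CM",      TRUE,        FALSE,
    "DLL4_NOTCH1",   "DLL4",   "EC",   "NOTCH1",  "CM",      TRUE,        TRUE,
    "IGF1_IGF1R",    "IGF1",   "FB",   "IGF1R",   "CM",      TRUE,        TRUE,
    "PDGFB_PDGFRB",  "PDGFB",  "EC",   "PDGFRB",  "PC",      TRUE,        TRUE,
    "VEGFA_FLT1",    "VEGFA",  "CM",   "FLT1",    "EC",      TRUE,        TRUE
  )
}

#' Configuration for the synthetic two-condition atlas
#'
#' Defines the study conditions emulated by [generate_atlas()]: a cohort of
#' 14 healthy and 5 disease (hypertrophy) samples over two sequencing
#' batches, seven cell types with planted markers, negative-binomial UMI
#' counts with lognormal library-size spread, an additive log2 batch shift
#' on a random 20% gene subset, heterotypic doublets, planted condition
#' effects in cardiomyocytes, planted ligand-receptor axes, and a small
#' flat-profile low-quality cell population confined to one batch (the
#' analogue of a "lowQC" cluster).
#'
#' @param n_cells_per_type_per_sample Cells simulated per cell type per
#'   sample (singlets).
#' @param n_samples_healthy,n_samples_disease Number of samples per
#'   condition.
#' @param n_genes Total genes in the simulated universe.
#' @param cell_types Named list mapping type name to marker genes.
#' @param base_mean Per-gene negative-binomial base mean (counts). A single
#'   number is used uniformly for every gene; a vector of length `n_genes`
#'   is used as is. `NULL` draws filler-gene means from
#'   lognormal(log 0.2, 1) and uses 0.5 for named genes.
#' @param dispersion Negative-binomial size parameter (inverse
#'   overdispersion); variance is `mu + mu^2 / dispersion`.
#' @param batch_shift Additive shift on log2 mean applied in the second
#'   batch to `batch_gene_fraction` of genes.
#' @param batch_gene_fraction Fraction of genes receiving the batch shift.
#' @param libsize_sdlog Standard deviation (log scale) of the per-cell
#'   lognormal library-size factor.
#' @param marker_log2fc Log2 elevation of marker genes in their own type.
#' @param n_program_genes_per_type Number of filler genes forming each
#'   type's broader expression program (disjoint across types), elevated
#'   by `program_log2fc` in that type. Real cell types differ across many
#'   genes, not only canonical markers; this is what makes the types
#'   separable in PCA space.
#' @param program_log2fc Log2 elevation of program genes in their type.
#' @param lr_log2fc Log2 elevation of planted ligand/receptor genes in
#'   their donor/receiver type when the axis is active.
#' @param effect_table Tibble of planted condition effects
#'   (`gene`, `cell_type`, `condition`, `log2fc`).
#' @param doublet_rate Fraction of heterotypic doublets appended, in
#'   `[0, 0.5)`; the number appended is `floor(rate * n_singlets)`.
#' @param lr_truth Tibble of planted ligand-receptor axes (see
#'   [default_lr_truth()]).
#' @param n_junk_cells Number of flat-profile, depth-inflated low-quality
#'   cells confined to the second batch (0 disables).
#' @param n_healthy_unique Number of filler genes expressed exclusively in
#'   healthy cells (synthetic fixture for the unique-gene-removal
#'   sensitivity analysis); 0 disables.
#' @param seed Integer RNG seed; identical config and seed give
#'   bit-identical atlases.
#'
#' @return An `atlas_config` list, validated.
#' @export
atlas_config <- function(n_cells_per_type_per_sample = 20,
                         n_samples_healthy = 14,
                         n_samples_disease = 5,
                         n_genes = 2000,
                         cell_types = default_marker_panel(),
                         base_mean = NULL,
                         dispersion = 2,
                         batch_shift = 1,
                         batch_gene_fraction = 0.2,
                         libsize_sdlog = 0.3,
                         marker_log2fc = 3,
                         n_program_genes_per_type = 60,
                         program_log2fc = 3,
                         lr_log2fc = 3,
                         effect_table = default_effect_table(),
                         doublet_rate = 0.05,
                         lr_truth = default_lr_truth(),
                         n_junk_cells = 60,
                         n_healthy_unique = 0,
                         seed = 1) {
  cfg <- list(
    n_cells_per_type_per_sample = as.integer(n_cells_per_type_per_sample),
    n_samples_healthy = as.integer(n_samples_healthy),
    n_samples_disease = as.integer(n_samples_disease),
    n_genes = as.integer(n_genes),
    cell_types = cell_types,
    base_mean = base_mean,
    dispersion = dispersion,
    batch_shift = batch_shift,
    batch_gene_fraction = batch_gene_fraction,
    libsize_sdlog = libsize_sdlog,
    marker_log2fc = marker_log2fc,
    n_program_genes_per_type = as.integer(n_program_genes_per_type),
    program_log2fc = program_log2fc,
    lr_log2fc = lr_log2fc,
    effect_table = as_tibble(effect_table),
    doublet_rate = doublet_rate,
    lr_truth = as_tibble(lr_truth),
    n_junk_cells = as.integer(n_junk_cells),
    n_healthy_unique = as.integer(n_healthy_unique),
    seed = as.integer(seed)
  )
  class(cfg) <- "atlas_config"
  validate_atlas_config(cfg)
  cfg
}

validate_atlas_config <- function(cfg) {
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 0.5) {
    abort("`doublet_rate` must lie in [0, 0.5).")
  }
  if (nrow(cfg$effect_table) > 0 && !all(is.finite(cfg$effect_table$log2fc))) {
    abort("All planted fold changes must be finite.")
  }
  universe <- atlas_gene_universe(cfg)
  named <- unique(c(cfg$effect_table$gene, cfg$lr_truth$ligand, cfg$lr_truth$receptor))
  missing <- setdiff(named, universe)
  if (length(missing) > 0) {
    abort(paste0("Genes named in effect_table/lr_truth do not fit in the ",
                 "gene universe: ", paste(missing, collapse = ", ")))
  }
  bad_type <- setdiff(
    unique(c(cfg$effect_table$cell_type, cfg$lr_truth$donor, cfg$lr_truth$receiver)),
    names(cfg$cell_types)
  )
  if (length(bad_type) > 0) {
    abort(paste0("Unknown cell type in effect_table/lr_truth: ",
                 paste(bad_type, collapse = ", ")))
  }
  invisible(cfg)
}

# Named (special) genes first, then filler G####; the last
# `n_healthy_unique` filler genes are reserved for healthy-only expression.
# The named catalogue is fixed: cell-type markers, the disease panel, the
# MYH6 isoform, the default planted-effect genes, and every gene of the
# shipped ligand-receptor database, so planted effects and L-R axes can
# only reference genes that exist.
atlas_gene_universe <- function(cfg) {
  db <- read_lr_db()
  special <- unique(c(
    unlist(cfg$cell_types, use.names = FALSE),
    disease_panel(), "MYH6",
    default_effect_table()$gene,
    unlist(split_subunits(c(db$ligand_genes, db$receptor_genes)))
  ))
  if (length(special) + cfg$n_healthy_unique >= cfg$n_genes) {
    abort("`n_genes` too small for the named genes plus healthy-unique filler.")
  }
  n_fill <- cfg$n_genes - length(special)
  filler <- setdiff(sprintf("G%04d", seq_len(n_fill + length(special))), special)
  c(special, filler[seq_len(n_fill)])
}

#' Generate a synthetic two-condition, two-batch snRNA-seq atlas
#'
#' Draws a sparse gene-by-cell UMI count matrix from a gamma-Poisson
#' (negative-binomial) model with planted cell-type markers, a linear
#' batch shift on the log2 mean for a random gene subset, per-cell
#' lognormal library-size factors, planted condition effects and
#' ligand-receptor structure, an optional flat-profile low-quality
#' population, and appended heterotypic doublets.
#'
#' @param config An [atlas_config()] object.
#' @return A `count_matrix`: list with `counts` (sparse dgCMatrix, genes x
#'   cells) and `cell_meta` (tibble: `barcode`, `sample_id`, `condition`,
#'   `batch`, `true_type`, `is_doublet`).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  validate_atlas_config(config)
  genes <- atlas_gene_universe(config)
  ng <- config$n_genes
  types <- names(config$cell_types)

  with_seed(config$seed, {
    base_mean <- config$base_mean
    if (is.null(base_mean)) {
      base_mean <- rlnorm(ng, meanlog = log(0.2), sdlog = 1)
      base_mean[!startsWith(genes, "G")] <- 0.5
    } else if (length(base_mean) == 1) {
      base_mean <- rep(base_mean, ng)
    }
    stopifnot(length(base_mean) == ng, all(base_mean >= 0))

    samples <- tibble(
      sample_id = c(sprintf("H%02d", seq_len(config$n_samples_healthy)),
                    sprintf("D%02d", seq_len(config$n_samples_disease))),
      condition = rep(c("healthy", "disease"),
                      c(config$n_samples_healthy, config$n_samples_disease))
    ) |>
      group_by(.data$condition) |>
      mutate(batch = paste0("b", 1 + (row_number() - 1) %% 2)) |>
      ungroup()

    cell_meta <- tidyr::expand_grid(samples, true_type = types) |>
      tidyr::uncount(config$n_cells_per_type_per_sample) |>
      mutate(is_doublet = FALSE)

    if (config$n_junk_cells > 0) {
      junk_pool <- samples |> filter(.data$batch == "b2")
      junk <- junk_pool[sample.int(nrow(junk_pool), config$n_junk_cells,
                                   replace = TRUE), ] |>
        mutate(true_type = "lowQC", is_doublet = FALSE)
      cell_meta <- bind_rows(cell_meta, junk)
    }
    nc <- nrow(cell_meta)
    cell_meta <- cell_meta |>
      mutate(barcode = sprintf("cell_%05d", seq_len(nc)), .before = 1)

    # log2-additive mean model: base * 2^(batch + marker + effect + LR)
    log2mu <- matrix(log2(base_mean), ng, nc)
    batch_genes <- sample.int(ng, round(config$batch_gene_fraction * ng))
    in_b2 <- cell_meta$batch == "b2"
    log2mu[batch_genes, in_b2] <- log2mu[batch_genes, in_b2] + config$batch_shift

    gidx <- setNames(seq_len(ng), genes)
    for (ty in types) {
      mg <- gidx[config$cell_types[[ty]]]
      cc <- cell_meta$true_type == ty
      log2mu[mg, cc] <- log2mu[mg, cc] + config$marker_log2fc
    }
    # broader per-type expression programs on disjoint filler-gene sets
    if (config$n_program_genes_per_type > 0) {
      filler <- which(startsWith(genes, "G"))
      if (config$n_healthy_unique > 0) {
        filler <- setdiff(filler, seq(ng - config$n_healthy_unique + 1L, ng))
      }
      need <- config$n_program_genes_per_type * length(types)
      if (need > length(filler)) {
        abort("Not enough filler genes for the per-type programs.")
      }
      prog <- matrix(sample(filler, need), ncol = length(types))
      for (j in seq_along(types)) {
        cc <- cell_meta$true_type == types[j]
        log2mu[prog[, j], cc] <- log2mu[prog[, j], cc] + config$program_log2fc
      }
    }
    if (nrow(config$effect_table) > 0) {
      for (i in seq_len(nrow(config$effect_table))) {
        e <- config$effect_table[i, ]
        cc <- cell_meta$true_type == e$cell_type & cell_meta$condition == e$condition
        log2mu[gidx[e$gene], cc] <- log2mu[gidx[e$gene], cc] + e$log2fc
      }
    }
    if (nrow(config$lr_truth) > 0) {
      boosts <- bind_rows(
        config$lr_truth |> transmute(gene = .data$ligand, type = .data$donor,
                                     .data$healthy_on, .data$disease_on),
        config$lr_truth |> transmute(gene = .data$receptor, type = .data$receiver,
                                     .data$healthy_on, .data$disease_on)
      ) |>
        tidyr::pivot_longer(c("healthy_on", "disease_on"),
                            names_to = "condition", values_to = "on") |>
        mutate(condition = sub("_on$", "", .data$condition)) |>
        filter(.data$on) |>
        distinct(.data$gene, .data$type, .data$condition)
      for (i in seq_len(nrow(boosts))) {
        b <- boosts[i, ]
        cc <- cell_meta$true_type == b$type & cell_meta$condition == b$condition
        log2mu[gidx[b$gene], cc] <- log2mu[gidx[b$gene], cc] + config$lr_log2fc
      }
    }

    mu <- 2^log2mu
    junk_cols <- cell_meta$true_type == "lowQC"
    if (any(junk_cols)) {
      # flat, depth-inflated profile: broad gene detection, one batch only
      mu[, junk_cols] <- 5 * mean(base_mean)
    }
    if (config$n_healthy_unique > 0) {
      hu <- seq(ng - config$n_healthy_unique + 1L, ng)
      mu[hu, ] <- 0
      mu[hu, cell_meta$condition == "healthy"] <- mean(base_mean)
    }

    lib <- rlnorm(nc, 0, config$libsize_sdlog)
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = config$dispersion),
                     ng, nc, dimnames = list(genes, cell_meta$barcode))
    cm <- new_count_matrix(as(counts, "CsparseMatrix"), cell_meta)
    if (config$doublet_rate > 0) {
      cm <- inject_doublets(cm, config$doublet_rate, seed = config$seed + 1L)
    }
    cm
  })
}

new_count_matrix <- function(counts, cell_meta) {
  cell_meta <- as_tibble(cell_meta)
  stopifnot(ncol(counts) == nrow(cell_meta),
            identical(colnames(counts), cell_meta$barcode))
  if (anyDuplicated(cell_meta$barcode)) abort("Duplicate cell barcodes.")
  if (length(counts@x) > 0 && (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    abort("Counts must be nonnegative integers.")
  }
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%d doublet-flagged)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$cell_meta$is_doublet %||% FALSE)))
  invisible(x)
}

#' Append heterotypic doublets to a count matrix
#'
#' Appends `floor(rate * n_singlets)` artificial cells, each the gene-wise
#' sum of the raw counts of two randomly chosen singlets of different true
#' types, flagged `is_doublet = TRUE`. Sample, condition and batch are
#' inherited from the first parent; `true_type` records both parent types
#' joined by `+`.
#'
#' @param matrix A `count_matrix`.
#' @param rate Doublet fraction in `[0, 0.5)`.
#' @param seed Integer RNG seed.
#' @return The augmented `count_matrix` (unchanged when `rate` is 0).
#' @export
inject_doublets <- function(matrix, rate, seed = 1) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (rate < 0 || rate >= 0.5) abort("`rate` must lie in [0, 0.5).")
  singlet <- which(!matrix$cell_meta$is_doublet)
  n_d <- floor(rate * length(singlet))
  if (n_d == 0) return(matrix)
  if (length(singlet) < 2) abort("Need at least 2 singlets to form doublets.")
  types <- matrix$cell_meta$true_type[singlet]
  if (length(unique(types)) < 2) {
    abort("Heterotypic doublets need at least 2 distinct true types.")
  }
  with_seed(seed, {
    p1 <- integer(n_d); p2 <- integer(n_d)
    for (i in seq_len(n_d)) {
      a <- sample(singlet, 1)
      pool <- singlet[types != matrix$cell_meta$true_type[a]]
      b <- if (length(pool) == 1) pool else sample(pool, 1)
      p1[i] <- a; p2[i] <- b
    }
    d_counts <- matrix$counts[, p1, drop = FALSE] + matrix$counts[, p2, drop = FALSE]
    bc <- sprintf("doublet_%04d", seq_len(n_d))
    colnames(d_counts) <- bc
    m1 <- matrix$cell_meta[p1, ]
    d_meta <- m1 |>
      mutate(
        barcode = bc,
        true_type = paste(
          pmin(m1$true_type, matrix$cell_meta$true_type[p2]),
          pmax(m1$true_type, matrix$cell_meta$true_type[p2]), sep = "+"),
        is_doublet = TRUE
      )
    new_count_matrix(cbind(matrix$counts, d_counts),
                     bind_rows(matrix$cell_meta, d_meta))
  })
}
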