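#' Annotate clusters by marker-panel expression
#'
#' Scores each cluster against each marker panel by the mean normalized
#' expression of the panel genes over member cells, z-scored per panel
#' across clusters. A cluster is labelled with the panel maximizing the
#' z-score; when the runner-up lies within 10% of the top z-score the
#' cluster is labelled as the hybrid `"A-B"` (top panel first).
#'
#' @param norm A `normalized_matrix`.
#' @param clusters A `cluster_labels` tibble.
#' @param panel Named list mapping type name to marker genes; genes absent
#'   from the matrix are dropped with a warning.
#' @param tie_tol Relative tie tolerance for hybrid labelling.
#' @return Tibble: `cluster`, `type`.
#' @export
annotate_types <- function(norm, clusters, panel, tie_tol = 0.1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (length(panel) == 0) abort("Empty marker panel.")
  genes <- rownames(norm$values)
  panel <- imap(panel, function(gs, ty) {
    miss <- setdiff(gs, genes)
    if (length(miss) > 0) {
      warn(paste0("Dropping missing marker genes for ", ty, ": ",
                  paste(miss, collapse = ", ")))
    }
    intersect(gs, genes)
  })
  if (any(lengths(panel) == 0)) abort("A marker panel has no genes present in the matrix.")
  clusters <- as_tibble(clusters)
  ids <- sort(unique(clusters$cluster))
  cell_of <- match(clusters$barcode, colnames(norm$values))
  score <- vapply(ids, function(cl) {
    cells <- cell_of[clusters$cluster == cl]
    vapply(panel, function(gs) {
      v <- norm$values[gs, cells, drop = FALSE]
      sum(v) / (length(gs) * length(cells))  # sum is primitive: S4-dispatches on sparse

    }, numeric(1))
  }, numeric(length(panel)))  # panels x clusters
  score <- matrix(score, nrow = length(panel),
                  dimnames = list(names(panel), ids))
  z <- t(scale(t(score)))  # z per panel across clusters
  z[is.nan(z)] <- 0
  labels <- vapply(seq_along(ids), function(j) {
    zs <- sort(z[, j], decreasing = TRUE)
    if (length(zs) > 1 && zs[2] >= zs[1] - tie_tol * abs(zs[1])) {
      paste(names(zs)[1:2], collapse = "-")
    } else {
      names(zs)[1]
    }
  }, character(1))
  tibble(cluster = ids, type = labels)
}

#' Per-cell cardiomyocyte disease score
#'
#' The mean of log2-normalized expression over the ten-gene cardiomyocyte
#' disease/stress panel ([disease_panel()]), per cell. Panel genes absent
#' from the matrix are dropped with a warning; the score is 0 exactly when
#' every present panel gene has zero counts in the cell.
#'
#' @param norm A `normalized_matrix`.
#' @param cells Optional character vector of barcodes to score (default
#'   all cells).
#' @param panel Gene panel (defaults to the ten-gene disease panel).
#' @return Tibble: `barcode`, `score`.
#' @export
disease_score <- function(norm, cells = NULL, panel = disease_panel()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  present <- intersect(panel, rownames(norm$values))
  if (length(present) == 0) abort("No disease-panel gene present in the matrix.")
  if (length(present) < length(panel)) {
    warn(paste0("Disease-panel genes missing from matrix: ",
                paste(setdiff(panel, present), collapse = ", ")))
  }
  v <- norm$values
  if (!is.null(cells)) v <- v[, match(cells, colnames(v)), drop = FALSE]
  tibble(barcode = colnames(v),
         score = unname(Matrix::colMeans(v[present, , drop = FALSE])))
}

# Bimodal-likelihood sufficient statistics per gene for a cell group:
# zero/positive counts and first/second moments of the positive values.
bimod_stats <- function(values) {
  n <- ncol(values)
  npos <- Matrix::rowSums(values > 0)
  s1 <- Matrix::rowSums(values)
  s2 <- Matrix::rowSums(values^2)
  list(n = n, npos = npos, n0 = n - npos, s1 = s1, s2 = s2)
}

# Log-likelihood of the bimodal model for one group under a shared sigma:
# zero with probability 1 - pi, Normal(mu, sigma^2) when positive, with
# pi and mu at their MLEs. 0*log(0) terms are taken as 0 (boundary pi).
bimod_ll <- function(st, sigma) {
  pi_hat <- st$npos / st$n
  zero_part <- ifelse(st$n0 > 0, st$n0 * log(pmax(1 - pi_hat, .Machine$double.xmin)), 0)
  pos_part <- ifelse(st$npos > 0, st$npos * log(pmax(pi_hat, .Machine$double.xmin)), 0)
  # sum over positives of dnorm(x; mu_hat, sigma): uses s2 - s1^2/npos
  rss <- ifelse(st$npos > 0, st$s2 - st$s1^2 / pmax(st$npos, 1), 0)
  norm_part <- ifelse(
    st$npos > 0,
    -st$npos / 2 * log(2 * pi * sigma^2) - rss / (2 * sigma^2),
    0)
  zero_part + pos_part + norm_part
}

bimod_lrt_vec <- function(va, vb) {
  sa <- bimod_stats(va)
  sb <- bimod_stats(vb)
  sp <- list(n = sa$n + sb$n, npos = sa$npos + sb$npos,
             n0 = sa$n0 + sb$n0, s1 = sa$s1 + sb$s1, s2 = sa$s2 + sb$s2)
  # shared sigma from pooled positive values
  rss_p <- sp$s2 - sp$s1^2 / pmax(sp$npos, 1)
  sigma <- ifelse(sp$npos > 1, sqrt(pmax(rss_p, 0) / (sp$npos - 1)), 1)
  sigma <- pmax(sigma, 1e-6)
  stat <- pmax(0, 2 * (bimod_ll(sa, sigma) + bimod_ll(sb, sigma) - bimod_ll(sp, sigma)))
  tibble(gene = rownames(va), lrt_stat = stat,
         p = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Bimodal likelihood-ratio test for one gene
#'
#' Tests differential expression between two cell groups under a bimodal
#' model: expression is zero with probability `1 - pi` and
#' `Normal(mu, sigma^2)` when positive. `pi` and `mu` are fitted per group
#' and pooled; `sigma` is shared, estimated from the pooled positive
#' values. The statistic is `2 * (ll_a + ll_b - ll_pooled)`, compared to a
#' chi-squared distribution with 2 degrees of freedom. Groups with no
#' positive values are handled at the `pi = 0` boundary.
#'
#' @param norm A `normalized_matrix`.
#' @param cells_a,cells_b Barcodes of the two non-empty groups.
#' @param gene Gene identifier.
#' @return Tibble: `gene`, `lrt_stat`, `p`.
#' @export
bimod_lrt <- function(norm, cells_a, cells_b, gene) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!gene %in% rownames(norm$values)) abort(paste0("Gene not found: ", gene))
  if (length(cells_a) == 0 || length(cells_b) == 0) abort("Both groups must be non-empty.")
  va <- norm$values[gene, match(cells_a, colnames(norm$values)), drop = FALSE]
  vb <- norm$values[gene, match(cells_b, colnames(norm$values)), drop = FALSE]
  bimod_lrt_vec(va, vb)
}

#' Differential expression between conditions (bimod LRT + Bonferroni)
#'
#' Computes, per gene, mean log2-normalized expression in each group, the
#' mean difference (disease minus healthy), the bimodal likelihood-ratio
#' statistic and p-value, and the Bonferroni-adjusted p-value using the
#' total number of genes in the dataset (`p_adj = min(1, p * n_genes)`),
#' regardless of how many genes are tested. Optionally adds a per-patient
#' clustered t-test p-value (`p_patient`) from per-sample pseudobulk
#' means.
#'
#' @param norm A `normalized_matrix`.
#' @param healthy_cells,disease_cells Barcodes of the two groups.
#' @param genes Genes to test (default all).
#' @param clustered Add the per-patient clustered t-test p-value (requires
#'   `sample_id` and `condition` in the metadata, with at least 2 samples
#'   per condition among the given cells).
#' @return A `de_table` tibble: `gene`, `mean_healthy`, `mean_disease`,
#'   `mean_diff`, `lrt_stat`, `p`, `p_adj` (and `p_patient` when
#'   `clustered`).
#' @export
de_table <- function(norm, healthy_cells, disease_cells, genes = NULL,
                     clustered = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  n_genes_total <- nrow(norm$values)
  if (is.null(genes)) genes <- rownames(norm$values)
  miss <- setdiff(genes, rownames(norm$values))
  if (length(miss) > 0) abort(paste0("Genes not found: ", paste(miss, collapse = ", ")))
  ia <- match(healthy_cells, colnames(norm$values))
  ib <- match(disease_cells, colnames(norm$values))
  va <- norm$values[genes, ia, drop = FALSE]
  vb <- norm$values[genes, ib, drop = FALSE]
  out <- bimod_lrt_vec(va, vb) |>
    mutate(mean_healthy = unname(Matrix::rowMeans(va)),
           mean_disease = unname(Matrix::rowMeans(vb)),
           mean_diff = .data$mean_disease - .data$mean_healthy,
           p_adj = pmin(1, .data$p * n_genes_total)) |>
    select("gene", "mean_healthy", "mean_disease", "mean_diff",
           "lrt_stat", "p", "p_adj")
  if (clustered) {
    meta <- norm$cell_meta
    cells <- c(healthy_cells, disease_cells)
    out$p_patient <- vapply(genes, function(g) {
      res <- clustered_t_test(norm, g,
                              sample_ids = meta$sample_id[match(cells, meta$barcode)],
                              condition = meta$condition[match(cells, meta$barcode)],
                              cells = cells)
      res$p_value
    }, numeric(1))
  }
  structure(out, class = c("de_table", class(tibble())),
            n_genes_total = n_genes_total)
}

# Pooled-variance two-sample t-test on two vectors of per-sample means.
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  diff <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  if (sp2 == 0) {
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    stat <- diff / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * pt(-abs(stat), df)
  }
  tibble(statistic = stat, df = df, p_value = p)
}

#' Per-patient clustered t-test for one gene
#'
#' Collapses cells to per-sample pseudobulk means of the gene's normalized
#' expression and applies a two-sided pooled-variance two-sample t-test on
#' the sample means between conditions, so within-sample correlation of
#' cells is respected by aggregation. When the pooled variance is zero and
#' the group means differ, the p-value underflows (reported as 0,
#' effectively below 1e-15).
#'
#' @param norm A `normalized_matrix`.
#' @param gene Gene identifier.
#' @param sample_ids,condition Per-cell sample and condition labels
#'   (defaults taken from the metadata). Each condition needs at least 2
#'   samples.
#' @param cells Optional barcodes restricting the cells used.
#' @return Tibble: `statistic`, `df`, `p_value`, `mean_healthy`,
#'   `mean_disease`.
#' @export
clustered_t_test <- function(norm, gene, sample_ids = NULL, condition = NULL,
                             cells = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!gene %in% rownames(norm$values)) abort(paste0("Gene not found: ", gene))
  if (is.null(cells)) cells <- colnames(norm$values)
  idx <- match(cells, colnames(norm$values))
  if (is.null(sample_ids)) sample_ids <- norm$cell_meta$sample_id[idx]
  if (is.null(condition)) condition <- norm$cell_meta$condition[idx]
  v <- norm$values[gene, idx]
  df <- tibble(v = as.numeric(v), sample_id = sample_ids, condition = condition) |>
    group_by(.data$condition, .data$sample_id) |>
    summarise(m = mean(.data$v), .groups = "drop")
  per_cond <- split(df$m, df$condition)
  if (length(per_cond) != 2 || any(lengths(per_cond) < 2)) {
    abort("Each of the two conditions needs at least 2 samples.")
  }
  h <- per_cond[["healthy"]] %||% per_cond[[1]]
  d <- per_cond[["disease"]] %||% per_cond[[2]]
  pooled_t(h, d) |>
    mutate(mean_healthy = mean(h), mean_disease = mean(d))
}

#' Rank a gene family by differential expression
#'
#' Sorts genes ascending by `mean_diff` (disease minus healthy), so the
#' most downregulated gene comes first; ties break alphabetically.
#'
#' @param de A `de_table`.
#' @param genes Non-empty character vector of genes present in `de`.
#' @return The corresponding rows of `de`, ranked, with a `rank` column.
#' @export
rank_gene_family <- function(de, genes) {
  if (length(genes) == 0) abort("`genes` must be non-empty.")
  miss <- setdiff(genes, de$gene)
  if (length(miss) > 0) abort(paste0("Genes absent from DE table: ",
                                     paste(miss, collapse = ", ")))
  de |>
    filter(.data$gene %in% genes) |>
    arrange(.data$mean_diff, .data$gene) |>
    mutate(rank = row_number())
}

#' @export
glance.de_table <- function(x, alpha = 0.05, ...) {
  tibble(
    n_genes_tested = nrow(x),
    n_genes_total = attr(x, "n_genes_total"),
    n_up = sum(x$p_adj < alpha & x$mean_diff > 0),
    n_down = sum(x$p_adj < alpha & x$mean_diff < 0)
  )
}
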