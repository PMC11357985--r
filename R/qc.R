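#' Batch-mixing correction by iterative centroid matching
#'
#' A light-weight integration step with the contract of a shared-embedding
#' batch correction: cells are grouped by k-means into `n_groups` putative
#' cell-type groups, and within each group every batch's centroid offset
#' from the group centroid is subtracted from that batch's cells. The two
#' steps alternate for `n_iter` iterations. On data whose batches differ by
#' location shifts this aligns batch centroids per group and increases the
#' local batch-mixing (LISI) score without altering within-batch geometry.
#'
#' @param embedding An `embedding`.
#' @param batch_labels Per-cell batch label (length = number of cells).
#' @param n_groups Number of k-means groups (putative cell types).
#' @param n_iter Number of alternation iterations.
#' @param seed Integer RNG seed for k-means initialization.
#' @return A corrected `embedding` of identical shape. With a single batch
#'   the input is returned unchanged with a warning.
#' @export
correct_batches <- function(embedding, batch_labels, n_groups = 10,
                            n_iter = 5, seed = 1) {
  stopifnot(inherits(embedding, "embedding"), n_groups >= 1)
  x <- embedding$coords
  stopifnot(length(batch_labels) == nrow(x))
  batches <- unique(batch_labels)
  if (length(batches) < 2) {
    warn("Single batch: nothing to correct, returning input unchanged.")
    return(embedding)
  }
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      grp <- if (n_groups == 1) rep(1L, nrow(x)) else {
        kmeans(x, centers = n_groups, nstart = 3, iter.max = 50)$cluster
      }
      for (g in unique(grp)) {
        gi <- grp == g
        g_cent <- colMeans(x[gi, , drop = FALSE])
        for (b in batches) {
          bi <- gi & batch_labels == b
          if (!any(bi)) next
          off <- colMeans(x[bi, , drop = FALSE]) - g_cent
          x[bi, ] <- sweep(x[bi, , drop = FALSE], 2, off, "-")
        }
      }
    }
  })
  structure(list(coords = x, d = embedding$d, hvg = embedding$hvg),
            class = "embedding")
}

#' Local Inverse Simpson's Index of batch mixing
#'
#' For each cell, neighbours within the `ceiling(3 * perplexity)` nearest
#' cells are weighted by a Gaussian kernel whose bandwidth is tuned per
#' cell so the weight entropy matches `log(perplexity)`; label
#' probabilities are the normalized weight mass per label and the LISI is
#' the inverse Simpson index `1 / sum(p^2)`. A neighbourhood whose weight
#' lies entirely in one dataset scores exactly 1; a neighbourhood split
#' equally between two datasets scores exactly 2.
#'
#' @param embedding An `embedding`.
#' @param labels Per-cell label (batch/dataset).
#' @param perplexity Effective neighbourhood size (must be < number of
#'   cells).
#' @return A `lisi_vector` tibble: `barcode`, `lisi`; attribute
#'   `perplexity`.
#' @export
compute_lisi <- function(embedding, labels, perplexity = 30) {
  stopifnot(inherits(embedding, "embedding"))
  x <- embedding$coords
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (perplexity >= n) abort("`perplexity` must be smaller than the number of cells.")
  labels <- as.character(labels)
  lab_levels <- sort(unique(labels))
  k <- min(n - 1L, as.integer(ceiling(3 * perplexity)))
  nn <- knn_exact(x, k = k)
  lab_idx <- matrix(match(labels[nn$index], lab_levels), n, k)
  lisi <- vapply(seq_len(n), function(i) {
    w <- perplexity_weights(nn$dist2[i, ], perplexity)
    p <- vapply(seq_along(lab_levels),
                function(l) sum(w[lab_idx[i, ] == l]), numeric(1))
    p <- p / sum(p)
    1 / sum(p^2)
  }, numeric(1))
  structure(tibble(barcode = rownames(x), lisi = lisi),
            class = c("lisi_vector", class(tibble())),
            perplexity = perplexity)
}

# Gaussian kernel weights over squared distances with bandwidth tuned by
# binary search so that the Shannon entropy of the normalized weights
# equals log(perplexity).
perplexity_weights <- function(d2, perplexity, tol = 1e-11, max_iter = 128) {
  d2 <- d2 - min(d2)
  if (all(d2 == 0)) return(rep(1 / length(d2), length(d2)))
  target <- log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    h <- log(sw) + beta * sum(d2 * w) / sw
    if (abs(h - target) < tol) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else            { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w / sum(w)
}

#' Shared-nearest-neighbour graph clustering
#'
#' Builds an exact kNN graph in the embedding, weights edges by the
#' Jaccard overlap of (self-inclusive) neighbour sets, prunes overlaps
#' below 1/15, and partitions the graph with Leiden modularity
#' optimization at the given resolution. Deterministic for a fixed seed;
#' cluster ids are contiguous integers from 0, ordered by decreasing size.
#'
#' @param embedding An `embedding`.
#' @param k Neighbours per cell (default 20).
#' @param resolution Modularity resolution parameter (default 0.25).
#' @param seed Integer RNG seed.
#' @return A `cluster_labels` tibble: `barcode`, `cluster`; attributes
#'   `resolution`, `n_dims_used`.
#' @export
cluster_graph <- function(embedding, k = 20, resolution = 0.25, seed = 1) {
  stopifnot(inherits(embedding, "embedding"))
  x <- embedding$coords
  n <- nrow(x)
  if (n == 0) abort("Empty embedding.")
  if (k >= n) abort("`k` must be smaller than the number of cells.")
  nn <- knn_exact(x, k = k)
  # self-inclusive neighbour incidence; SNN weight = Jaccard overlap
  adj <- sparseMatrix(
    i = c(rep(seq_len(n), k), seq_len(n)),
    j = c(as.vector(nn$index), seq_len(n)),
    x = 1, dims = c(n, n))
  shared <- tcrossprod(adj)
  snn <- shared
  snn@x <- snn@x / (2 * (k + 1) - snn@x)
  snn@x[snn@x < 1 / 15] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  g <- graph_from_adjacency_matrix(snn, mode = "undirected", weighted = TRUE)
  memb <- with_seed(seed, {
    membership(cluster_leiden(g, objective_function = "modularity",
                              resolution = resolution, n_iterations = 10))
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  structure(tibble(barcode = rownames(x),
                   cluster = unname(relabel[as.character(memb)])),
            class = c("cluster_labels", class(tibble())),
            resolution = resolution, n_dims_used = embedding$d)
}

#' Doublet scoring by proportion of artificial nearest neighbours (pANN)
#'
#' Generates artificial doublets by averaging the normalized profiles of
#' random cell pairs, re-embeds real and artificial cells jointly, and
#' scores each real cell by the fraction of artificial cells among its
#' `k` nearest neighbours in the joint embedding.
#'
#' @param norm A `normalized_matrix`.
#' @param artificial_fraction Fraction of artificial doublets generated,
#'   relative to the number of real cells, in (0, 1).
#' @param k Neighbour count; default `round(0.01 * n_cells)` bounded to
#'   `[10, 100]`.
#' @param n_hvg,d Embedding parameters for the joint re-embedding.
#' @param seed Integer RNG seed.
#' @return A `doublet_scores` tibble: `barcode`, `pann`; attributes
#'   `artificial_fraction`, `k`.
#' @export
score_doublets <- function(norm, artificial_fraction = 0.25, k = NULL,
                           n_hvg = 2000, d = 12, seed = 1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (artificial_fraction <= 0 || artificial_fraction >= 1) {
    abort("`artificial_fraction` must lie in (0, 1).")
  }
  n <- ncol(norm$values)
  n_art <- max(1L, floor(artificial_fraction * n))
  if (is.null(k)) k <- min(100L, max(10L, as.integer(round(0.01 * n))))
  if (k > n + n_art - 1) abort("`k` exceeds the total number of cells.")
  with_seed(seed, {
    p1 <- sample.int(n, n_art, replace = TRUE)
    p2 <- sample.int(n, n_art, replace = TRUE)
    art <- (norm$values[, p1, drop = FALSE] + norm$values[, p2, drop = FALSE]) / 2
    colnames(art) <- sprintf("artificial_%05d", seq_len(n_art))
    joint <- structure(
      list(values = cbind(norm$values, art),
           cell_meta = tibble(barcode = c(colnames(norm$values), colnames(art)))),
      class = "normalized_matrix")
    emb <- reduce_dimensions(joint, n_hvg = n_hvg, d = d)
    nn <- knn_exact(emb$coords, k = k)
    is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
    pann <- rowMeans(matrix(is_art[nn$index[seq_len(n), ]], n, k))
    structure(tibble(barcode = colnames(norm$values), pann = pann),
              class = c("doublet_scores", class(tibble())),
              artificial_fraction = artificial_fraction, k = k)
  })
}

#' Cluster-level QC by the genes/LISI ratio Tukey fence
#'
#' Computes, per cell, the ratio of the number of genes expressed to the
#' LISI score; averages it per cluster; and flags clusters whose mean
#' ratio lies above `Q3 + 1.5 * IQR` or below `Q1 - 1.5 * IQR` of the
#' cluster means (quartiles by linear interpolation between order
#' statistics). Flagged clusters are excluded from downstream analysis.
#'
#' @param norm A `normalized_matrix` (provides `n_genes_expressed`).
#' @param lisi A `lisi_vector` tibble.
#' @param clusters A `cluster_labels` tibble.
#' @return A `cluster_qc` tibble: `cluster`, `n_cells`, `mean_ratio`,
#'   `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`, `excluded`.
#' @export
exclude_outlier_clusters <- function(norm, lisi, clusters) {
  stopifnot(inherits(norm, "normalized_matrix"))
  df <- norm$cell_meta |>
    select("barcode", "n_genes_expressed") |>
    inner_join(as_tibble(lisi), by = "barcode") |>
    inner_join(as_tibble(clusters), by = "barcode")
  if (nrow(df) == 0) abort("No overlapping barcodes between inputs.")
  per_cluster <- df |>
    mutate(ratio = .data$n_genes_expressed / .data$lisi) |>
    group_by(.data$cluster) |>
    summarise(n_cells = n(), mean_ratio = mean(.data$ratio), .groups = "drop") |>
    arrange(.data$cluster)
  if (any(per_cluster$n_cells == 0)) abort("Cluster with zero cells.")
  if (nrow(per_cluster) < 4) {
    warn("Fewer than 4 clusters: Tukey fence undefined, no cluster excluded.")
    out <- per_cluster |>
      mutate(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
             lower_fence = -Inf, upper_fence = Inf, excluded = FALSE)
  } else {
    f <- quartile_fences(per_cluster$mean_ratio)
    out <- per_cluster |>
      mutate(q1 = f$q1, q3 = f$q3, iqr = f$iqr,
             lower_fence = f$lower, upper_fence = f$upper,
             excluded = .data$mean_ratio > f$upper | .data$mean_ratio < f$lower)
  }
  structure(out, class = c("cluster_qc", class(tibble())))
}

#' @export
glance.cluster_qc <- function(x, ...) {
  tibble(n_clusters = nrow(x), n_excluded = sum(x$excluded),
         q1 = x$q1[1], q3 = x$q3[1],
         lower_fence = x$lower_fence[1], upper_fence = x$upper_fence[1])
}
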