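#' Write a count matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv`, `barcodes.tsv` and `cell_meta.tsv` (barcode, sample_id,
#' condition, batch, true_type, is_doublet).
#'
#' @param matrix A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- matrix$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(matrix$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(matrix$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read a 10x-style triplet directory into a count matrix
#'
#' Expects `matrix.mtx` + `features.tsv` + `barcodes.tsv`; `cell_meta.tsv`
#' is joined by barcode when present, with missing metadata fields
#' defaulting to `"unknown"`.
#'
#' @param dir Directory path.
#' @return A `count_matrix`.
#' @export
read_matrix <- function(dir) {
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
    if (!file.exists(file.path(dir, f))) abort(paste0("Missing file: ", f))
  }
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "features.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[`, character(1), 1)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    abort(sprintf(
      "Dimension mismatch: matrix is %d x %d but features/barcodes have %d/%d entries.",
      nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  if (anyDuplicated(barcodes)) abort("Duplicate barcodes in barcodes.tsv.")
  dimnames(m) <- list(genes, barcodes)
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- tibble(barcode = barcodes)
  if (file.exists(meta_path)) {
    found <- read_tsv(meta_path, show_col_types = FALSE)
    meta <- left_join(meta, found, by = "barcode")
  }
  for (col in c("sample_id", "condition", "batch", "true_type")) {
    if (!col %in% names(meta)) meta[[col]] <- "unknown"
    meta[[col]] <- tidyr::replace_na(as.character(meta[[col]]), "unknown")
  }
  if (!"is_doublet" %in% names(meta)) meta$is_doublet <- FALSE
  meta$is_doublet <- tidyr::replace_na(as.logical(meta$is_doublet), FALSE)
  new_count_matrix(m, meta)
}

#' Depth-normalize and log2-transform UMI counts
#'
#' Computes `log2(1 + scale * count / n_umi)` per entry, where `n_umi` is
#' the cell's total raw count. Zero counts map to exactly zero, so the
#' sparsity pattern is preserved. Per-cell `n_umi` and `n_genes_expressed`
#' (genes with raw count > 0) are recorded in the metadata.
#'
#' @param matrix A `count_matrix`; every cell must have `n_umi > 0`.
#' @param scale Scale factor (default 10,000).
#' @return A `normalized_matrix`: list with `values` (sparse dgCMatrix) and
#'   `cell_meta` (tibble including `n_umi`, `n_genes_expressed`).
#' @export
normalize_log2 <- function(matrix, scale = 1e4) {
  stopifnot(inherits(matrix, "count_matrix"), scale > 0)
  n_umi <- Matrix::colSums(matrix$counts)
  if (any(n_umi == 0)) {
    abort(paste0("Cells with zero UMI: ",
                 paste(head(colnames(matrix$counts)[n_umi == 0], 5), collapse = ", ")))
  }
  v <- matrix$counts
  # per-entry column depth via the dgCMatrix column pointer
  depth <- rep.int(n_umi, diff(v@p))
  v@x <- log2(1 + scale * v@x / depth)
  meta <- matrix$cell_meta |>
    mutate(n_umi = as.integer(n_umi),
           n_genes_expressed = as.integer(Matrix::colSums(matrix$counts > 0)))
  structure(list(values = v, cell_meta = meta), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells (log2, depth-normalized)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

subset_cells <- function(norm, barcodes) {
  keep <- match(barcodes, colnames(norm$values))
  if (anyNA(keep)) abort("Unknown barcodes in subset.")
  structure(list(values = norm$values[, keep, drop = FALSE],
                 cell_meta = norm$cell_meta[keep, ]),
            class = class(norm))
}

#' Reduce a normalized matrix to principal-component space
#'
#' Selects the `n_hvg` most variable genes by variance-to-mean dispersion
#' of the normalized values, z-scores them gene-wise (clipped at +/- 10),
#' and returns the top `d` principal components. Component signs follow a
#' fixed convention (largest-magnitude gene loading positive) so results
#' are reproducible; selected genes are processed in canonical name order
#' so the embedding is invariant to input gene ordering.
#'
#' @param norm A `normalized_matrix`.
#' @param n_hvg Number of highly variable genes to keep.
#' @param d Number of principal components (must not exceed cell count).
#' @return An `embedding`: list with `coords` (cells x d matrix, barcodes
#'   as rownames) and `d`.
#' @export
reduce_dimensions <- function(norm, n_hvg = 2000, d = 12) {
  stopifnot(inherits(norm, "normalized_matrix"))
  nc <- ncol(norm$values)
  if (d > nc) abort("`d` exceeds the number of cells.")
  g_mean <- Matrix::rowMeans(norm$values)
  g_var <- row_vars_sparse(norm$values, g_mean)
  disp <- ifelse(g_mean > 0, g_var / g_mean, 0)
  ord <- order(-disp, rownames(norm$values))
  hvg <- sort(rownames(norm$values)[ord[seq_len(min(n_hvg, sum(disp > 0)))]])
  x <- Matrix::t(norm$values[hvg, , drop = FALSE])  # cells x genes
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- Inf  # constant genes carry no signal
  x <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  x[x > 10] <- 10; x[x < -10] <- -10
  d <- min(d, ncol(x))
  # eigen-decomposition of the gene-gene covariance (genes << cells here)
  cv <- crossprod(x) / (nrow(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  rot <- eig$vectors[, seq_len(d), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  coords <- x %*% rot
  rownames(coords) <- colnames(norm$values)
  colnames(coords) <- paste0("PC", seq_len(d))
  structure(list(coords = coords, d = d, hvg = hvg, rotation = rot),
            class = "embedding")
}

row_vars_sparse <- function(m, mu = Matrix::rowMeans(m)) {
  n <- ncol(m)
  sq <- Matrix::rowSums(m^2)
  (sq - n * mu^2) / (n - 1)
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells x %d dimensions\n", nrow(x$coords), x$d))
  invisible(x)
}

#' Export an embedding as TSV
#'
#' @param embedding An `embedding`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- as_tibble(embedding$coords) |>
    mutate(barcode = rownames(embedding$coords), .before = 1)
  write_tsv(df, path)
  invisible(path)
}
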