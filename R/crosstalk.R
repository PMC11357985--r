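#' Read a ligand-receptor pair database
#'
#' TSV with columns `pair`, `ligand_genes`, `receptor_genes`; multi-subunit
#' complexes separate genes with `+`. With `path = NULL` the small curated
#' database shipped with the package is loaded (a synthetic, hand-curated
#' stand-in for large public ligand-receptor resources, including the
#' ephrin-Eph and VEGF axes).
#'
#' @param path TSV path, or `NULL` for the shipped database.
#' @return A `lr_database` tibble: `pair`, `ligand_genes`,
#'   `receptor_genes`.
#' @export
read_lr_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lr_pairs.tsv", package = "cardiocomm")
  }
  db <- read_tsv(path, show_col_types = FALSE,
                 col_types = cols(.default = col_character()))
  need <- c("pair", "ligand_genes", "receptor_genes")
  if (!all(need %in% names(db))) {
    abort("LR database needs columns pair, ligand_genes, receptor_genes.")
  }
  if (anyDuplicated(db$pair)) abort("Duplicate pair names in LR database.")
  if (any(db$ligand_genes == "" | db$receptor_genes == "")) {
    abort("Every pair needs at least one ligand and one receptor gene.")
  }
  structure(as_tibble(db[need]), class = c("lr_database", class(tibble())))
}

split_subunits <- function(x) strsplit(x, "+", fixed = TRUE)

# Multi-subunit expression summary: per-gene mean over cells, minimum over
# subunits (limiting-subunit logic). Returns the summary and the smallest
# expressed fraction across subunits.
subunit_summary <- function(values, genes, cells_idx) {
  v <- values[genes, cells_idx, drop = FALSE]
  m <- Matrix::rowMeans(v)
  frac <- Matrix::rowMeans(v > 0)
  list(summary = min(m), min_frac = min(frac))
}

#' Score one ligand-receptor pair between a donor and a receiver group
#'
#' The ligand summary is the mean log2-normalized expression over donor
#' cells (minimum over subunits for complexes); the receptor summary
#' likewise over receiver cells; the score is their arithmetic mean. The
#' pair is marked `filtered` when any subunit gene is expressed in fewer
#' than `min_frac` of its group's cells, or when a gene is absent from the
#' matrix (with a warning).
#'
#' @param norm A `normalized_matrix`.
#' @param donor_cells,receiver_cells Non-empty barcode vectors.
#' @param pair One row of an `lr_database`.
#' @param min_frac Expression-fraction filter threshold.
#' @return Tibble: `pair`, `ligand_summary`, `receptor_summary`, `score`,
#'   `filtered`.
#' @export
pair_score <- function(norm, donor_cells, receiver_cells, pair,
                       min_frac = 0.1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (length(donor_cells) == 0 || length(receiver_cells) == 0) {
    abort("Donor and receiver cell sets must be non-empty.")
  }
  lig <- split_subunits(pair$ligand_genes)[[1]]
  rec <- split_subunits(pair$receptor_genes)[[1]]
  absent <- setdiff(c(lig, rec), rownames(norm$values))
  if (length(absent) > 0) {
    warn(paste0("Pair ", pair$pair, " has genes absent from the matrix: ",
                paste(absent, collapse = ", "), "; pair filtered."))
    return(tibble(pair = pair$pair, ligand_summary = NA_real_,
                  receptor_summary = NA_real_, score = NA_real_,
                  filtered = TRUE))
  }
  di <- match(donor_cells, colnames(norm$values))
  ri <- match(receiver_cells, colnames(norm$values))
  ls <- subunit_summary(norm$values, lig, di)
  rs <- subunit_summary(norm$values, rec, ri)
  tibble(pair = pair$pair,
         ligand_summary = ls$summary, receptor_summary = rs$summary,
         score = (ls$summary + rs$summary) / 2,
         filtered = ls$min_frac < min_frac || rs$min_frac < min_frac)
}

#' Permutation test for one ligand-receptor pair
#'
#' The null distribution is generated by shuffling cell-type labels across
#' all cells (type sizes preserved) and recomputing the pair score for the
#' donor/receiver types; the p-value uses add-one smoothing,
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, so it is never zero.
#' Deterministic for a fixed seed.
#'
#' @param norm A `normalized_matrix`.
#' @param type_labels Per-cell cell-type label (aligned to columns).
#' @param pair One row of an `lr_database`; genes must be present.
#' @param donor,receiver Cell-type names.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed.
#' @return Tibble: `pair`, `donor`, `receiver`, `score`, `p`.
#' @export
permutation_test <- function(norm, type_labels, pair, donor, receiver,
                             n_perm = 1000, seed = 1) {
  stopifnot(inherits(norm, "normalized_matrix"), n_perm >= 100)
  n <- ncol(norm$values)
  stopifnot(length(type_labels) == n)
  if (length(unique(type_labels)) < 2) {
    abort("Degenerate labelling: need at least 2 cell types.")
  }
  lig <- split_subunits(pair$ligand_genes)[[1]]
  rec <- split_subunits(pair$receptor_genes)[[1]]
  absent <- setdiff(c(lig, rec), rownames(norm$values))
  if (length(absent) > 0) abort(paste0("Genes absent: ", paste(absent, collapse = ", ")))
  vl <- as.matrix(norm$values[lig, , drop = FALSE])
  vr <- as.matrix(norm$values[rec, , drop = FALSE])
  d_idx <- which(type_labels == donor)
  r_idx <- which(type_labels == receiver)
  if (length(d_idx) == 0 || length(r_idx) == 0) abort("Empty donor or receiver type.")
  obs <- (min(rowMeans(vl[, d_idx, drop = FALSE])) +
          min(rowMeans(vr[, r_idx, drop = FALSE]))) / 2
  nd <- length(d_idx); nr <- length(r_idx)
  null_scores <- with_seed(seed, {
    di <- matrix(0L, nd, n_perm)
    ri <- matrix(0L, nr, n_perm)
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      lb <- type_labels[p]
      di[, b] <- which(lb == donor)
      ri[, b] <- which(lb == receiver)
    }
    Dm <- sparseMatrix(i = as.vector(di), j = rep(seq_len(n_perm), each = nd),
                       x = 1, dims = c(n, n_perm))
    Rm <- sparseMatrix(i = as.vector(ri), j = rep(seq_len(n_perm), each = nr),
                       x = 1, dims = c(n, n_perm))
    ml <- as.matrix(vl %*% Dm) / nd  # |lig| x n_perm
    mr <- as.matrix(vr %*% Rm) / nr
    lig_sum <- if (nrow(ml) == 1) ml[1, ] else do.call(pmin, asplit(ml, 1))
    rec_sum <- if (nrow(mr) == 1) mr[1, ] else do.call(pmin, asplit(mr, 1))
    (lig_sum + rec_sum) / 2
  })
  p_val <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  tibble(pair = pair$pair, donor = donor, receiver = receiver,
         score = obs, p = p_val)
}

#' Score all ligand-receptor pairs between all cell-type pairs
#'
#' Evaluates every database pair for every ordered donor/receiver type
#' combination within one condition, using a single shared set of label
#' permutations for the null (type sizes preserved). A pair is significant
#' when its permutation p-value is below `alpha` and every subunit passes
#' the expression-fraction filter in its group. Pairs with genes absent
#' from the matrix are reported as filtered with `NA` score.
#'
#' @param norm A `normalized_matrix` for one condition.
#' @param type_labels Per-cell cell-type label.
#' @param lr_db An `lr_database`.
#' @param condition Condition name recorded in the result.
#' @param n_perm,alpha,min_frac,seed Test parameters.
#' @return An `interaction_result` tibble: `condition`, `donor`,
#'   `receiver`, `pair`, `score`, `p`, `filtered`, `significant`;
#'   attribute `types`.
#' @export
score_interactions <- function(norm, type_labels, lr_db, condition = "all",
                               n_perm = 1000, alpha = 0.05, min_frac = 0.1,
                               seed = 1) {
  stopifnot(inherits(norm, "normalized_matrix"), n_perm >= 100)
  n <- ncol(norm$values)
  stopifnot(length(type_labels) == n)
  types <- sort(unique(type_labels))
  if (length(types) < 2) abort("Need at least 2 cell types.")
  db <- as_tibble(lr_db)
  all_genes <- unique(unlist(split_subunits(c(db$ligand_genes, db$receptor_genes))))
  present <- intersect(all_genes, rownames(norm$values))
  has_all <- vapply(seq_len(nrow(db)), function(i) {
    all(c(split_subunits(db$ligand_genes[i])[[1]],
          split_subunits(db$receptor_genes[i])[[1]]) %in% present)
  }, logical(1))
  if (any(!has_all)) {
    warn(paste0("Pairs with absent genes filtered: ",
                paste(db$pair[!has_all], collapse = ", ")))
  }
  v <- as.matrix(norm$values[present, , drop = FALSE])
  t_idx <- lapply(types, function(ty) which(type_labels == ty))
  names(t_idx) <- types
  sizes <- lengths(t_idx)
  obs_mean <- vapply(t_idx, function(ii) rowMeans(v[, ii, drop = FALSE]),
                     numeric(length(present)))
  obs_frac <- vapply(t_idx, function(ii) rowMeans(v[, ii, drop = FALSE] > 0),
                     numeric(length(present)))
  obs_mean <- matrix(obs_mean, nrow = length(present),
                     dimnames = list(present, types))
  obs_frac <- matrix(obs_frac, nrow = length(present),
                     dimnames = list(present, types))

  null_means <- with_seed(seed, {
    out <- array(NA_real_, c(length(present), length(types), n_perm),
                 dimnames = list(present, types, NULL))
    for (b in seq_len(n_perm)) {
      lb <- type_labels[sample.int(n)]
      S <- sparseMatrix(i = seq_len(n), j = match(lb, types), x = 1,
                        dims = c(n, length(types)))
      out[, , b] <- sweep(as.matrix(v %*% S), 2, sizes, "/")
    }
    out
  })

  grid <- tidyr::expand_grid(donor = types, receiver = types,
                             pair_row = seq_len(nrow(db)))
  res <- pmap(grid, function(donor, receiver, pair_row) {
    pr <- db[pair_row, ]
    if (!has_all[pair_row]) {
      return(tibble(condition = condition, donor = donor, receiver = receiver,
                    pair = pr$pair, score = NA_real_, p = NA_real_,
                    filtered = TRUE, significant = FALSE))
    }
    lig <- split_subunits(pr$ligand_genes)[[1]]
    rec <- split_subunits(pr$receptor_genes)[[1]]
    obs <- (min(obs_mean[lig, donor]) + min(obs_mean[rec, receiver])) / 2
    nl <- null_means[lig, donor, , drop = FALSE]
    nr <- null_means[rec, receiver, , drop = FALSE]
    lig_null <- apply(nl, 3, min)
    rec_null <- apply(nr, 3, min)
    null_s <- (lig_null + rec_null) / 2
    p_val <- (1 + sum(null_s >= obs)) / (1 + n_perm)
    filt <- min(obs_frac[lig, donor]) < min_frac ||
      min(obs_frac[rec, receiver]) < min_frac
    tibble(condition = condition, donor = donor, receiver = receiver,
           pair = pr$pair, score = obs, p = p_val, filtered = filt,
           significant = !filt && p_val < alpha)
  }) |> list_rbind()
  structure(res, class = c("interaction_result", class(tibble())),
            types = types, alpha = alpha, min_frac = min_frac,
            n_perm = n_perm)
}

#' Count significant interactions per directed cell-type pair
#'
#' Builds the directed count matrix `count[donor, receiver]` of
#' significant pairs for one condition, with per-type incoming sums
#' (excluding self-signalling, i.e. ligands from any *other* cell type),
#' per-type outgoing sums, and the grand total.
#'
#' @param results An `interaction_result` tibble from a single condition.
#' @return An `interaction_counts` object: list with `condition`, `counts`
#'   (types x types matrix), `incoming`, `outgoing`, `total`.
#' @export
count_interactions <- function(results) {
  types <- attr(results, "types") %||%
    sort(unique(c(results$donor, results$receiver)))
  results <- as_tibble(results)
  cond <- unique(results$condition)
  if (length(cond) > 1) abort("Results mix conditions; count one condition at a time.")
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(donor = types, receiver = types))
  sig <- results |> filter(.data$significant)
  if (nrow(sig) > 0) {
    tab <- sig |> count(.data$donor, .data$receiver)
    counts[cbind(match(tab$donor, types), match(tab$receiver, types))] <-
      as.integer(tab$n)
  }
  incoming <- colSums(counts) - diag(counts)
  outgoing <- rowSums(counts)
  structure(list(condition = if (length(cond)) cond else "none",
                 counts = counts,
                 incoming = incoming, outgoing = outgoing,
                 total = sum(counts)),
            class = "interaction_counts")
}

#' @export
print.interaction_counts <- function(x, ...) {
  cat(sprintf("<interaction_counts> condition %s: %d significant interactions\n",
              x$condition, x$total))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.interaction_counts <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n",
                                stringsAsFactors = FALSE)) |>
    mutate(condition = x$condition, .before = 1)
}

#' Compare interaction counts between conditions
#'
#' Differences (disease minus healthy) per directed cell-type pair and per
#' type (incoming, excluding self; outgoing), plus the total delta.
#'
#' @param healthy,disease `interaction_counts` objects over the same
#'   cell-type universe.
#' @return An `interaction_delta` object: list with `pairs` (tibble:
#'   donor, receiver, healthy, disease, delta), `types` (tibble: type,
#'   incoming/outgoing per condition and deltas), `total_delta`.
#' @export
compare_conditions <- function(healthy, disease) {
  stopifnot(inherits(healthy, "interaction_counts"),
            inherits(disease, "interaction_counts"))
  th <- rownames(healthy$counts); td <- rownames(disease$counts)
  if (!identical(th, td)) abort("Cell-type universes differ between conditions.")
  pairs <- as_tibble(as.data.frame.table(healthy$counts, responseName = "healthy",
                                         stringsAsFactors = FALSE)) |>
    mutate(disease = as.vector(disease$counts),
           delta = .data$disease - .data$healthy)
  types <- tibble(
    type = th,
    incoming_healthy = unname(healthy$incoming),
    incoming_disease = unname(disease$incoming),
    delta_incoming = unname(disease$incoming - healthy$incoming),
    outgoing_healthy = unname(healthy$outgoing),
    outgoing_disease = unname(disease$outgoing),
    delta_outgoing = unname(disease$outgoing - healthy$outgoing)
  )
  structure(list(pairs = pairs, types = types,
                 total_healthy = healthy$total, total_disease = disease$total,
                 total_delta = disease$total - healthy$total),
            class = "interaction_delta")
}

#' @export
print.interaction_delta <- function(x, ...) {
  cat(sprintf("<interaction_delta> total: %d (healthy) -> %d (disease), delta %+d\n",
              x$total_healthy, x$total_disease, x$total_delta))
  print(x$types)
  invisible(x)
}

#' @export
tidy.interaction_delta <- function(x, ...) x$pairs

#' @export
glance.interaction_delta <- function(x, ...) {
  tibble(total_healthy = x$total_healthy, total_disease = x$total_disease,
         total_delta = x$total_delta)
}

#' Sensitivity analysis: remove healthy-unique genes and recompare
#'
#' Identifies genes expressed (nonzero) only in healthy cells, removes
#' them from both condition matrices, re-runs the full interaction
#' scoring, counting and condition comparison, and returns the original
#' and reduced comparisons side by side. An empty unique-gene set
#' reproduces the original comparison exactly.
#'
#' @param norm_healthy,norm_disease `normalized_matrix` objects sharing a
#'   gene universe.
#' @param types_healthy,types_disease Per-cell cell-type labels.
#' @param lr_db An `lr_database`.
#' @param n_perm,alpha,min_frac,seed Passed to [score_interactions()].
#' @return List: `removed_genes`, `original` and `reduced`
#'   (`interaction_delta` objects).
#' @export
sensitivity_remove_unique <- function(norm_healthy, norm_disease,
                                      types_healthy, types_disease, lr_db,
                                      n_perm = 1000, alpha = 0.05,
                                      min_frac = 0.1, seed = 1) {
  if (!identical(rownames(norm_healthy$values), rownames(norm_disease$values))) {
    abort("The two matrices must share a gene universe.")
  }
  run_cmp <- function(nh, nd) {
    rh <- score_interactions(nh, types_healthy, lr_db, condition = "healthy",
                             n_perm = n_perm, alpha = alpha,
                             min_frac = min_frac, seed = seed)
    rd <- score_interactions(nd, types_disease, lr_db, condition = "disease",
                             n_perm = n_perm, alpha = alpha,
                             min_frac = min_frac, seed = seed)
    compare_conditions(count_interactions(rh), count_interactions(rd))
  }
  expressed_h <- Matrix::rowSums(norm_healthy$values > 0) > 0
  expressed_d <- Matrix::rowSums(norm_disease$values > 0) > 0
  unique_h <- rownames(norm_healthy$values)[expressed_h & !expressed_d]
  original <- run_cmp(norm_healthy, norm_disease)
  if (length(unique_h) == 0) {
    reduced <- original
  } else {
    keep <- setdiff(rownames(norm_healthy$values), unique_h)
    strip <- function(x) {
      structure(list(values = x$values[keep, , drop = FALSE],
                     cell_meta = x$cell_meta), class = class(x))
    }
    reduced <- suppressWarnings(run_cmp(strip(norm_healthy), strip(norm_disease)))
  }
  list(removed_genes = unique_h, original = original, reduced = reduced)
}
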