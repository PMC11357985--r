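# Shared in-code fixtures: everything is generated at test time.

# Small atlas config for fast module tests.
tiny_config <- function(...) {
  defaults <- list(
    n_cells_per_type_per_sample = 10,
    n_samples_healthy = 3,
    n_samples_disease = 2,
    n_genes = 600,
    n_program_genes_per_type = 20,
    n_junk_cells = 0,
    doublet_rate = 0,
    seed = 1
  )
  args <- utils::modifyList(defaults, list(...))
  # keep the default planted effects consistent with a trimmed type set
  if (!is.null(args$cell_types)) {
    types <- names(args$cell_types)
    if (is.null(args$effect_table)) {
      et <- default_effect_table()
      args$effect_table <- et[et$cell_type %in% types, ]
    }
    if (is.null(args$lr_truth)) {
      lt <- default_lr_truth()
      args$lr_truth <- lt[lt$donor %in% types & lt$receiver %in% types, ]
    }
  }
  do.call(atlas_config, args)
}

# Build a normalized_matrix directly from a dense value matrix, for tests
# that need exact expression values.
fake_norm <- function(values, meta = NULL) {
  values <- as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(meta)) meta <- tibble::tibble(barcode = colnames(values))
  meta$n_genes_expressed <- as.integer(Matrix::colSums(values > 0))
  structure(list(values = values, cell_meta = meta),
            class = "normalized_matrix")
}

# Build an embedding object directly from a coordinate matrix.
fake_embedding <- function(coords) {
  if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  }
  structure(list(coords = coords, d = ncol(coords)), class = "embedding")
}

# Build a count_matrix from a dense nonnegative integer matrix.
fake_counts <- function(m, meta = NULL) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(meta)) {
    meta <- tibble::tibble(barcode = colnames(m), sample_id = "s1",
                           condition = "healthy", batch = "b1",
                           true_type = "A", is_doublet = FALSE)
  }
  structure(list(counts = as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                 cell_meta = meta),
            class = "count_matrix")
}

# Independent inverse-Simpson oracle: explicit Gaussian weights with
# entropy-matched bandwidth over the k nearest neighbours, written as
# straight-line arithmetic (no package internals).
lisi_oracle <- function(coords, labels, perplexity) {
  n <- nrow(coords)
  k <- min(n - 1, ceiling(3 * perplexity))
  levs <- sort(unique(labels))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    ord <- order(d2, seq_len(n))
    ord <- setdiff(ord, i)[seq_len(k)]
    dd <- d2[ord] - min(d2[ord])
    if (all(dd == 0)) {
      w <- rep(1 / k, k)
    } else {
      lo <- -Inf; hi <- Inf; beta <- 1
      for (iter in 1:100) {
        w <- exp(-beta * dd)
        h <- log(sum(w)) + beta * sum(dd * w) / sum(w)
        if (abs(h - log(perplexity)) < 1e-10) break
        if (h > log(perplexity)) {
          lo <- beta
          beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
        } else {
          hi <- beta
          beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
        }
      }
      w <- w / sum(w)
    }
    p <- vapply(levs, function(l) sum(w[labels[ord] == l]), numeric(1))
    out[i] <- 1 / sum(p^2)
  }
  out
}

# Direct bimodal log-likelihood oracle on raw vectors, written from the
# model definition (zero w.p. 1 - pi, Normal(mu, sigma) otherwise).
bimod_oracle <- function(xa, xb) {
  pos <- c(xa[xa > 0], xb[xb > 0])
  sigma <- max(stats::sd(pos), 1e-6)
  ll <- function(x) {
    n <- length(x); np <- sum(x > 0)
    pi_hat <- np / n
    out <- 0
    if (n - np > 0) out <- out + (n - np) * log(1 - pi_hat)
    if (np > 0) {
      xp <- x[x > 0]
      out <- out + np * log(pi_hat) +
        sum(stats::dnorm(xp, mean(xp), sigma, log = TRUE))
    }
    out
  }
  stat <- 2 * (ll(xa) + ll(xb) - ll(c(xa, xb)))
  list(stat = max(0, stat),
       p = stats::pchisq(max(0, stat), df = 2, lower.tail = FALSE))
}
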