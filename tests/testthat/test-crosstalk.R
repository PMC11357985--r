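lr_row <- function(pair, lig, rec) {
  tibble::tibble(pair = pair, ligand_genes = lig, receptor_genes = rec)
}

test_that("pair scores average ligand and receptor summaries", {
  v <- matrix(0, 4, 20, dimnames = list(c("L1", "L2", "R1", "R2"),
                                        sprintf("c%03d", 1:20)))
  v["L1", 1:10] <- 2; v["L2", 1:10] <- 6
  v["R1", 11:20] <- 4
  v["R2", 11:20] <- c(rep(1, 9), 0)  # expressed in 90% of receivers
  norm <- fake_norm(v)
  donor <- sprintf("c%03d", 1:10); recv <- sprintf("c%03d", 11:20)
  s <- pair_score(norm, donor, recv, lr_row("P", "L1", "R1"))
  expect_equal(s$score, 3)
  expect_false(s$filtered)
  # multi-subunit: limiting subunit (minimum over subunit means)
  s2 <- pair_score(norm, donor, recv, lr_row("P", "L1+L2", "R1"))
  expect_equal(s2$ligand_summary, 2)
  s3 <- pair_score(norm, donor, recv, lr_row("P", "L2", "R1+R2"))
  expect_equal(s3$receptor_summary, min(4, 0.9))
  # expression-fraction filter
  v2 <- v; v2["L1", 1:10] <- 0; v2["L1", 1] <- 2  # 10% < threshold at f=0.2
  s4 <- pair_score(fake_norm(v2), donor, recv, lr_row("P", "L1", "R1"),
                   min_frac = 0.2)
  expect_true(s4$filtered)
  expect_warning(
    s5 <- pair_score(norm, donor, recv, lr_row("P", "ABSENT", "R1")),
    "absent")
  expect_true(s5$filtered)
  expect_true(is.na(s5$score))
  expect_error(pair_score(norm, character(0), recv, lr_row("P", "L1", "R1")),
               "non-empty")
})

test_that("permutation p-values use add-one smoothing and fixed seeds", {
  set.seed(5)
  n <- 60
  v <- matrix(0, 2, n, dimnames = list(c("L", "R"), sprintf("c%03d", 1:n)))
  types <- rep(c("A", "B"), each = n / 2)
  v["L", types == "A"] <- 8 + runif(n / 2)   # ligand exclusive to donor type
  v["R", types == "B"] <- 8 + runif(n / 2)
  norm <- fake_norm(v)
  pr <- lr_row("LR", "L", "R")
  res <- permutation_test(norm, types, pr, "A", "B", n_perm = 999, seed = 1)
  expect_equal(res$p, 1 / 1000)  # observed beats every null draw
  res2 <- permutation_test(norm, types, pr, "A", "B", n_perm = 999, seed = 1)
  expect_identical(res$p, res2$p)
  expect_gte(res$p, 1 / 1000)
  expect_error(permutation_test(norm, rep("A", n), pr, "A", "A", 500),
               "Degenerate")
})

test_that("permutation p matches exhaustive enumeration on 6 cells", {
  v <- matrix(0, 2, 6, dimnames = list(c("L", "R"), sprintf("c%03d", 1:6)))
  v["L", ] <- c(5, 4, 3, 0.5, 0.2, 0.1)
  v["R", ] <- c(0.3, 0.1, 0.2, 4, 6, 5)
  types <- c("A", "A", "A", "B", "B", "B")
  norm <- fake_norm(v)
  obs <- (mean(v["L", 1:3]) + mean(v["R", 4:6])) / 2
  combos <- combn(6, 3)
  null_scores <- apply(combos, 2, function(a) {
    (mean(v["L", a]) + mean(v["R", setdiff(1:6, a)])) / 2
  })
  b <- sum(null_scores >= obs)  # includes the observed assignment itself
  p_hat <- permutation_test(norm, types, lr_row("LR", "L", "R"), "A", "B",
                            n_perm = 20000, seed = 3)$p
  expect_lt(abs(p_hat - b / ncol(combos)), 0.02)
})

test_that("permutation p is calibrated under exchangeable labels", {
  set.seed(9)
  n <- 80
  types <- rep(c("A", "B"), each = n / 2)
  ps <- vapply(1:200, function(i) {
    v <- matrix(rexp(2 * n), 2, n,
                dimnames = list(c("L", "R"), sprintf("c%03d", 1:n)))
    permutation_test(fake_norm(v), types, lr_row("LR", "L", "R"),
                     "A", "B", n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_true(all(ps >= 1 / 201 & ps <= 1))
})

test_that("interaction counting and totals follow the partition identity", {
  mk <- function(donor, receiver, sig) {
    structure(tibble::tibble(condition = "healthy", donor = donor,
                             receiver = receiver,
                             pair = paste0("p", seq_along(donor)),
                             score = 1, p = 0.01, filtered = FALSE,
                             significant = sig),
              types = c("CM", "EC", "FB"),
              class = c("interaction_result", class(tibble::tibble())))
  }
  empty <- mk(character(0), character(0), logical(0))
  c0 <- count_interactions(empty)
  expect_equal(sum(c0$counts), 0)
  expect_equal(c0$total, 0)

  res <- mk(c("EC", "EC", "EC", "FB", "CM"),
            c("CM", "CM", "CM", "CM", "CM"),
            rep(TRUE, 5))
  cc <- count_interactions(res)
  expect_equal(unname(cc$incoming["CM"]), 4)
  expect_equal(cc$total, 5)
  expect_equal(cc$counts["EC", "CM"], 3)
  expect_equal(sum(cc$incoming) + sum(diag(cc$counts)), cc$total)

  mixed <- res
  mixed$condition <- c("healthy", "healthy", "disease", "healthy", "healthy")
  expect_error(count_interactions(mixed), "mix conditions")
})

test_that("condition comparison is antisymmetric and zero on identity", {
  mk_counts <- function(m, cond) {
    types <- c("CM", "EC")
    counts <- matrix(m, 2, 2, dimnames = list(donor = types, receiver = types))
    structure(list(condition = cond, counts = counts,
                   incoming = colSums(counts) - diag(counts),
                   outgoing = rowSums(counts), total = sum(counts)),
              class = "interaction_counts")
  }
  h <- mk_counts(c(1L, 3L, 2L, 0L), "healthy")
  d <- mk_counts(c(1L, 1L, 0L, 2L), "disease")
  same <- compare_conditions(h, h)
  expect_true(all(same$pairs$delta == 0))
  expect_equal(same$total_delta, 0)
  ab <- compare_conditions(h, d)
  ba <- compare_conditions(d, h)
  expect_equal(ab$pairs$delta, -ba$pairs$delta)
  expect_equal(ab$types$delta_incoming, -ba$types$delta_incoming)
  expect_equal(ab$total_delta, -ba$total_delta)
  h3 <- mk_counts(c(1L, 3L, 2L, 0L), "healthy")
  rownames(h3$counts) <- colnames(h3$counts) <- c("CM", "FB")
  expect_error(compare_conditions(h3, d), "universes differ")
})

test_that("shared-permutation scoring recovers the planted EC->CM loss", {
  cfg <- tiny_config(n_cells_per_type_per_sample = 12,
                     n_samples_healthy = 6, n_samples_disease = 5,
                     cell_types = list(CM = c("TNNT2", "TTN"),
                                       EC = c("CDH5", "PECAM1"),
                                       FB = c("PDGFRA", "LAMB1")),
                     n_genes = 400, seed = 43)
  cm <- generate_atlas(cfg)
  norm <- normalize_log2(cm)
  db <- read_lr_db()
  run_one <- function(cond) {
    keep <- norm$cell_meta$condition == cond
    sub <- structure(list(values = norm$values[, keep],
                          cell_meta = norm$cell_meta[keep, ]),
                     class = "normalized_matrix")
    suppressWarnings(score_interactions(
      sub, sub$cell_meta$true_type, db, condition = cond,
      n_perm = 300, seed = 7))
  }
  rh <- run_one("healthy")
  rd <- run_one("disease")
  expect_true(all(rh$p[!is.na(rh$p)] > 0))
  # the planted healthy-only axis is significant in healthy, not disease
  ephb1_h <- rh |> dplyr::filter(donor == "EC", receiver == "CM",
                                 pair == "EFNB2_EPHB1")
  ephb1_d <- rd |> dplyr::filter(donor == "EC", receiver == "CM",
                                 pair == "EFNB2_EPHB1")
  expect_true(ephb1_h$significant)
  expect_false(ephb1_d$significant)
  # the always-on control stays significant in both conditions
  ctrl_h <- rh |> dplyr::filter(donor == "EC", receiver == "CM",
                                pair == "DLL4_NOTCH1")
  ctrl_d <- rd |> dplyr::filter(donor == "EC", receiver == "CM",
                                pair == "DLL4_NOTCH1")
  expect_true(ctrl_h$significant && ctrl_d$significant)
  delta <- compare_conditions(count_interactions(rh), count_interactions(rd))
  expect_lt(delta$types$delta_incoming[delta$types$type == "CM"], 0)
})

test_that("healthy-unique gene removal reproduces or preserves results", {
  cfg <- tiny_config(n_cells_per_type_per_sample = 10,
                     n_samples_healthy = 5, n_samples_disease = 5,
                     cell_types = list(CM = c("TNNT2", "TTN"),
                                       EC = c("CDH5", "PECAM1"),
                                       FB = c("PDGFRA", "LAMB1")),
                     n_genes = 300, n_healthy_unique = 20, seed = 47)
  cm <- generate_atlas(cfg)
  norm <- normalize_log2(cm)
  split_cond <- function(cond) {
    keep <- norm$cell_meta$condition == cond
    structure(list(values = norm$values[, keep],
                   cell_meta = norm$cell_meta[keep, ]),
              class = "normalized_matrix")
  }
  nh <- split_cond("healthy"); nd <- split_cond("disease")
  db <- read_lr_db()
  out <- suppressWarnings(sensitivity_remove_unique(
    nh, nd, nh$cell_meta$true_type, nd$cell_meta$true_type, db,
    n_perm = 200, seed = 3))
  expect_length(out$removed_genes, 20)
  expect_false(any(out$removed_genes %in%
                     unlist(strsplit(c(db$ligand_genes, db$receptor_genes),
                                     "+", fixed = TRUE))))
  # noise genes are in no pair, so the comparison is unchanged
  expect_equal(out$reduced$pairs, out$original$pairs)
  expect_equal(out$reduced$total_delta, out$original$total_delta)

  # a healthy-only ligand drops its pair from both conditions
  vals <- as.matrix(norm$values)
  vals["DLL4", norm$cell_meta$condition == "disease"] <- 0
  norm2 <- fake_norm(vals, meta = norm$cell_meta)
  nh2 <- structure(list(values = norm2$values[, norm$cell_meta$condition == "healthy"],
                        cell_meta = nh$cell_meta), class = "normalized_matrix")
  nd2 <- structure(list(values = norm2$values[, norm$cell_meta$condition == "disease"],
                        cell_meta = nd$cell_meta), class = "normalized_matrix")
  out2 <- suppressWarnings(sensitivity_remove_unique(
    nh2, nd2, nh$cell_meta$true_type, nd$cell_meta$true_type, db,
    n_perm = 200, seed = 3))
  expect_true("DLL4" %in% out2$removed_genes)
  # with its ligand removed the pair can no longer count in either condition
  ec_cm <- function(cmp, col) {
    cmp$pairs[[col]][cmp$pairs$donor == "EC" & cmp$pairs$receiver == "CM"]
  }
  expect_lte(ec_cm(out2$reduced, "healthy"), ec_cm(out2$original, "healthy"))
  expect_lte(ec_cm(out2$reduced, "disease"), ec_cm(out2$original, "disease"))
})

test_that("the shipped LR database is well-formed", {
  db <- read_lr_db()
  expect_gte(nrow(db), 50)
  expect_false(anyDuplicated(db$pair) > 0)
  expect_true(all(c("EFNB2_EPHB1", "EFNB2_EPHA4", "EFNA5_EPHA4",
                    "VEGFA_FLT1_NRP1", "VEGFB_FLT1") %in% db$pair))
  subunits <- strsplit(db$receptor_genes, "+", fixed = TRUE)
  expect_true(any(lengths(subunits) > 1))
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(pair = c("a", "a"), ligand_genes = "L",
                                  receptor_genes = "R"), bad)
  expect_error(read_lr_db(bad), "Duplicate")
})
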