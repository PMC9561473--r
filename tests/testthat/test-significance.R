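make_scored_fixture <- function(seed = 77, n_cells = 120, n_feat = 50,
                                n_refs = 4) {
  emb <- random_embedding(n_cells, 3, seed = seed)
  X <- withr::with_seed(seed + 1, {
    matrix(rpois(n_cells * n_feat, 2), nrow = n_cells,
           dimnames = list(NULL, paste0("g", seq_len(n_feat))))
  })
  S <- pairwise_similarity(emb, seq_len(n_refs) * 10, gamma = 0.5)
  list(X = X, S = S, E = score_all(X, S))
}

test_that("permutation preserves each feature's value multiset", {
  fx <- make_scored_fixture()
  P <- withr::with_seed(5, freemarkers:::permute_columns(fx$X))
  expect_identical(dim(P), dim(fx$X))
  for (j in c(1, 25, 50)) {
    expect_identical(sort(P[, j]), sort(fx$X[, j]))
    expect_false(identical(P[, j], fx$X[, j]))
  }
  Xs <- Matrix::Matrix(fx$X, sparse = TRUE)
  Ps <- withr::with_seed(5, freemarkers:::permute_columns(Xs))
  expect_s4_class(Ps, "CsparseMatrix")
  for (j in c(1, 25, 50)) {
    expect_identical(sort(as.vector(Ps[, j])), as.numeric(sort(fx$X[, j])))
  }
})

test_that("the null model is seeded, recomputable and flags constants", {
  fx <- make_scored_fixture()
  fx$X[, 3] <- 7 # constant feature: permuting it cannot move its score
  n1 <- build_null(fx$X, fx$S, n_rounds = 2, seed = 9)
  n2 <- build_null(fx$X, fx$S, n_rounds = 2, seed = 9)
  expect_identical(n1$null_scores, n2$null_scores)
  expect_identical(nrow(n1$null_scores), 2L * ncol(fx$X))
  expect_equal(n1$mean, colMeans(n1$null_scores), tolerance = 1e-12)
  expect_equal(n1$sd, apply(n1$null_scores, 2, sd), tolerance = 1e-12)
  const_rows <- c(3, 3 + ncol(fx$X))
  expect_true(all(n1$null_scores[const_rows, ] == 0))
  expect_warning(build_null(fx$X[, 1:10], fx$S, n_rounds = 1, seed = 1),
                 "unstable")
})

test_that("significance calls calibrate scores against the null", {
  fx <- make_scored_fixture()
  null <- build_null(fx$X, fx$S, seed = 13)
  sig <- significance_calls(fx$E, null, sd_cutoff = 5)
  expect_s3_class(sig, "significance_table")
  expect_identical(nrow(sig), nrow(fx$E) * ncol(fx$E))
  # a score at the null mean is maximally unremarkable
  E0 <- fx$E
  E0[1, ] <- null$mean
  sig0 <- significance_calls(E0, null, sd_cutoff = 5)
  r1 <- sig0[sig0$feature_id == "g1", ]
  expect_equal(r1$n_sd, rep(0, ncol(fx$E)))
  expect_equal(r1$p, rep(1, ncol(fx$E)))
  expect_false(any(r1$significant))
  # n_sd arithmetic
  nulltoy <- null
  nulltoy$mean[] <- 0
  nulltoy$sd[] <- 0.1
  Etoy <- matrix(0.5, nrow = 2, ncol = ncol(fx$E),
                 dimnames = list(c("a", "b"), colnames(fx$E)))
  sigtoy <- significance_calls(Etoy, nulltoy, sd_cutoff = 5)
  expect_equal(sigtoy$n_sd, rep(5, nrow(sigtoy)))
  expect_true(all(sigtoy$significant))
})

test_that("corrections satisfy their defining inequalities and the BH oracle", {
  fx <- make_scored_fixture()
  null <- build_null(fx$X, fx$S, seed = 13)
  sig <- significance_calls(fx$E, null)
  expect_true(all(sig$p_bonferroni >= sig$p - 1e-15))
  expect_true(all(sig$q_bh >= sig$p - 1e-15))
  expect_true(all(sig$p >= 0 & sig$p <= 1))
  expect_true(all(sig$q_bh <= 1 & sig$p_bonferroni <= 1))
  for (ref in unique(sig$reference_cell_id)) {
    rows <- sig[sig$reference_cell_id == ref, ]
    expect_equal(rows$q_bh, oracle_bh(rows$p), tolerance = 1e-12)
    # |n_sd| down implies p up within a reference cell
    o <- order(abs(rows$n_sd), decreasing = TRUE)
    expect_true(all(diff(rows$p[o]) >= -1e-15))
  }
  # Bonferroni never beats BH at equal alpha
  expect_lte(sum(sig$p_bonferroni <= 0.05), sum(sig$q_bh <= 0.05))
  # BH on a hand-made table of 10 p-values
  p10 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  expect_equal(stats::p.adjust(p10, "BH"), oracle_bh(p10), tolerance = 1e-12)
})

test_that("empirical and one-sided p-value variants behave", {
  fx <- make_scored_fixture()
  null <- build_null(fx$X, fx$S, seed = 13)
  sig_emp <- significance_calls(fx$E, null, p_method = "empirical")
  expect_true(all(sig_emp$p >= 1 / (1 + nrow(null$null_scores))))
  expect_true(all(sig_emp$p <= 1))
  sig_one <- significance_calls(fx$E, null, sided = "one", sd_cutoff = 2)
  neg <- sig_one$n_sd < 0
  expect_false(any(sig_one$significant[neg]))
  expect_true(all(sig_one$p[neg] > 0.5))
})

test_that("a degenerate all-zero null yields n_sd 0, never infinities", {
  E <- matrix(c(1, -2, 0.5, 3), nrow = 2,
              dimnames = list(c("a", "b"), c("r1", "r2")))
  null <- structure(
    list(null_scores = matrix(0, 40, 2, dimnames = list(NULL, c("r1", "r2"))),
         mean = c(r1 = 0, r2 = 0), sd = c(r1 = 0, r2 = 0),
         reference_cell_ids = c("r1", "r2"), n_rounds = 1, seed = 1),
    class = "null_model"
  )
  sig <- significance_calls(E, null)
  expect_true(all(sig$n_sd == 0))
  expect_true(all(is.finite(sig$p)))
})

test_that("the KS ranking matches the exhaustive ECDF oracle", {
  # direct supremum example
  obs <- c(1, 2, 3, 4, 5)
  pooled <- c(0.5, 1.5, 2.5)
  res <- suppressWarnings(stats::ks.test(obs, pooled))
  expect_equal(unname(res$statistic), oracle_ks(obs, pooled))
  # and on random pairs
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- rnorm(sample(5:40, 1))
      b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
      expect_equal(unname(suppressWarnings(stats::ks.test(a, b))$statistic),
                   oracle_ks(a, b), tolerance = 1e-12)
    }
  })
})

test_that("global ranking orders features by departure from the null", {
  fx <- make_scored_fixture()
  null <- build_null(fx$X, fx$S, seed = 19)
  E <- fx$E
  # plant a feature whose scores all exceed the null maximum
  E["g5", ] <- max(null$null_scores) + 1:ncol(E)
  gr <- ks_global_ranking(E, null)
  expect_identical(sort(gr$rank), seq_len(nrow(E)))
  g5 <- gr[gr$feature_id == "g5", ]
  expect_equal(g5$ks_statistic, 1)
  expect_identical(g5$rank, 1L)
  # a feature drawn at matching quantiles of the null is near 0
  pooled <- as.vector(null$null_scores)
  E["g6", ] <- stats::quantile(pooled, probs = (1:ncol(E) - 0.5) / ncol(E),
                               type = 1)
  gr2 <- ks_global_ranking(E, null)
  expect_lt(gr2$ks_statistic[gr2$feature_id == "g6"], 0.3)
  # invariance under a joint strictly monotone transform
  tr <- function(x) x^3 + 2 * x
  nullt <- null
  nullt$null_scores <- tr(null$null_scores)
  nullt$mean <- colMeans(nullt$null_scores)
  nullt$sd <- apply(nullt$null_scores, 2, sd)
  grt <- ks_global_ranking(tr(E), nullt)
  expect_equal(grt$ks_statistic[order(grt$feature_id)],
               gr2$ks_statistic[order(gr2$feature_id)], tolerance = 1e-12)
})

test_that("annotation labels exactly the enriched cells", {
  fx <- block_marker_fixture()
  ms <- score_markers_per_cell(fx$X, fx$marker, fx$coords, gamma = fx$gamma)
  S <- pairwise_similarity(fx$coords, seq_len(nrow(fx$X)), gamma = fx$gamma)
  null <- build_null(fx$X, S, seed = 21)
  ann <- annotate_cells(ms, null, sd_cutoff = 8,
                        label_map = c(g1 = "block"))
  expect_identical(ann$label == "block", unname(fx$in_block))
  # scores at the null mean annotate nothing
  ms0 <- ms
  ms0[, 1] <- null$mean
  ann0 <- annotate_cells(ms0, null, sd_cutoff = 8, label_map = c(g1 = "block"))
  expect_true(all(ann0$label == "unassigned"))
})

test_that("cells enriched for several markers keep all labels", {
  fx <- block_marker_fixture()
  X <- fx$X
  X[, 2] <- X[, 1] # second marker with the same confinement
  colnames(X)[2] <- "g2"
  ms <- score_markers_per_cell(X, c("g1", "g2"), fx$coords, gamma = fx$gamma)
  S <- pairwise_similarity(fx$coords, seq_len(nrow(X)), gamma = fx$gamma)
  null <- build_null(X, S, seed = 22)
  ann <- annotate_cells(ms, null, sd_cutoff = 8,
                        label_map = c(g1 = "A", g2 = "B"))
  expect_true(all(ann$label[fx$in_block] == "A;B"))
  expect_true(all(ann$n_labels[fx$in_block] == 2))
})
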