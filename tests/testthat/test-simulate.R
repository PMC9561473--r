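test_that("group simulation honours its contract", {
  sim <- simulate_groups(100, 2, 50, de_prob = 0, seed = 1)
  expect_true(all(sim$de_factors == 1))
  expect_false(any(de_truth(sim)))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(table(sim$group_labels)[[1]], 50L)
  # determinism
  sim2 <- simulate_groups(100, 2, 50, de_prob = 0, seed = 1)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$de_factors, sim2$de_factors)
  sim3 <- simulate_groups(100, 2, 50, de_prob = 0.3, seed = 2)
  expect_identical(de_truth(sim3),
                   apply(sim3$de_factors != 1, 1, any))
  expect_error(simulate_groups(100, 1, 50), "n_groups")
  expect_error(simulate_groups(100, 2, 50, de_prob = 2), "de_prob")
  expect_error(simulate_groups(100, 2, 50, de_factor_range = c(0.5, 2)),
               "de_factor_range")
})

test_that("group DE factors materialize as fold changes in the counts", {
  # degenerate factor range pins every DE magnitude at 4
  sim <- simulate_groups(5000, 2, 60, de_prob = 0.5,
                         de_factor_range = c(4, 4), seed = 7)
  up_in_1 <- which(abs(sim$de_factors[, 1] - 4) < 1e-9 & sim$de_factors[, 2] == 1)
  expect_gt(length(up_in_1), 0)
  g <- up_in_1[which.max(sim$base_means[up_in_1])] # strongest signal
  in1 <- sim$group_labels == "group_1"
  x1 <- sim$counts[in1, g] / sim$size_factors[in1]
  x2 <- sim$counts[!in1, g] / sim$size_factors[!in1]
  diff_hat <- mean(x1) - 4 * mean(x2)
  se <- sqrt(var(x1) / length(x1) + 16 * var(x2) / length(x2))
  expect_lt(abs(diff_hat), 3 * se)
})

test_that("path simulation interpolates from root to branch end", {
  sim <- simulate_paths(4000, 2, 40, de_prob = 0.5,
                        de_factor_range = c(3, 3), seed = 9)
  expect_true(all(sim$pseudotime >= 0 & sim$pseudotime <= 1))
  # an up-regulated gene's mean over a branch is base * E[f^t] = base*(f-1)/ln f
  up <- which(abs(sim$de_factors[, 1] - 3) < 1e-9 & sim$de_factors[, 2] == 1)
  g <- up[which.max(sim$base_means[up])]
  in1 <- sim$group_labels == "group_1"
  x <- sim$counts[in1, g] / sim$size_factors[in1]
  expected <- sim$base_means[g] * (3 - 1) / log(3)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 3 * se)
  # cells at the root keep the base mean: factor^0 = 1 for every gene
  near_root <- sim$pseudotime < 0.02
  expect_gt(sum(near_root), 10)
  rootx <- sim$counts[near_root, g] / sim$size_factors[near_root]
  se_root <- sd(rootx) / sqrt(length(rootx))
  expect_lt(abs(mean(rootx) - sim$base_means[g] * mean(3^sim$pseudotime[near_root])),
            3 * se_root + 1e-9)
  # no DE means one homogeneous population regardless of branching
  h <- simulate_paths(500, 4, 30, de_prob = 0, seed = 3)
  expect_true(all(h$de_factors == 1))
})

test_that("library size and dispersion are recoverable by method of moments", {
  # dispersion, with size factors switched off
  sim_d <- simulate_groups(5000, 2, 300, de_prob = 0, dispersion = 0.1,
                           lib_size_sd = 0, seed = 31)
  mu <- colMeans(sim_d$counts)
  v <- apply(sim_d$counts, 2, var)
  keep <- mu > 1
  d_hat <- stats::median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_lt(abs(d_hat - 0.1) / 0.1, 0.1)
  # log library-size spread tracks the size-factor sdlog
  sim_l <- simulate_groups(5000, 2, 2000, de_prob = 0, lib_size_sd = 0.25,
                           seed = 32)
  s_hat <- sd(log(rowSums(sim_l$counts)))
  expect_lt(abs(s_hat - 0.25) / 0.25, 0.1)
})

test_that("the PCA test embedding is deterministic and separates groups", {
  sim <- simulate_groups(200, 2, 100, de_prob = 0.2, seed = 13)
  emb <- make_test_embedding(sim$counts, n_components = 5)
  expect_identical(dim(emb), c(200L, 5L))
  expect_identical(emb, make_test_embedding(sim$counts, n_components = 5))
  g1 <- sim$group_labels == "group_1"
  sep <- abs(mean(emb[g1, 1]) - mean(emb[!g1, 1]))
  within <- max(sd(emb[g1, 1]), sd(emb[!g1, 1]))
  expect_gt(sep, within)
  # duplicated cells map to duplicated embedding rows
  dup <- rbind(sim$counts, sim$counts[1:3, ])
  embd <- make_test_embedding(dup, n_components = 3)
  expect_equal(unname(embd[201:203, ]), unname(embd[1:3, ]), tolerance = 1e-8)
  expect_error(make_test_embedding(sim$counts, 0), "positive")
  expect_error(make_test_embedding(sim$counts, 1000), "min\\(dim")
})

test_that("a rank-1 expression pattern is recovered by one component", {
  withr::with_seed(15, {
    cell_axis <- sort(runif(80, 0, 2))
    gene_load <- runif(40, 0.5, 2)
    counts <- expm1(outer(cell_axis, gene_load)) # log1p-inverse of rank-1
  })
  emb <- make_test_embedding(counts, n_components = 1)
  expect_gt(abs(cor(emb[, 1], cell_axis)), 0.99)
})

test_that("AUROC matches the pair-counting oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)), 0)
  prob <- c(0.9, 0.8, 0.8, 0.55, 0.5, 0.5, 0.5, 0.3, 0.2, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(auroc(prob, truth), oracle_auroc(prob, truth))
  withr::with_seed(21, {
    for (i in 1:10) {
      p <- round(runif(15), 1) # coarse grid forces ties
      t <- runif(15) < 0.4
      if (all(t) || !any(t)) next
      expect_equal(auroc(p, t), oracle_auroc(p, t))
    }
  })
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("marker recovery aggregates per-gene evidence correctly", {
  sim <- simulate_groups(200, 2, 100, de_prob = 0.2, seed = 17)
  res <- run_benchmark(sim, seed = 17)
  expect_s3_class(res, "benchmark_result")
  expect_true(res$auroc >= 0 && res$auroc <= 1)
  expect_identical(res$n_refs, 5L) # 0.5% of 200, floored at min_refs
  expect_identical(length(res$probabilities), 100L)
  # the same pipeline rerun with the same seed is identical
  res2 <- run_benchmark(sim, seed = 17)
  expect_identical(res$auroc, res2$auroc)
  expect_identical(res$references$indices, res2$references$indices)
  # max_abs_nsd aggregation is a valid alternative
  sim_small <- simulate_groups(150, 2, 60, de_prob = 0.3, seed = 19)
  r_nsd <- run_benchmark(sim_small, aggregation = "max_abs_nsd", seed = 19)
  expect_true(r_nsd$auroc >= 0 && r_nsd$auroc <= 1)
})
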