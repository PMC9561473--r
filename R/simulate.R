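#' Simulate group-structured scRNA-seq counts with known DE factors
#'
#' Negative-binomial count simulator in the spirit of the
#' gamma-Poisson "groups" design used in scRNA-seq benchmarking: gene base
#' means are drawn from a Gamma distribution, each gene is differentially
#' expressed (DE) in each group with probability `de_prob`, receiving a
#' multiplicative factor drawn log-uniformly from `de_factor_range` and
#' inverted (factor -> 1/factor) with probability 1/2 so up- and
#' down-regulation are equally likely. A factor of exactly 1 means "not DE
#' in that group" and is the benchmark's ground truth. Cells are split
#' evenly across groups (or by `group_weights`), get log-normal size
#' factors centred on 1, and counts are drawn from a negative binomial
#' (gamma-Poisson) with the given dispersion. Dropout and batch effects
#' are deliberately not modelled: the benchmark needs ground-truth DE
#' factors and realistic overdispersion, nothing more.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param n_groups Number of groups (>= 2).
#' @param de_prob Probability a gene is DE in a given group (default 0.1).
#' @param de_factor_range Length-2 positive range (> 1) of DE factor
#'   magnitudes, sampled log-uniformly (default `c(3, 6)`).
#' @param base_mean_shape,base_mean_rate Gamma parameters of gene base
#'   means (defaults 0.6 and 0.3, typical of UMI data).
#' @param dispersion NB dispersion (1/size); variance is
#'   `mu + dispersion * mu^2` (default 0.1).
#' @param lib_size_sd SD of log cell size factors (default 0.25).
#' @param group_weights Optional positive weights for uneven group sizes.
#' @param seed RNG seed.
#' @return A `simulated_dataset`: list with `counts` (cells x genes
#'   integer matrix), `group_labels`, `de_factors` (genes x groups),
#'   `base_means`, `size_factors`, `mode`, `seed`, `params`.
#' @seealso [simulate_paths()], [de_truth()], [run_benchmark()].
#' @export
simulate_groups <- function(n_cells, n_groups, n_genes, de_prob = 0.1,
                            de_factor_range = c(3, 6),
                            base_mean_shape = 0.6, base_mean_rate = 0.3,
                            dispersion = 0.1, lib_size_sd = 0.25,
                            group_weights = NULL, seed = NULL) {
  check_sim_args(n_cells, n_groups, n_genes, de_prob, de_factor_range)
  with_seed(seed, {
    parts <- sim_common(n_cells, n_groups, n_genes, de_prob, de_factor_range,
                        base_mean_shape, base_mean_rate, lib_size_sd,
                        group_weights)
    mu <- parts$size_factors *
      t(parts$base_means * parts$de_factors[, parts$group_idx, drop = FALSE])
    counts <- draw_counts(mu, dispersion, n_cells, n_genes)
    new_simulated_dataset(counts, parts, mode = "groups", seed = seed,
                          extra = list(dispersion = dispersion,
                                       lib_size_sd = lib_size_sd))
  })
}

#' Simulate trajectory-structured counts with known DE factors
#'
#' Like [simulate_groups()], but each cell sits at a pseudotime
#' `t ~ Uniform(0, 1)` along its branch, and DE gene means interpolate
#' log-linearly from the root mean (t = 0) to the branch-end mean
#' (factor fully applied at t = 1): `mu = base_mean * factor^t`.
#' `group_labels` are branch ids and `de_factors` the branch-end factors.
#'
#' @inheritParams simulate_groups
#' @param n_branches Number of trajectory branches (>= 2).
#' @return A `simulated_dataset` with `mode = "paths"` and an extra
#'   `pseudotime` element.
#' @export
simulate_paths <- function(n_cells, n_branches, n_genes, de_prob = 0.1,
                           de_factor_range = c(3, 6),
                           base_mean_shape = 0.6, base_mean_rate = 0.3,
                           dispersion = 0.1, lib_size_sd = 0.25,
                           group_weights = NULL, seed = NULL) {
  check_sim_args(n_cells, n_branches, n_genes, de_prob, de_factor_range)
  with_seed(seed, {
    parts <- sim_common(n_cells, n_branches, n_genes, de_prob,
                        de_factor_range, base_mean_shape, base_mean_rate,
                        lib_size_sd, group_weights)
    tt <- stats::runif(n_cells)
    logf <- log(parts$de_factors[, parts$group_idx, drop = FALSE])  # genes x cells
    mu <- parts$size_factors * t(parts$base_means * exp(logf * rep(tt, each = n_genes)))
    counts <- draw_counts(mu, dispersion, n_cells, n_genes)
    ds <- new_simulated_dataset(counts, parts, mode = "paths", seed = seed,
                                extra = list(dispersion = dispersion,
                                             lib_size_sd = lib_size_sd))
    ds$pseudotime <- tt
    ds
  })
}

check_sim_args <- function(n_cells, n_groups, n_genes, de_prob,
                           de_factor_range) {
  if (n_cells < 2L || n_genes < 1L) validation_error("need >= 2 cells and >= 1 gene")
  if (n_groups < 2L) validation_error("`n_groups` must be >= 2")
  if (de_prob < 0 || de_prob > 1) validation_error("`de_prob` must be in [0, 1]")
  if (length(de_factor_range) != 2L || any(de_factor_range <= 1) ||
      de_factor_range[1] > de_factor_range[2]) {
    validation_error("`de_factor_range` must be an increasing range with both ends > 1")
  }
}

sim_common <- function(n_cells, n_groups, n_genes, de_prob, de_factor_range,
                       base_mean_shape, base_mean_rate, lib_size_sd,
                       group_weights) {
  base_means <- stats::rgamma(n_genes, shape = base_mean_shape,
                              rate = base_mean_rate)
  de_factors <- matrix(1, n_genes, n_groups,
                       dimnames = list(paste0("gene_", seq_len(n_genes)),
                                       paste0("group_", seq_len(n_groups))))
  is_de <- matrix(stats::runif(n_genes * n_groups) < de_prob, n_genes, n_groups)
  n_de <- sum(is_de)
  if (n_de > 0) {
    mag <- exp(stats::runif(n_de, log(de_factor_range[1]),
                            log(de_factor_range[2])))
    down <- stats::runif(n_de) < 0.5
    de_factors[is_de] <- ifelse(down, 1 / mag, mag)
  }
  if (is.null(group_weights)) group_weights <- rep(1, n_groups)
  if (length(group_weights) != n_groups || any(group_weights <= 0)) {
    validation_error("`group_weights` must be ", n_groups, " positive numbers")
  }
  group_idx <- rep(seq_len(n_groups),
                   diff(round(cumsum(c(0, group_weights)) / sum(group_weights) * n_cells)))
  # mean-1 log-normal size factors
  size_factors <- stats::rlnorm(n_cells, meanlog = -lib_size_sd^2 / 2,
                                sdlog = lib_size_sd)
  list(base_means = base_means, de_factors = de_factors,
       group_idx = group_idx, size_factors = size_factors)
}

draw_counts <- function(mu, dispersion, n_cells, n_genes) {
  counts <- matrix(
    stats::rnbinom(n_cells * n_genes, mu = as.vector(mu), size = 1 / dispersion),
    n_cells, n_genes
  )
  dimnames(counts) <- list(paste0("cell_", seq_len(n_cells)),
                           paste0("gene_", seq_len(n_genes)))
  counts
}

new_simulated_dataset <- function(counts, parts, mode, seed, extra) {
  structure(
    list(counts = counts,
         group_labels = colnames(parts$de_factors)[parts$group_idx],
         de_factors = parts$de_factors,
         base_means = parts$base_means,
         size_factors = parts$size_factors,
         mode = mode, seed = seed, params = extra),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes, mode = ", x$mode, ", ",
      length(unique(x$group_labels)), " groups, ",
      sum(de_truth(x)), " DE genes\n", sep = "")
  invisible(x)
}

#' Ground-truth DE flags of a simulated dataset
#'
#' A gene is a true marker iff its DE factor differs from 1 in any group.
#'
#' @param sim A `simulated_dataset`.
#' @return Logical vector over genes.
#' @export
de_truth <- function(sim) {
  apply(sim$de_factors != 1, 1L, any)
}

#' PCA test embedding of a count matrix
#'
#' Deterministic stand-in for the UMAP preprocessing of a real analysis:
#' log1p-transform, center genes, and project cells onto the top
#' `n_components` principal axes. The sign of each component is fixed by
#' making its largest-magnitude gene loading positive, so the embedding is
#' reproducible across platforms.
#'
#' @param counts Cells x genes matrix (dense or sparse).
#' @param n_components Number of principal components
#'   (`< min(dim(counts))`).
#' @param seed Unused by the (deterministic) projection; accepted for
#'   interface uniformity with the other generators.
#' @return Cells x `n_components` embedding matrix.
#' @export
make_test_embedding <- function(counts, n_components = 10L, seed = NULL) {
  if (n_components <= 0) validation_error("`n_components` must be positive")
  if (n_components >= min(dim(counts))) {
    validation_error("`n_components` must be < min(dim(counts))")
  }
  L <- log1p(as.matrix(counts))
  L <- sweep(L, 2L, colMeans(L), "-")
  sv <- svd(L, nu = n_components, nv = n_components)
  # sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  emb <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) *
    rep(flip, each = nrow(L))
  dimnames(emb) <- list(rownames(L), paste0("PC", seq_len(n_components)))
  emb
}

#' AUROC of marker recovery from a significance table
#'
#' Aggregates each gene's per-reference-cell p-values into a single
#' probability of being differentially expressed (`1 - p` with `p` the
#' minimum across reference cells by default, or the p-value of the
#' largest `|n_sd|`), then computes the AUROC of that probability against
#' the ground-truth DE flags via the rank-sum identity (ties averaged).
#'
#' @param sig A `significance_table` from [significance_calls()].
#' @param truth Logical ground-truth DE flag per gene, named by feature id
#'   or aligned to the table's sorted unique feature ids.
#' @param aggregation `"min_p"` (default) or `"max_abs_nsd"`.
#' @return A `benchmark_result`: list with `auroc`, `method`,
#'   `probabilities` (per gene), `truth`.
#' @export
auroc_marker_recovery <- function(sig, truth,
                                  aggregation = c("min_p", "max_abs_nsd")) {
  aggregation <- match.arg(aggregation)
  fid <- sort(unique(sig$feature_id))
  if (!is.null(names(truth))) truth <- truth[fid]
  if (length(truth) != length(fid) || anyNA(truth)) {
    validation_error("`truth` must provide one flag per scored feature")
  }
  prob <- if (aggregation == "min_p") {
    1 - tapply(sig$p, sig$feature_id, min)[fid]
  } else {
    nsd <- tapply(abs(sig$n_sd), sig$feature_id, max)[fid]
    1 - 2 * stats::pnorm(-nsd)
  }
  structure(
    list(auroc = auroc(prob, truth), method = aggregation,
         probabilities = prob, truth = truth),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> AUROC = ", format(x$auroc, digits = 4),
      " (aggregation: ", x$method, ", ", sum(x$truth), "/",
      length(x$truth), " true markers)\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUROC (equivalent to the normalized Wilcoxon rank sum):
#' the probability that a randomly chosen positive outranks a randomly
#' chosen negative, with tied scores contributing 1/2.
#'
#' @param score Numeric classifier score, higher = more positive.
#' @param truth Logical labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    validation_error("`truth` must contain both classes")
  }
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end marker-recovery benchmark
#'
#' Runs the full pipeline on a simulated dataset: PCA test embedding,
#' reference cell selection by the dissimilarity algorithm (0.5% of cells,
#' at least `min_refs`), RBF similarity, enrichment scoring of the
#' log1p-transformed counts, permutation null, significance calls, and
#' AUROC of marker recovery against the simulation's ground truth.
#'
#' Because the PCA embedding's coordinate scale is arbitrary, the RBF
#' `gamma` defaults to the median heuristic ([suggest_gamma()]).
#'
#' @param sim A `simulated_dataset`.
#' @param ref_frac Fraction of cells used as reference cells
#'   (default 0.005).
#' @param min_refs Lower bound on the number of reference cells
#'   (default 5).
#' @param n_components PCA components of the test embedding (default 10).
#' @param gamma RBF bandwidth or `"auto"` (median heuristic; default).
#' @param n_rounds Permutation rounds for the null (default 1).
#' @param aggregation Passed to [auroc_marker_recovery()].
#' @param seed Seed for selection tie-breaks and the permutation null.
#' @return A `benchmark_result` with the fitted pipeline objects attached
#'   (`references`, `n_refs`, `gamma`).
#' @export
run_benchmark <- function(sim, ref_frac = 0.005, min_refs = 5L,
                          n_components = 10L, gamma = "auto",
                          n_rounds = 1L, aggregation = "min_p",
                          seed = NULL) {
  if (!inherits(sim, "simulated_dataset")) {
    validation_error("`sim` must be a simulated_dataset")
  }
  emb <- make_test_embedding(sim$counts, n_components)
  if (identical(gamma, "auto")) gamma <- suggest_gamma(emb, seed = seed)
  n_refs <- max(as.integer(min_refs), as.integer(round(ref_frac * nrow(emb))))
  refs <- select_reference_cells(emb, n = n_refs, gamma = gamma, seed = seed)
  S <- pairwise_similarity(emb, refs$indices, kind = "rbf", gamma = gamma)
  X <- log1p(sim$counts)
  E <- score_all(X, S)
  null <- build_null(X, S, n_rounds = n_rounds,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  sig <- significance_calls(E, null)
  res <- auroc_marker_recovery(sig, stats::setNames(de_truth(sim), colnames(sim$counts)),
                               aggregation = aggregation)
  res$references <- refs
  res$n_refs <- n_refs
  res$gamma <- gamma
  res
}
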