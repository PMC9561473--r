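#' Permutation-derived empirical null of enrichment scores
#'
#' Each permutation round shuffles every feature vector independently
#' across cells (cell labels permuted per feature), which breaks the
#' feature-embedding association while preserving each feature's marginal
#' value distribution, then scores all randomized features against every
#' reference cell. The pooled scores form, per reference cell, an
#' empirical null against which observed enrichment scores are calibrated
#' in standard-deviation units.
#'
#' @inheritParams score_all
#' @param n_rounds Number of independent permutation rounds (default 1,
#'   i.e. one shuffle of all feature vectors; the null then holds
#'   `n_features` scores per reference cell).
#' @param seed Seed driving the permutations.
#' @return A `null_model`: list with `null_scores`
#'   (`n_features * n_rounds` x references), per-reference `mean` and `sd`
#'   (sample SD), `n_rounds`, and `seed`.
#' @export
build_null <- function(X, similarities, n_rounds = 1L, seed = NULL) {
  if (!is.numeric(n_rounds) || length(n_rounds) != 1L || n_rounds < 1L) {
    validation_error("`n_rounds` must be a positive integer")
  }
  n_rounds <- as.integer(n_rounds)
  if (ncol(X) * n_rounds < 30L) {
    warning("null sample has only ", ncol(X) * n_rounds,
            " scores per reference cell; SD estimates may be unstable")
  }
  null_scores <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_rounds), function(r) {
      score_all(permute_columns(X), similarities)
    }))
  })
  rownames(null_scores) <- NULL
  m <- colMeans(null_scores)
  s <- apply(null_scores, 2L, stats::sd)
  structure(
    list(null_scores = null_scores, mean = m, sd = s,
         reference_cell_ids = colnames(similarities),
         n_rounds = n_rounds, seed = seed),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> ", nrow(x$null_scores), " null scores x ",
      ncol(x$null_scores), " reference cells (", x$n_rounds,
      " round(s))\n", sep = "")
  invisible(x)
}

# Independently permute each column of a cells x features matrix across
# cells. Sparse input stays sparse: a column's nonzero values are assigned
# to a uniformly random subset of rows in random order, which is exactly a
# uniform permutation of the full column.
permute_columns <- function(X) {
  n <- nrow(X)
  if (inherits(X, "sparseMatrix")) {
    Xc <- methods::as(X, "CsparseMatrix")
    p <- Xc@p
    newi <- Xc@i
    newx <- Xc@x
    for (j in seq_len(ncol(Xc))) {
      if (p[j + 1L] == p[j]) next
      at <- (p[j] + 1L):p[j + 1L]
      rows <- sample.int(n, length(at))
      o <- order(rows)
      newi[at] <- rows[o] - 1L
      newx[at] <- Xc@x[at][o]
    }
    out <- Xc
    out@i <- newi
    out@x <- newx
    out
  } else {
    out <- apply(X, 2L, sample)
    dimnames(out) <- dimnames(X)
    out
  }
}

#' Significance calls for enrichment scores against an empirical null
#'
#' Converts raw enrichment scores into signed standard-deviation units
#' (`n_sd`) relative to each reference cell's empirical null, with
#' p-values, Bonferroni correction over all `features x references` tests,
#' and Benjamini-Hochberg FDR within each reference cell (each reference
#' cell's marker list is treated as its own family).
#'
#' The primary criterion is the SD cutoff: a (feature, reference) pair is
#' significant when `|n_sd| >= sd_cutoff` (two-sided; set
#' `sided = "one"` for positive enrichment only). p-values default to the
#' Gaussian tail of `n_sd`, which extends into the extreme tails (8-20 SD)
#' where the empirical rank within the null saturates at
#' `1 / n_null`; `p_method = "empirical"` gives the rank-based value.
#'
#' @param E Features x references score matrix from [score_all()].
#' @param null A `null_model` from [build_null()] with matching reference
#'   columns.
#' @param sd_cutoff Positive number of null SDs required for significance
#'   (default 5).
#' @param alpha Significance level attached to the table for the p-based
#'   criteria (default 0.05); does not affect the `significant` flag.
#' @param p_method `"gaussian"` (default) or `"empirical"`.
#' @param sided `"two"` (default, discovery of presence and absence
#'   markers) or `"one"` (positive enrichment only).
#' @return A `significance_table` data.frame with one row per
#'   (feature, reference) pair, ordered by feature then reference, and
#'   columns `feature_id`, `reference_cell_id`, `score`, `n_sd`, `p`,
#'   `p_bonferroni`, `q_bh`, `significant`.
#' @export
significance_calls <- function(E, null, sd_cutoff = 5, alpha = 0.05,
                               p_method = c("gaussian", "empirical"),
                               sided = c("two", "one")) {
  p_method <- match.arg(p_method)
  sided <- match.arg(sided)
  if (!is.numeric(sd_cutoff) || sd_cutoff <= 0) {
    validation_error("`sd_cutoff` must be positive")
  }
  if (!inherits(null, "null_model")) validation_error("`null` must be a null_model")
  if (ncol(E) != ncol(null$null_scores)) {
    validation_error("`E` and `null` disagree on the number of reference cells")
  }
  if (!is.null(colnames(E)) && !is.null(null$reference_cell_ids) &&
      !identical(colnames(E), null$reference_cell_ids)) {
    validation_error("reference cell ids of `E` and `null` do not match")
  }
  nf <- nrow(E); nr <- ncol(E)
  sd_safe <- ifelse(null$sd == 0, Inf, null$sd)  # degenerate null => n_sd 0
  n_sd <- sweep(sweep(E, 2L, null$mean, "-"), 2L, sd_safe, "/")

  if (p_method == "gaussian") {
    p <- if (sided == "two") 2 * stats::pnorm(-abs(n_sd)) else stats::pnorm(-n_sd)
  } else {
    centered_null <- sweep(null$null_scores, 2L, null$mean, "-")
    p <- matrix(NA_real_, nf, nr)
    for (j in seq_len(nr)) {
      nj <- centered_null[, j]
      dev <- E[, j] - null$mean[j]
      exceed <- if (sided == "two") {
        vapply(abs(dev), function(d) sum(abs(nj) >= d), numeric(1))
      } else {
        vapply(dev, function(d) sum(nj >= d), numeric(1))
      }
      p[, j] <- (1 + exceed) / (1 + length(nj))
    }
  }
  p <- pmin(p, 1)

  fid <- if (is.null(rownames(E))) paste0("feature_", seq_len(nf)) else rownames(E)
  rid <- if (is.null(colnames(E))) paste0("ref_", seq_len(nr)) else colnames(E)
  tab <- data.frame(
    feature_id = rep(fid, times = nr),
    reference_cell_id = rep(rid, each = nf),
    score = as.vector(E),
    n_sd = as.vector(n_sd),
    p = as.vector(p),
    stringsAsFactors = FALSE
  )
  tab$p_bonferroni <- pmin(1, tab$p * nf * nr)
  tab$q_bh <- stats::ave(tab$p, tab$reference_cell_id,
                         FUN = function(x) stats::p.adjust(x, "BH"))
  tab$significant <- if (sided == "two") abs(tab$n_sd) >= sd_cutoff else tab$n_sd >= sd_cutoff
  tab <- tab[order(tab$feature_id, tab$reference_cell_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sd_cutoff") <- sd_cutoff
  attr(tab, "alpha") <- alpha
  attr(tab, "sided") <- sided
  class(tab) <- c("significance_table", "data.frame")
  tab
}

#' Global feature ranking by Kolmogorov-Smirnov divergence from the null
#'
#' Ranks every feature as a *global* marker by the two-sample
#' Kolmogorov-Smirnov statistic between its observed enrichment scores
#' across all reference cells and the pooled empirical null scores (all
#' permuted features x all reference cells). Features whose score
#' distribution departs most from the null rank first; p-values come from
#' the two-sample KS test and are BH-corrected over features.
#'
#' @inheritParams significance_calls
#' @return A `global_ranking` data.frame with columns `feature_id`,
#'   `ks_statistic`, `p`, `p_corrected`, `rank`, ordered by rank
#'   (ascending `p_corrected`, ties broken by larger `ks_statistic`, then
#'   feature id).
#' @export
ks_global_ranking <- function(E, null) {
  if (!inherits(null, "null_model")) validation_error("`null` must be a null_model")
  pooled <- as.vector(null$null_scores)
  if (length(pooled) == 0) validation_error("empty null model")
  if (ncol(E) < 2L) {
    warning("only ", ncol(E), " reference cell(s); the per-feature score ",
            "sample is very small for a KS test")
  }
  fid <- if (is.null(rownames(E))) paste0("feature_", seq_len(nrow(E))) else rownames(E)
  ks <- vapply(seq_len(nrow(E)), function(f) {
    res <- suppressWarnings(stats::ks.test(E[f, ], pooled))
    c(res$statistic, res$p.value)
  }, numeric(2))
  tab <- data.frame(
    feature_id = fid,
    ks_statistic = ks[1, ],
    p = ks[2, ],
    stringsAsFactors = FALSE
  )
  tab$p_corrected <- stats::p.adjust(tab$p, "BH")
  o <- order(tab$p_corrected, -tab$ks_statistic, tab$feature_id)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("global_ranking", "data.frame")
  tab
}

#' Annotate cells from marker enrichment scores
#'
#' Inverse-mode annotation: given per-cell enrichment scores for a known
#' marker panel (from [score_markers_per_cell()]) and a per-cell empirical
#' null, a cell receives a marker's label when its score lies at least
#' `sd_cutoff` standard deviations *above* the null mean (one-sided:
#' only positive enrichment annotates). Cells passing for several markers
#' keep all labels; cells passing for none are `"unassigned"`.
#'
#' @param marker_scores Cells x markers score matrix.
#' @param null A `null_model` whose columns are the same cells (build it
#'   with every cell as a reference).
#' @param sd_cutoff Positive SD threshold (default 8).
#' @param label_map Named character vector mapping marker id -> label;
#'   defaults to the marker ids themselves.
#' @return A data.frame with `cell_id`, `label` (labels joined by `";"`,
#'   or `"unassigned"`), and `n_labels`.
#' @export
annotate_cells <- function(marker_scores, null, sd_cutoff = 8,
                           label_map = NULL) {
  if (!inherits(null, "null_model")) validation_error("`null` must be a null_model")
  if (!is.numeric(sd_cutoff) || sd_cutoff <= 0) {
    validation_error("`sd_cutoff` must be positive")
  }
  if (nrow(marker_scores) != ncol(null$null_scores)) {
    validation_error("`null` must hold one column per cell in `marker_scores`")
  }
  markers <- colnames(marker_scores)
  if (is.null(label_map)) {
    label_map <- stats::setNames(markers, markers)
  }
  missing_ids <- setdiff(markers, names(label_map))
  if (length(missing_ids) > 0) {
    validation_error("no label for marker(s): ", paste(missing_ids, collapse = ", "))
  }
  sd_safe <- ifelse(null$sd == 0, Inf, null$sd)
  n_sd <- (marker_scores - null$mean) / sd_safe  # column recycling over cells
  pass <- n_sd >= sd_cutoff
  label <- apply(pass, 1L, function(row) {
    hits <- label_map[markers[row]]
    if (length(hits) == 0) "unassigned" else paste(hits, collapse = ";")
  })
  data.frame(
    cell_id = cell_ids_of(marker_scores),
    label = unname(label),
    n_labels = unname(rowSums(pass)),
    stringsAsFactors = FALSE
  )
}
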