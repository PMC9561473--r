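#' Enrichment score of one feature in one reference cell's neighbourhood
#'
#' The enrichment score of feature `f` in reference cell `c` is the
#' ordinary-least-squares slope of the regression of the similarity vector
#' `y_c` on the feature vector `x_f`, fitted with an intercept:
#' \deqn{\hat\beta_{c,f} = \mathrm{cov}(x_f, y_c) / \mathrm{var}(x_f).}
#' Features detected only in cells similar to `c` score high and positive,
#' features with non-selective detection score near 0, and features detected
#' only in cells dissimilar to `c` score negative. The intercept matters:
#' without it, nonnegative expression and similarity could never yield the
#' negative scores that flag selectively *absent* features.
#'
#' Zero-variance features (e.g. completely undetected genes) score exactly
#' 0 rather than NaN, consistent with "uninformative" features scoring
#' around zero. Scores are computed on the matrix values as supplied
#' (counts, log-normalized expression, tf-idf, binarized accessibility);
#' no hidden normalization is applied.
#'
#' @param x Numeric feature vector over cells (length >= 2).
#' @param y Numeric similarity vector over the same cells.
#' @return A single slope.
#' @examples
#' enrichment_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.9, 0.8)) # 0.7
#' @seealso [score_all()] for the vectorized features x references form.
#' @export
enrichment_score <- function(x, y) {
  if (length(x) != length(y)) {
    validation_error("`x` and `y` must have equal length")
  }
  if (length(x) < 2L) validation_error("need at least 2 cells")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    validation_error("`x` and `y` must be finite")
  }
  if (min(x) == max(x)) return(0)
  stats::cov(x, y) / stats::var(x)
}

#' Enrichment scores for all features against all reference cells
#'
#' Vectorized single pass over reference cells:
#' `scores[f, c] = enrichment_score(X[, f], similarities[, c])`.
#' Sparse feature matrices are consumed without densification via
#' cross-product moments.
#'
#' @param X Cells x features matrix (dense or `Matrix` sparse),
#'   nonnegative finite values; rownames are cell ids, colnames feature ids.
#' @param similarities Cells x references similarity matrix, as returned by
#'   [pairwise_similarity()]. Row order must match `X`; when both carry
#'   cell ids this is enforced.
#' @return Features x references numeric matrix of slopes, dimnames
#'   `(feature_ids, reference_cell_ids)`.
#' @export
score_all <- function(X, similarities) {
  if (is.null(dim(X)) || is.null(dim(similarities))) {
    validation_error("`X` and `similarities` must be matrices")
  }
  if (nrow(X) != nrow(similarities)) {
    validation_error("`X` (", nrow(X), " cells) and `similarities` (",
                     nrow(similarities), " cells) disagree on cell count")
  }
  if (nrow(X) < 2L) validation_error("need at least 2 cells")
  if (!is.null(rownames(X)) && !is.null(rownames(similarities)) &&
      !identical(rownames(X), rownames(similarities))) {
    validation_error("cell ids of `X` and `similarities` do not match")
  }
  n <- nrow(X)
  mx <- Matrix::colMeans(X)
  my <- colMeans(similarities)
  # cov(x, y) * (n-1)/n = E[xy] - E[x]E[y]; the 1/n vs 1/(n-1) factor
  # cancels in the cov/var ratio, so population moments are used throughout.
  cross <- as.matrix(Matrix::crossprod(X, similarities)) / n
  num <- cross - outer(mx, my)
  msq <- Matrix::colMeans(X * X)
  vx <- msq - mx^2
  # constant columns: vx is 0 up to rounding in the moment difference
  zero_var <- vx <= 0 | vx < 1e-13 * msq
  vx[zero_var] <- 1
  scores <- num / vx
  scores[zero_var, ] <- 0
  dimnames(scores) <- list(feature_ids_of(X), colnames(similarities))
  scores
}

#' Score a marker panel in every cell's neighbourhood (inverse mode)
#'
#' For annotation, scoring is inverted: instead of discovering markers for
#' a few reference cells, a known marker panel is scored with *every* cell
#' acting as its own reference, so each cell gets one enrichment score per
#' marker. Cells are processed in blocks to bound the cells x cells
#' similarity memory.
#'
#' @inheritParams score_all
#' @param marker_ids Character vector of feature ids present in
#'   `colnames(X)`.
#' @inheritParams pairwise_similarity
#' @param block_size Number of reference cells per block (memory knob).
#' @return Cells x markers numeric matrix of enrichment scores.
#' @seealso [annotate_cells()] for thresholding these scores against a
#'   per-cell permutation null.
#' @export
score_markers_per_cell <- function(X, marker_ids, embedding,
                                   kind = c("rbf", "cosine"), gamma = NULL,
                                   block_size = 512L) {
  kind <- match.arg(kind)
  check_embedding(embedding)
  if (nrow(X) != nrow(embedding)) {
    validation_error("`X` and `embedding` disagree on cell count")
  }
  fid <- feature_ids_of(X)
  missing_ids <- setdiff(marker_ids, fid)
  if (length(missing_ids) > 0) {
    validation_error("marker id(s) not in the feature matrix: ",
                     paste(missing_ids, collapse = ", "))
  }
  Xm <- X[, match(marker_ids, fid), drop = FALSE]
  N <- nrow(X)
  out <- matrix(NA_real_, N, length(marker_ids),
                dimnames = list(cell_ids_of(X), marker_ids))
  for (from in seq(1L, N, by = block_size)) {
    block <- from:min(from + block_size - 1L, N)
    S <- pairwise_similarity(embedding, block, kind = kind, gamma = gamma)
    out[block, ] <- t(score_all(Xm, S))
  }
  out
}
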