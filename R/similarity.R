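#' Cell-to-cell similarity over an embedding
#'
#' Similarity between cells is computed over a low-dimensional embedding
#' (multidimensional UMAP components, principal components, or 2D spatial
#' coordinates). The default kernel is the radial basis function
#' \eqn{\exp(-\gamma\,d^2)} of the Euclidean distance \eqn{d} between
#' embedding rows; `gamma` acts as the inverse of the neighbourhood size
#' within which two cells count as similar (larger `gamma`, tighter
#' neighbourhood). Cosine similarity is available as an alternative metric.
#'
#' `gamma` has no universal default because its scale is tied to the
#' embedding's coordinate scale; `gamma = 0.8` is a sensible choice for a
#' multidimensional UMAP embedding, and small values (e.g. 0.001) suit raw
#' 2D spatial coordinates. See [suggest_gamma()] for a data-driven value.
#'
#' @param embedding Numeric matrix, one row per cell, one column per
#'   embedding dimension.
#' @param reference_index Row index (1-based) of the reference cell.
#' @param gamma Positive RBF bandwidth parameter.
#' @return Numeric vector of length `nrow(embedding)`: similarity of every
#'   cell to the reference cell. For the RBF kernel all values are in (0, 1]
#'   and the reference cell's own similarity is exactly 1.
#' @examples
#' emb <- cbind(x = c(0, 2, 4), y = c(0, 0, 0))
#' rbf_similarity(emb, 1, gamma = 0.25)
#' @seealso [pairwise_similarity()] for the batched form,
#'   [select_reference_cells()] for choosing reference cells.
#' @export
rbf_similarity <- function(embedding, reference_index, gamma) {
  check_embedding(embedding)
  i <- check_cell_index(reference_index, nrow(embedding))
  check_gamma(gamma)
  d2 <- rowSums(sweep(embedding, 2L, embedding[i, ], "-")^2)
  v <- exp(-gamma * d2)
  v[i] <- 1
  v
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    validation_error("`gamma` must be a single positive number")
  }
  invisible(gamma)
}

#' @rdname rbf_similarity
#' @export
cosine_similarity <- function(embedding, reference_index) {
  check_embedding(embedding)
  i <- check_cell_index(reference_index, nrow(embedding))
  nrm <- sqrt(rowSums(embedding^2))
  if (nrm[i] == 0) {
    validation_error("reference cell ", i, " has a zero-norm embedding row")
  }
  v <- as.vector(embedding %*% embedding[i, ]) / (nrm * nrm[i])
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm embedding row(s) mapped to similarity 0")
    v[zero] <- 0
  }
  v[i] <- 1
  v
}

#' Similarity of all cells to a set of reference cells
#'
#' Batched form of [rbf_similarity()] / [cosine_similarity()]: column `j` of
#' the result is the similarity vector anchored at `reference_indices[j]`.
#'
#' @inheritParams rbf_similarity
#' @param reference_indices Integer vector of distinct reference cell rows.
#' @param kind `"rbf"` (default) or `"cosine"`.
#' @return Numeric matrix, cells x references. Column names are the
#'   embedding's row names at the reference indices when available.
#' @export
pairwise_similarity <- function(embedding, reference_indices,
                                kind = c("rbf", "cosine"), gamma = NULL) {
  kind <- match.arg(kind)
  check_embedding(embedding)
  idx <- vapply(reference_indices, check_cell_index, integer(1),
                n = nrow(embedding), what = "reference_indices")
  if (anyDuplicated(idx)) {
    validation_error("`reference_indices` contains duplicates")
  }
  if (kind == "rbf") {
    check_gamma(gamma)
    # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clamped against rounding
    sq <- rowSums(embedding^2)
    d2 <- outer(sq, sq[idx], "+") - 2 * embedding %*% t(embedding[idx, , drop = FALSE])
    d2[d2 < 0] <- 0
    s <- exp(-gamma * d2)
    s[cbind(idx, seq_along(idx))] <- 1
  } else {
    s <- vapply(idx, function(i) cosine_similarity(embedding, i),
                numeric(nrow(embedding)))
  }
  s <- matrix(s, nrow = nrow(embedding), ncol = length(idx))
  rownames(s) <- rownames(embedding)
  colnames(s) <- cell_ids_of(embedding)[idx]
  s
}

#' Data-driven RBF bandwidth
#'
#' Returns \eqn{1 / \mathrm{median}(d^2)} over pairwise squared Euclidean
#' distances of (a sample of) embedding rows, a standard kernel-bandwidth
#' heuristic ("median heuristic") that puts typical cell pairs at
#' similarity \eqn{e^{-1}}. Used by the benchmark harness, where the
#' embedding scale is arbitrary.
#'
#' @inheritParams rbf_similarity
#' @param max_cells Cap on rows entering the pairwise computation; rows
#'   beyond it are subsampled under `seed`.
#' @param seed Seed for the subsample (only used when `nrow > max_cells`).
#' @return A single positive `gamma`.
#' @export
suggest_gamma <- function(embedding, max_cells = 1000L, seed = NULL) {
  check_embedding(embedding)
  n <- nrow(embedding)
  if (n > max_cells) {
    keep <- with_seed(seed, sort(sample.int(n, max_cells)))
    embedding <- embedding[keep, , drop = FALSE]
  }
  d2 <- as.vector(stats::dist(embedding))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) {
    validation_error("embedding is degenerate: all rows coincide")
  }
  1 / med
}
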