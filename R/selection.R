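#' Select reference cells by iterative dissimilarity
#'
#' Picks `n` reference cells that are maximally dissimilar to one another,
#' so that scoring neighbourhoods anchored at them covers the population's
#' diversity without clustering. Starting from a seed cell, the algorithm
#' repeatedly (i) computes the similarity of the last selected cell to all
#' cells, (ii) appends the least similar cell still in consideration
#' (ties broken uniformly at random), and (iii) removes the `k` nearest
#' neighbours of the anchor cell from consideration, which prevents the
#' walk from ping-ponging between two extremes of the embedding. Selection
#' stops after `n` cells, or earlier when fewer than `k` candidate cells
#' remain.
#'
#' Dissimilarity is judged against the *last* selected cell only, not
#' against the whole selected set, so this is intentionally not
#' farthest-point sampling.
#'
#' @inheritParams pairwise_similarity
#' @param n Number of reference cells to select (1..N).
#' @param k Number of nearest neighbours of the anchor cell excluded per
#'   iteration. Defaults to [default_k()], `floor(N / n) - 1`, which makes
#'   `n` selections approximately exhaust the sample.
#' @param start Index of the first reference cell, or `"auto"` (default):
#'   the cell nearest the embedding centroid, a deterministic choice.
#' @param seed Seed for random tie-breaking; when `NULL` a seed is drawn
#'   and reported via `message()` so the run can be reproduced.
#' @return A `reference_set`: list with `indices` (ordered selected rows,
#'   `indices[1]` is the start cell), `cell_ids`, `method = "algorithm"`,
#'   and `params`.
#' @examples
#' set.seed(1)
#' emb <- matrix(rnorm(200), ncol = 2)
#' select_reference_cells(emb, n = 5, gamma = 1, seed = 42)
#' @export
select_reference_cells <- function(embedding, n, kind = c("rbf", "cosine"),
                                   gamma = NULL, k = NULL, start = "auto",
                                   seed = NULL) {
  kind <- match.arg(kind)
  check_embedding(embedding)
  if (kind == "rbf") check_gamma(gamma)
  N <- nrow(embedding)
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > N) {
    validation_error("`n` must be in [1, ", N, "] (got ", n, ")")
  }
  n <- as.integer(n)
  if (is.null(k)) k <- default_k(N, n)
  if (k < 0 || k != as.integer(k)) validation_error("`k` must be a nonnegative integer")
  k <- as.integer(k)
  if (identical(start, "auto")) {
    centroid <- colMeans(embedding)
    start <- which.min(rowSums(sweep(embedding, 2L, centroid, "-")^2))
  }
  start <- check_cell_index(start, N, "start")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("select_reference_cells: using generated seed ", seed)
  }

  sim_to <- function(i) {
    if (kind == "rbf") rbf_similarity(embedding, i, gamma)
    else cosine_similarity(embedding, i)
  }

  selected <- start
  remaining <- setdiff(seq_len(N), start)
  with_seed(seed, {
    while (length(selected) < n) {
      if (length(remaining) == 0L || length(remaining) < k) break
      anchor <- selected[length(selected)]
      sims <- sim_to(anchor)
      simr <- sims[remaining]
      ties <- remaining[simr == min(simr)]
      pick <- sample_one(ties)
      selected <- c(selected, pick)
      remaining <- remaining[remaining != pick]
      if (k > 0L && length(remaining) > 0L) {
        # k nearest neighbours of the anchor, by the same similarity vector
        ord <- remaining[order(sims[remaining], decreasing = TRUE)]
        remaining <- setdiff(remaining, ord[seq_len(min(k, length(ord)))])
      }
    }
  })
  if (length(selected) < n) {
    warning("stopped after ", length(selected), " of ", n,
            " selections: fewer than k = ", k, " candidate cells remained")
  }
  new_reference_set(selected, cell_ids_of(embedding)[selected],
                    method = "algorithm",
                    params = list(n = n, k = k, start = start, seed = seed,
                                  kind = kind, gamma = gamma))
}

#' Default per-iteration exclusion count for reference cell selection
#'
#' `k = max(0, floor(N / n) - 1)`: excluding `k` neighbours plus the
#' selected cell at each of `n` iterations approximately exhausts the `N`
#' cells, so the selected set spreads over the whole sample.
#'
#' @param N Total number of cells.
#' @param n Number of cells to select.
#' @return A nonnegative integer.
#' @export
default_k <- function(N, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    validation_error("`n` must be a positive integer")
  }
  if (!is.numeric(N) || length(N) != 1L || N < n) {
    validation_error("`N` must be >= n")
  }
  max(0L, as.integer(N %/% n) - 1L)
}

#' Select reference cells at the lattice points of a 2D grid
#'
#' For 2D coordinates (spatial transcriptomics spots, 2D embeddings) a
#' fixed rectangular grid is often preferable to the data-driven walk.
#' Lattice points are placed uniformly over the bounding box of the
#' coordinates (corners included) and visited in row-major order; each
#' lattice point contributes the cell nearest to it, unless that cell was
#' already selected or lies within `d` of a previously selected cell,
#' where `d = min_dist_frac * (grid-cell diagonal)`. The minimum-distance
#' rule prevents over-selection of cells at the embedding's edge.
#'
#' @param coords Numeric matrix with exactly 2 columns, one row per cell.
#' @param grid_shape Integer vector `c(rows, cols)` of lattice dimensions.
#' @param min_dist_frac Minimum pairwise distance between selected cells,
#'   as a fraction of the grid-cell diagonal (default 0.2).
#' @return A `reference_set` with `method = "grid"`.
#' @export
grid_select <- function(coords, grid_shape, min_dist_frac = 0.2) {
  check_embedding(coords, min_rows = 1L)
  if (ncol(coords) != 2L) validation_error("`coords` must have exactly 2 columns")
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    validation_error("`grid_shape` must be c(rows, cols), both >= 1")
  }
  if (!is.numeric(min_dist_frac) || min_dist_frac < 0) {
    validation_error("`min_dist_frac` must be >= 0")
  }
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  if (diff(rx) == 0 && diff(ry) == 0) {
    warning("all coordinates coincide; selecting a single cell")
    return(new_reference_set(1L, cell_ids_of(coords)[1L], "grid",
                             list(grid_shape = c(rows, cols),
                                  min_dist_frac = min_dist_frac)))
  }
  gx <- if (cols == 1L) mean(rx) else seq(rx[1], rx[2], length.out = cols)
  gy <- if (rows == 1L) mean(ry) else seq(ry[1], ry[2], length.out = rows)
  cw <- diff(rx) / max(cols - 1L, 1L)
  ch <- diff(ry) / max(rows - 1L, 1L)
  d <- min_dist_frac * sqrt(cw^2 + ch^2)

  selected <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      nearest <- which.min((coords[, 1] - gx[c])^2 + (coords[, 2] - gy[r])^2)
      if (nearest %in% selected) next
      if (length(selected) > 0 && d > 0) {
        dmin <- sqrt(min(rowSums(
          sweep(coords[selected, , drop = FALSE], 2L, coords[nearest, ], "-")^2
        )))
        if (dmin < d) next
      }
      selected <- c(selected, nearest)
    }
  }
  new_reference_set(selected, cell_ids_of(coords)[selected], "grid",
                    list(grid_shape = c(rows, cols),
                         min_dist_frac = min_dist_frac, d = d))
}

new_reference_set <- function(indices, cell_ids, method, params) {
  structure(
    list(indices = as.integer(indices), cell_ids = cell_ids,
         method = method, params = params),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", length(x$indices), " cells, method = ",
      x$method, "\n", sep = "")
  cat("indices:", utils::head(x$indices, 10L),
      if (length(x$indices) > 10L) "...", "\n")
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$indices)
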