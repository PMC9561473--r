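# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Signal a validation error (bad user input, caught by the CLI as exit 2).
validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("fm_validation_error", "error")))
}

is_validation_error <- function(e) inherits(e, "fm_validation_error")

# Run `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL runs on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    validation_error("`seed` must be a single finite number")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate a cells x d embedding matrix.
check_embedding <- function(embedding, min_rows = 2L) {
  if (!is.matrix(embedding) || !is.numeric(embedding)) {
    validation_error("`embedding` must be a numeric matrix (cells x dimensions)")
  }
  if (ncol(embedding) < 1L || nrow(embedding) < min_rows) {
    validation_error(
      "`embedding` needs at least 1 column and ", min_rows, " rows"
    )
  }
  if (!all(is.finite(embedding))) {
    validation_error("`embedding` contains non-finite values")
  }
  invisible(embedding)
}

check_cell_index <- function(i, n, what = "reference_index") {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) ||
      i != as.integer(i) || i < 1L || i > n) {
    stop("`", what, "` must be a single integer in [1, ", n, "]")
  }
  as.integer(i)
}

# Cell ids for a matrix, synthesizing "cell_<i>" when rownames are absent.
cell_ids_of <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(x)))
  ids
}

feature_ids_of <- function(x) {
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(ncol(x)))
  ids
}

# Uniform pick from a vector of candidates (safe for length 1).
sample_one <- function(x) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L)]
}
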