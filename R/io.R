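#' Read a cell-by-feature matrix
#'
#' Reads Matrix Market triplets (with `features.tsv` / `barcodes.tsv`
#' sidecar lists, the 10x convention) or delimited text. Orientation is
#' explicit because dumps differ: MTX defaults to cells-as-columns (10x),
#' delimited text to cells-as-rows. The returned matrix is always
#' cells x features, sparse storage preserved for MTX, with cell ids as
#' rownames and feature ids as colnames. Delimited matrices must carry a
#' header row of feature ids and a first column of cell ids.
#'
#' @param path Path to a `.mtx`, `.tsv` or `.csv` file.
#' @param format `"auto"` (from the extension), `"mtx"`, `"tsv"` or
#'   `"csv"`.
#' @param cells_as `"rows"` or `"cols"`; `NULL` picks the format default.
#' @return Cells x features matrix (a `dgCMatrix` for MTX, a base matrix
#'   otherwise).
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                        cells_as = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", tsv = "tsv", txt = "tsv", csv = "csv",
                     validation_error("cannot infer format of ", path))
  }
  if (format == "mtx") {
    if (is.null(cells_as)) cells_as <- "cols"
    bad <- function(e) {
      validation_error(path, " is not valid Matrix Market: ",
                       conditionMessage(e))
    }
    # readMM only warns on truncated triplet lists; treat that as fatal too
    m <- tryCatch(methods::as(Matrix::readMM(path), "CsparseMatrix"),
                  error = bad, warning = bad)
    features <- read_sidecar(path, "features.tsv")
    barcodes <- read_sidecar(path, "barcodes.tsv")
    if (cells_as == "cols") {
      check_sidecar_len(features, nrow(m), path, "features.tsv")
      check_sidecar_len(barcodes, ncol(m), path, "barcodes.tsv")
      m <- Matrix::t(m)
    } else {
      check_sidecar_len(features, ncol(m), path, "features.tsv")
      check_sidecar_len(barcodes, nrow(m), path, "barcodes.tsv")
    }
    dimnames(m) <- list(barcodes, features)
  } else {
    if (is.null(cells_as)) cells_as <- "rows"
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) validation_error(path, ": matrix body is not numeric")
    if (cells_as == "cols") m <- t(m)
  }
  if (anyDuplicated(colnames(m))) {
    validation_error(path, ": duplicate feature ids")
  }
  vals <- matrix_values(m)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    validation_error(path, ": values must be finite and nonnegative")
  }
  m
}

matrix_values <- function(m) if (inherits(m, "sparseMatrix")) m@x else m

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sidecar of an MTX file: `<prefix>features.tsv` next to `<prefix>matrix.mtx`,
# or a bare `features.tsv` in the same directory.
read_sidecar <- function(mtx_path, name) {
  pre <- sub("matrix\\.mtx$", "", basename(mtx_path))
  if (identical(pre, basename(mtx_path))) pre <- ""
  candidates <- unique(file.path(dirname(mtx_path), c(paste0(pre, name), name)))
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) {
    validation_error("missing sidecar for ", mtx_path, ": expected ",
                     candidates[1])
  }
  ids <- utils::read.table(hit[1], header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[[1]]
  as.character(ids)
}

check_sidecar_len <- function(ids, expected, mtx_path, name) {
  if (length(ids) != expected) {
    validation_error(name, " for ", mtx_path, " lists ", length(ids),
                     " ids but the matrix has ", expected)
  }
}

#' Write a cell-by-feature matrix
#'
#' Inverse of [read_matrix()]: `"mtx"` writes Matrix Market triplets with
#' `features.tsv` / `barcodes.tsv` sidecars (cells as columns, 10x
#' convention); `"tsv"`/`"csv"` write a dense table with feature-id header
#' and cell-id first column (cells as rows).
#'
#' @param m Cells x features matrix.
#' @param path Output path.
#' @param format `"auto"`, `"mtx"`, `"tsv"` or `"csv"`.
#' @export
write_matrix <- function(m, path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", tsv = "tsv", csv = "csv",
                     validation_error("cannot infer format of ", path))
  }
  if (format == "mtx") {
    sp <- methods::as(methods::as(Matrix::t(m), "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(sp, path)
    pre <- sub("matrix\\.mtx$", "", basename(path))
    if (identical(pre, basename(path))) pre <- ""
    dir <- dirname(path)
    writeLines(feature_ids_of(m), file.path(dir, paste0(pre, "features.tsv")))
    writeLines(cell_ids_of(m), file.path(dir, paste0(pre, "barcodes.tsv")))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(as.matrix(m))
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       col.names = NA, row.names = TRUE)
  }
  invisible(path)
}

#' Read a cell embedding from headerless delimited text
#'
#' One row per cell, one column per dimension; the separator (tab, comma
#' or whitespace) is inferred from the first line.
#'
#' @param path Path to the text file.
#' @return Numeric matrix, cells x dimensions.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  if (!is.numeric(m) || !all(is.finite(m))) {
    validation_error(path, ": embedding must be numeric and finite")
  }
  dimnames(m) <- NULL
  m
}

#' Term frequency-inverse document frequency transform
#'
#' The single-cell tf-idf dialect used to weight accessibility (or count)
#' matrices before embedding: term frequency is the within-cell proportion
#' `tf[i, j] = x[i, j] / rowSum(i)`, inverse document frequency is
#' `idf[j] = ln(1 + N / df_j)` with `df_j` the number of cells detecting
#' feature `j`, and the output is their product. Features detected nowhere
#' get idf 0 by convention (their column stays all-zero). With
#' `binarize = TRUE` the matrix is first thresholded at `x > 0`, the usual
#' treatment of scATAC-seq accessibility.
#'
#' @param X Cells x features matrix, nonnegative; every cell must have a
#'   positive total.
#' @param binarize Replace values by detection indicators first
#'   (default `FALSE`).
#' @return Transformed matrix of the same shape and storage kind.
#' @export
tfidf_transform <- function(X, binarize = FALSE) {
  if (any(matrix_values(X) < 0)) validation_error("`X` must be nonnegative")
  if (binarize) {
    if (inherits(X, "sparseMatrix")) X@x[] <- as.numeric(X@x > 0) else X[] <- as.numeric(X > 0)
  }
  rs <- Matrix::rowSums(X)
  if (any(rs == 0)) {
    validation_error(sum(rs == 0), " cell(s) have all-zero rows; tf is undefined")
  }
  df <- Matrix::colSums(X > 0)
  idf <- ifelse(df == 0, 0, log(1 + nrow(X) / df))
  if (inherits(X, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = 1 / rs) %*% X %*% Matrix::Diagonal(x = idf)
    out <- methods::as(out, "CsparseMatrix")
    dimnames(out) <- dimnames(X)
  } else {
    out <- (X / rs) * rep(idf, each = nrow(X))
  }
  out
}

#' Write a result table deterministically
#'
#' Writes significance tables, global rankings, annotations, enrichment
#' matrices or reference sets as TSV with a header line, deterministic row
#' order (feature id, then reference cell id, as applicable) and floats
#' rendered with 6 significant digits, so equal inputs always produce
#' byte-identical files.
#'
#' @param x The object to serialize.
#' @param path Output path.
#' @export
write_results <- function(x, path) {
  UseMethod("write_results")
}

fmt_num <- function(v) {
  if (is.double(v)) formatC(v, digits = 6, format = "g") else v
}

write_tsv_formatted <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.significance_table <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[order(df$feature_id, df$reference_cell_id), , drop = FALSE]
  write_tsv_formatted(df, path)
}

#' @export
write_results.global_ranking <- function(x, path) {
  write_tsv_formatted(as.data.frame(x), path)
}

#' @export
write_results.reference_set <- function(x, path) {
  write_tsv_formatted(
    data.frame(rank = seq_along(x$indices), cell_id = x$cell_ids,
               index = x$indices, stringsAsFactors = FALSE),
    path
  )
}

#' @export
write_results.matrix <- function(x, path) {
  # enrichment matrix: features x references with ids
  df <- data.frame(feature_id = feature_row_ids(x), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x, optional = TRUE))
  colnames(df) <- c("feature_id", colnames(x) %||% paste0("ref_", seq_len(ncol(x))))
  df <- df[order(df$feature_id), , drop = FALSE]
  write_tsv_formatted(df, path)
}

feature_row_ids <- function(x) {
  if (is.null(rownames(x))) paste0("feature_", seq_len(nrow(x))) else rownames(x)
}

#' @export
write_results.data.frame <- function(x, path) {
  ord <- intersect(c("feature_id", "reference_cell_id", "cell_id"), names(x))
  if (length(ord) > 0) x <- x[do.call(order, x[ord]), , drop = FALSE]
  write_tsv_formatted(x, path)
}

#' Read a plain-text marker list
#'
#' One feature id per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the list.
#' @return Character vector of feature ids.
#' @export
read_marker_list <- function(path) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# Flat key=value config files; later sources win.
read_config <- function(path) {
  if (!file.exists(path)) validation_error("config not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) validation_error("config line not key=value: ", lines[bad][1])
  stats::setNames(as.list(trimws(vapply(kv, `[`, "", 3L))),
                  trimws(vapply(kv, `[`, "", 2L)))
}
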