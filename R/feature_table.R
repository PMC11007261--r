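# Feature tables are plain integer matrices, samples as rows and taxa as
# columns, with unique dimnames. Keeping the base-matrix representation (as
# vegan does) lets every downstream step use ordinary indexing.

#' Validate a feature table
#'
#' Checks the invariants of an amplicon feature table: a numeric matrix of
#' non-negative integer counts with unique sample (row) and taxon (column)
#' identifiers and at least one positive count per sample.
#'
#' @param x Matrix, samples as rows, taxa as columns, with dimnames.
#' @return `x`, invisibly, with counts stored as integer-valued numerics.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    ps_stop("feature table must be a numeric matrix", "format_error")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    ps_stop("feature table must have sample row names and taxon column names",
            "format_error")
  if (anyDuplicated(rownames(x)))
    ps_stop("duplicate sample identifiers in feature table", "format_error")
  if (anyDuplicated(colnames(x)))
    ps_stop("duplicate taxon identifiers in feature table", "format_error")
  if (anyNA(x))
    ps_stop("feature table contains missing values", "format_error")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    ps_stop(sprintf("negative count at sample '%s', taxon '%s'",
                    rownames(x)[bad[1]], colnames(x)[bad[2]]), "format_error")
  }
  if (any(abs(x - round(x)) > 1e-9)) {
    bad <- which(abs(x - round(x)) > 1e-9, arr.ind = TRUE)[1, ]
    ps_stop(sprintf("non-integer count %.6g at sample '%s', taxon '%s'",
                    x[bad[1], bad[2]], rownames(x)[bad[1]],
                    colnames(x)[bad[2]]), "format_error")
  }
  if (any(rowSums(x) == 0))
    ps_stop(sprintf("sample(s) with no reads: %s",
                    paste(rownames(x)[rowSums(x) == 0], collapse = ", ")),
            "format_error")
  invisible(round(x))
}

#' Read a feature table from disk
#'
#' Reads a tab-separated (or BIOM-style dense TSV, which is the same layout
#' with taxa as rows) samples-by-taxa count matrix. The first column holds
#' row identifiers and the header holds column identifiers.
#'
#' @param path File path.
#' @param dialect `"tsv"` (samples as rows) or `"biom_dense"` (taxa as rows,
#'   as in BIOM dense exports; the matrix is transposed on read).
#' @param orientation Override the dialect's orientation: one of
#'   `"samples_rows"` or `"taxa_rows"`.
#' @return Validated integer matrix, samples as rows.
#' @export
read_feature_table <- function(path, dialect = c("tsv", "biom_dense"),
                               orientation = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ps_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      ps_stop(sprintf("non-numeric cell at row '%s', column '%s'",
                      ids[bad], names(body)[j]), "format_error")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  taxa_rows <- identical(dialect, "biom_dense")
  if (!is.null(orientation))
    taxa_rows <- match.arg(orientation, c("samples_rows", "taxa_rows")) ==
      "taxa_rows"
  if (taxa_rows) m <- t(m)
  validate_feature_table(m)
}

#' Write a feature table as tab-separated text
#'
#' @param x Feature table (samples as rows).
#' @param path Output path.
#' @param id_column Name for the leading identifier column.
#' @export
write_feature_table <- function(x, path, id_column = "sample_id") {
  x <- validate_feature_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param x Feature table; rows with positive totals are divided by their
#'   total so each row sums to 1.
#' @return Numeric matrix of per-sample proportions.
#' @export
relative_abundance <- function(x) {
  tot <- rowSums(x)
  if (any(tot == 0))
    ps_stop("cannot normalize sample(s) with zero total", "format_error")
  sweep(x, 1, tot, "/")
}
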