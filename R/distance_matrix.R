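# Distance matrices are full symmetric numeric matrices with dimnames; the
# labelled-matrix form (rather than `dist`) keeps label alignment explicit
# across the diversity, covariate and inference stages.

#' Validate a labelled distance matrix
#'
#' @param x Square numeric matrix with identical row/column labels.
#' @param tol Symmetry tolerance.
#' @return `x` invisibly.
#' @export
validate_distance_matrix <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x))
    ps_stop("distance matrix must be a square numeric matrix",
            "validation_error")
  if (is.null(rownames(x)) || !identical(rownames(x), colnames(x)))
    ps_stop("distance matrix must carry identical row and column labels",
            "validation_error")
  if (anyDuplicated(rownames(x)))
    ps_stop("duplicate labels in distance matrix", "validation_error")
  if (max(abs(x - t(x))) > tol)
    ps_stop(sprintf("asymmetric distance matrix (max |d_ij - d_ji| = %.3g)",
                    max(abs(x - t(x)))), "validation_error")
  if (any(abs(diag(x)) > tol))
    ps_stop("distance matrix diagonal must be zero", "validation_error")
  if (any(x < -tol))
    ps_stop("negative entries in distance matrix", "validation_error")
  invisible(x)
}

# Symmetrize and zero the diagonal of an almost-valid matrix.
dm_canonical <- function(x) {
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x
}

#' Build a labelled distance matrix from a `dist` or matrix
#'
#' @param d `dist` object or square matrix.
#' @param labels Optional labels to attach (required if `d` carries none).
#' @return Validated labelled matrix.
#' @export
as_distance_matrix <- function(d, labels = NULL) {
  m <- as.matrix(d)
  if (!is.null(labels)) rownames(m) <- colnames(m) <- labels
  m <- dm_canonical(m)
  validate_distance_matrix(m)
  m
}

#' Write / read a labelled square distance matrix as TSV
#'
#' Round-trips at full double precision (within 1e-12).
#'
#' @param dm Validated distance matrix.
#' @param path File path.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(label = rownames(dm), format(dm, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param labels Optional label order to return; entries are permuted
#'   consistently.
#' @export
read_distance_matrix <- function(path, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
  if (!is.null(labels)) {
    missing <- setdiff(labels, rownames(m))
    if (length(missing))
      ps_stop(sprintf("labels absent from matrix: %s",
                      paste(missing, collapse = ", ")), "alignment_error")
    m <- m[labels, labels]
  }
  m
}

# Align a named list of distance matrices to a common label order.
align_matrices <- function(mats, labels = NULL) {
  if (is.null(labels)) labels <- rownames(mats[[1]])
  lapply(mats, function(m) {
    missing <- setdiff(labels, rownames(m))
    if (length(missing))
      ps_stop(sprintf("distance matrix lacks labels: %s",
                      paste(missing, collapse = ", ")), "alignment_error")
    m[labels, labels]
  })
}

# Unfold the strict lower triangle of a labelled matrix into a vector,
# column-major: the common currency of Mantel/MRM statistics.
lower_triangle <- function(m) m[lower.tri(m)]
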