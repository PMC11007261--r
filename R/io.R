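# Newick, metadata and FASTA readers. Trees are ape "phylo" objects
# throughout; metadata is a plain data.frame with one row per sample.

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that fails loudly on malformed
#' input and zero-fills missing branch lengths (with a warning) so that
#' downstream branch-length arithmetic never sees `NA`.
#'
#' @param path Path to a newick file (or a literal newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path))
      ps_stop(sprintf("file not found: %s", path), "io_error")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes)
    ps_stop(sprintf(
      "unbalanced parentheses in newick (%d '(' vs %d ')') near offset %d",
      opens, closes, nchar(text)), "parse_error")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    ps_stop("newick parse failure", "parse_error")
  if (is.null(tr$edge.length)) {
    ps_warn("newick has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    ps_warn("missing branch lengths in newick; defaulting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (anyDuplicated(tr$tip.label))
    ps_stop("duplicate leaf labels in tree", "format_error")
  if (any(tr$edge.length < 0))
    ps_stop("negative branch lengths in tree", "format_error")
  tr
}

#' Read sample metadata
#'
#' Tab-separated metadata with required columns `sample_id`, `population`,
#' `species`, `latitude`, `longitude`, `altitude`, `host_plant`. Unknown
#' columns are preserved.
#'
#' @param path File path.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "population", "species", "latitude", "longitude",
                "altitude", "host_plant")
  missing <- setdiff(required, names(df))
  if (length(missing))
    ps_stop(sprintf("metadata lacks required column(s): %s",
                    paste(missing, collapse = ", ")), "schema_error")
  validate_metadata(df)
}

#' Validate sample metadata
#'
#' @param df Metadata data.frame (see [read_metadata()]).
#' @return `df` with numeric coordinate/altitude columns.
#' @export
validate_metadata <- function(df) {
  for (col in c("latitude", "longitude", "altitude")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      ps_stop(sprintf("non-numeric %s at row %d", col, which(is.na(v))[1]),
              "parse_error")
    df[[col]] <- v
  }
  if (anyDuplicated(df$sample_id))
    ps_stop("duplicate sample_id in metadata", "schema_error")
  if (any(df$latitude < -90 | df$latitude > 90))
    ps_stop(sprintf("latitude out of [-90, 90] at row %d",
                    which(df$latitude < -90 | df$latitude > 90)[1]),
            "range_error")
  if (any(df$longitude < -180 | df$longitude > 180))
    ps_stop(sprintf("longitude out of [-180, 180] at row %d",
                    which(df$longitude < -180 | df$longitude > 180)[1]),
            "range_error")
  df
}

#' Write sample metadata as TSV
#' @param df Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file into a character matrix
#'
#' @param path FASTA path; all sequences must share one length.
#' @return Character matrix (sequences as rows, sites as columns) over
#'   `A, C, G, T, -, N` in upper case.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  lens <- lengths(as.character(dna))
  if (length(unique(lens)) != 1)
    ps_stop("sequences differ in length; not an alignment", "format_error")
  rownames(mat) <- names(dna)
  if (anyDuplicated(rownames(mat)))
    ps_stop("duplicate sequence labels", "format_error")
  mat
}
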