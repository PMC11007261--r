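# Explanatory distance matrices: host genetic (K2P + gamma), great-circle
# geographic, Gower (host plant, altitude), Euclidean on alpha diversity,
# and population-to-sample expansion.

# Transition/transversion proportions for one sequence pair with pairwise
# deletion of gaps/ambiguities.
k2p_pq <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) ps_stop("no comparable sites in sequence pair", "format_error")
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (purine[a] == purine[b])   # A<->G or C<->T
  c(P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura two-parameter distance, optionally gamma-corrected
#'
#' Without gamma: \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) -
#' \frac{1}{4}\ln(1 - 2Q)} with P/Q the transition/transversion
#' proportions. With gamma shape \eqn{a} (Jin-Nei rate-heterogeneity
#' correction): \eqn{d = \frac{a}{2}[(1-2P-Q)^{-1/a} - 1] +
#' \frac{a}{4}[(1-2Q)^{-1/a} - 1]}.
#'
#' @param aln Character matrix from [read_alignment()] (sequences as rows),
#'   or any object coercible to one.
#' @param gamma_shape Positive gamma shape, or `NULL` for no correction.
#' @return Labelled distance matrix. Saturated pairs (where
#'   \eqn{1 - 2P - Q \le 0} or \eqn{1 - 2Q \le 0}) raise a saturation error
#'   naming the pair.
#' @export
k2p_distance <- function(aln, gamma_shape = NULL) {
  if (!is.matrix(aln)) aln <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(aln)
  if (n < 2) ps_stop("need >= 2 sequences", "config_error")
  labs <- rownames(aln)
  out <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pq <- k2p_pq(aln[i, ], aln[j, ])
    out[i, j] <- out[j, i] <- k2p_from_pq(pq["P"], pq["Q"], gamma_shape,
                                          pair = paste(labs[i], labs[j]))
  }
  validate_distance_matrix(out)
  out
}

#' @rdname k2p_distance
#' @param P,Q Transition and transversion proportions.
#' @param pair Label used in saturation error messages.
#' @export
k2p_from_pq <- function(P, Q, gamma_shape = NULL, pair = "") {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    ps_stop(sprintf("saturated K2P pair %s (P=%.3f, Q=%.3f)", pair, P, Q),
            "saturation_error")
  if (is.null(gamma_shape))
    -0.5 * log(w1) - 0.25 * log(w2)
  else {
    a <- gamma_shape
    (a / 2) * (w1^(-1 / a) - 1) + (a / 4) * (w2^(-1 / a) - 1)
  }
}

#' Great-circle geographic distance matrix
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param metadata data.frame with `latitude`/`longitude` (degrees) and
#'   either `sample_id` or `population` labels.
#' @param labels_from Column supplying the matrix labels.
#' @return Labelled distance matrix in kilometers.
#' @export
great_circle_matrix <- function(metadata, labels_from = "sample_id") {
  metadata <- validate_metadata_coords(metadata)
  labs <- metadata[[labels_from]]
  xy <- cbind(metadata$longitude, metadata$latitude)
  n <- nrow(xy)
  out <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[(i + 1):n, , drop = FALSE],
                                  r = 6371008.8) / 1000
    out[i, (i + 1):n] <- out[(i + 1):n, i] <- d
  }
  out
}

validate_metadata_coords <- function(df) {
  if (any(df$latitude < -90 | df$latitude > 90) ||
      any(df$longitude < -180 | df$longitude > 180))
    ps_stop("coordinates out of range", "range_error")
  df
}

#' Gower distance from one covariate column
#'
#' Numeric columns give range-normalized \eqn{|x - y| / \mathrm{range}}
#' (an all-equal column yields the all-zero matrix); categorical columns
#' give 0/1 mismatch.
#'
#' @param values Named vector (names become labels).
#' @return Labelled distance matrix in `[0, 1]`.
#' @export
gower_matrix <- function(values) {
  if (length(values) < 2) ps_stop("need >= 2 entities", "config_error")
  labs <- names(values)
  if (is.numeric(values)) {
    rng <- diff(range(values))
    m <- as.matrix(stats::dist(values, method = "manhattan"))
    if (rng > 0) m <- m / rng
  } else if (is.character(values) || is.factor(values)) {
    v <- as.character(values)
    m <- outer(v, v, FUN = "!=") * 1
  } else ps_stop("values must be numeric or categorical", "type_error")
  dimnames(m) <- list(labs, labs)
  dm_canonical(m)
}

#' Euclidean distance matrix from per-sample alpha diversity
#'
#' One-dimensional Euclidean distance \eqn{|a_i - a_j|}.
#'
#' @param alpha_values Named numeric vector of finite values.
#' @return Labelled distance matrix.
#' @export
alpha_euclidean <- function(alpha_values) {
  if (anyNA(alpha_values) || any(!is.finite(alpha_values)))
    ps_stop("alpha values must be finite", "coverage_error")
  m <- as.matrix(stats::dist(alpha_values))
  dimnames(m) <- list(names(alpha_values), names(alpha_values))
  m
}

#' Expand a population-level distance matrix to sample level
#'
#' \eqn{d(s, t)} = distance between the samples' populations; 0 for
#' same-population pairs.
#'
#' @param population_dm Labelled distance matrix over populations.
#' @param mapping Named character vector: sample id -> population.
#' @return Labelled distance matrix over samples.
#' @export
expand_to_samples <- function(population_dm, mapping) {
  missing <- setdiff(unique(mapping), rownames(population_dm))
  if (length(missing))
    ps_stop(sprintf("population(s) absent from matrix: %s",
                    paste(missing, collapse = ", ")), "coverage_error")
  m <- population_dm[mapping, mapping]
  dimnames(m) <- list(names(mapping), names(mapping))
  m
}

#' Build the four explanatory distance matrices for a sample set
#'
#' Genetics from a host tree's patristic distances (or a supplied
#' population matrix), expanded to samples; great-circle geography;
#' Gower altitude; Gower host plant. All aligned to the metadata's sample
#' order.
#'
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param host_tree Host `phylo` over populations (used when
#'   `genetics_dm` is NULL).
#' @param genetics_dm Optional precomputed population-level genetic
#'   distance matrix.
#' @return Named list of sample-level distance matrices:
#'   `genetics`, `geography`, `altitude`, `host_plant`.
#' @export
covariate_set <- function(metadata, host_tree = NULL, genetics_dm = NULL) {
  mapping <- stats::setNames(metadata$population, metadata$sample_id)
  if (is.null(genetics_dm)) {
    if (is.null(host_tree))
      ps_stop("need host_tree or genetics_dm", "config_error")
    genetics_dm <- ape::cophenetic.phylo(host_tree)
  }
  list(
    genetics = expand_to_samples(genetics_dm, mapping),
    geography = great_circle_matrix(metadata, labels_from = "sample_id"),
    altitude = gower_matrix(stats::setNames(metadata$altitude,
                                            metadata$sample_id)),
    host_plant = gower_matrix(stats::setNames(metadata$host_plant,
                                              metadata$sample_id)))
}
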