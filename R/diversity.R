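# Rarefaction, alpha diversity, taxonomy-based and phylogenetic beta
# diversity, and PCoA ordination.

#' Rarefy a feature table to even depth
#'
#' Each retained sample is a uniform subsample of its reads without
#' replacement, summing exactly to `depth`. Samples whose total is below
#' `depth` are dropped with a message; a sample at exactly `depth` is
#' returned unchanged.
#'
#' @param table Feature table (samples x taxa counts).
#' @param depth Target depth (>= 1).
#' @param seed RNG seed.
#' @param prune_zero_taxa Drop taxa with all-zero columns after rarefaction.
#' @return Rarefied feature table.
#' @export
rarefy <- function(table, depth, seed = 1L, prune_zero_taxa = FALSE) {
  if (depth <= 0) ps_stop("rarefaction depth must be positive", "config_error")
  table <- validate_feature_table(table)
  keep <- rowSums(table) >= depth
  if (!any(keep))
    ps_stop(sprintf("no sample reaches depth %d", depth), "empty_table_error")
  if (any(!keep))
    message(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(table)[!keep], collapse = ", ")))
  out <- with_seed(seed, vegan::rrarefy(table[keep, , drop = FALSE], depth))
  if (prune_zero_taxa) out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Alpha diversity of one sample
#'
#' Metrics: `observed` species richness; `chao1` (classic
#' \eqn{S + F_1^2 / (2 F_2)}, falling back to the bias-corrected
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} when no doubletons, or
#' bias-corrected throughout via `chao1_variant`); `shannon`
#' \eqn{-\sum p_i \log_2 p_i} (base 2 by default, the amplicon-platform
#' convention); `simpson` \eqn{1 - \sum p_i^2}; `goods_coverage`
#' \eqn{1 - F_1 / N}.
#'
#' @param counts Non-negative integer count vector with >= 1 positive entry.
#' @param metric One of `observed`, `chao1`, `shannon`, `simpson`,
#'   `goods_coverage`.
#' @param base Logarithm base for Shannon.
#' @param chao1_variant `"classic"` or `"bias_corrected"`.
#' @return A single finite value.
#' @export
alpha <- function(counts, metric = c("observed", "chao1", "shannon",
                                     "simpson", "goods_coverage"),
                  base = 2, chao1_variant = c("classic", "bias_corrected")) {
  metric <- match.arg(metric)
  chao1_variant <- match.arg(chao1_variant)
  if (any(counts < 0) || all(counts == 0))
    ps_stop("counts must be non-negative with at least one positive entry",
            "undefined_metric_error")
  x <- counts[counts > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  p <- x / sum(x)
  switch(metric,
    observed = s_obs,
    chao1 = if (chao1_variant == "classic" && f2 > 0)
      s_obs + f1^2 / (2 * f2)
    else
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
    shannon = -sum(p * log(p, base = base)),
    simpson = 1 - sum(p^2),
    goods_coverage = 1 - f1 / sum(x)
  )
}

#' Alpha diversity for every sample of a table
#'
#' @param table Feature table.
#' @param metrics Character vector of metric names (see [alpha()]).
#' @inheritParams alpha
#' @return data.frame with `sample_id` and one column per metric.
#' @export
alpha_table <- function(table, metrics = c("observed", "chao1", "shannon",
                                           "simpson", "goods_coverage"),
                        base = 2, chao1_variant = "classic") {
  out <- data.frame(sample_id = rownames(table), stringsAsFactors = FALSE)
  for (m in metrics)
    out[[m]] <- apply(table, 1, alpha, metric = m, base = base,
                      chao1_variant = chao1_variant)
  out
}

# Edge x taxon descendant incidence of a rooted/unrooted phylo, plus branch
# lengths, restricted and ordered to `taxa`. The workhorse for UniFrac.
edge_taxon_incidence <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    ps_stop(sprintf("table taxa missing from tree: %s",
                    paste(missing, collapse = ", ")), "mapping_error")
  if (length(setdiff(tree$tip.label, taxa)))
    tree <- ape::keep.tip(tree, taxa)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  inc <- matrix(FALSE, nnode, ntip,
                dimnames = list(NULL, tr$tip.label))
  inc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    inc[par, ] <- inc[par, ] | inc[chi, ]
  }
  list(inc = inc[tr$edge[, 2], taxa, drop = FALSE],
       len = tr$edge.length)
}

# UniFrac distances over all samples at once.
unifrac_matrix <- function(table, tree, weighted, normalized = FALSE) {
  ei <- edge_taxon_incidence(tree, colnames(table))
  D <- ei$inc * 1        # edges x taxa
  len <- ei$len
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  if (weighted) {
    ra <- relative_abundance(table)
    P <- D %*% t(ra)                          # edges x samples
    tipdepth <- drop(t(D) %*% len)            # root-to-tip path lengths
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sum(len * abs(P[, i] - P[, j]))
      if (normalized) {
        denom <- sum(tipdepth * (ra[i, ] + ra[j, ]))
        d <- if (denom > 0) d / denom else 0
      }
      out[i, j] <- out[j, i] <- d
    }
  } else {
    B <- (D %*% t((table > 0) * 1)) > 0       # edge has observed descendant
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- B[, i] | B[, j]
      uniq <- xor(B[, i], B[, j])
      denom <- sum(len[either])
      out[i, j] <- out[j, i] <- if (denom > 0) sum(len[uniq]) / denom else 0
    }
  }
  out
}

#' Beta diversity distance matrix
#'
#' `jaccard` (presence/absence, \eqn{1 - |A \cap B| / |A \cup B|}) and
#' `bray_curtis` are taxonomy-based; `unweighted_unifrac` (fraction of
#' branch length unique to one sample's observed leaves) and
#' `weighted_unifrac` (\eqn{\sum_b \ell_b |p_A(b) - p_B(b)|}, unnormalized
#' by default) are phylogenetic and require `tree` to contain every table
#' taxon as a leaf.
#'
#' @param table Feature table.
#' @param metric One of `jaccard`, `bray_curtis`, `unweighted_unifrac`,
#'   `weighted_unifrac`.
#' @param tree Microbial `phylo` (UniFrac metrics only).
#' @param normalized Use the normalized weighted-UniFrac variant.
#' @return Labelled distance matrix over samples.
#' @export
beta <- function(table, metric = c("jaccard", "bray_curtis",
                                   "unweighted_unifrac", "weighted_unifrac"),
                 tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  # accept counts or relative-abundance rows (population representatives)
  if (!is.matrix(table) || !is.numeric(table) || is.null(rownames(table)) ||
      is.null(colnames(table)) || anyNA(table) || any(table < 0) ||
      any(rowSums(table) == 0))
    ps_stop("beta() needs a non-negative abundance matrix with dimnames and positive row sums",
            "format_error")
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac") &&
      is.null(tree))
    ps_stop(sprintf("metric '%s' requires a tree", metric), "config_error")
  m <- switch(metric,
    jaccard = as.matrix(vegan::vegdist(table, method = "jaccard",
                                       binary = TRUE)),
    bray_curtis = as.matrix(vegan::vegdist(table, method = "bray")),
    unweighted_unifrac = unifrac_matrix(table, tree, weighted = FALSE),
    weighted_unifrac = unifrac_matrix(table, tree, weighted = TRUE,
                                      normalized = normalized))
  as_distance_matrix(m, rownames(table))
}

#' Principal coordinate analysis
#'
#' Classical (Torgerson) scaling of the double-centered \eqn{-D^2/2}
#' matrix. Axes with negative eigenvalues are dropped from the coordinates
#' but all eigenvalues are reported.
#'
#' @param dm Labelled distance matrix (>= 3 labels).
#' @return List with `coordinates` (samples x retained axes),
#'   `eigenvalues` (all, non-increasing) and `proportion_explained`
#'   (positive axes, relative to the positive-eigenvalue total).
#' @export
pcoa <- function(dm) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 3) ps_stop("PCoA needs >= 3 labels", "config_error")
  # negative eigenvalues are expected for non-Euclidean dissimilarities
  # and are reported below; cmdscale's warning about them is redundant
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = nrow(dm) - 1, eig = TRUE))
  eig <- sc$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- sc$points[, seq_len(min(npos, ncol(sc$points))), drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = pmax(eig[seq_len(npos)], 0) /
         sum(pmax(eig, 0)))
}
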