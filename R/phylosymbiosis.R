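# Co-dendrogram phylosymbiosis test: population representatives -> UPGMA
# dendrogram -> normalized Robinson-Foulds distance to the host phylogeny,
# with significance against randomized microbiome topologies.

#' Population-representative community table
#'
#' Collapses a sample-level table to one relative-abundance row per
#' population, either by the mean of each population's per-sample
#' relative abundances (`population_mean`) or by a uniformly chosen
#' single sample (`random_pick`).
#'
#' @param table Feature table (samples x taxa).
#' @param mapping Named character vector: sample id -> population.
#' @param mode `"population_mean"` or `"random_pick"`.
#' @param seed RNG seed (random_pick).
#' @return Matrix of relative abundances, one row per population.
#' @export
population_representatives <- function(table, mapping,
                                       mode = c("population_mean",
                                                "random_pick"),
                                       seed = 1L) {
  mode <- match.arg(mode)
  mapping <- mapping[rownames(table)]
  if (anyNA(mapping))
    ps_stop("sample(s) missing from population mapping", "design_error")
  ra <- relative_abundance(table)
  pops <- split(rownames(table), mapping)
  if (any(lengths(pops) == 0)) ps_stop("empty population", "design_error")
  rows <- if (mode == "population_mean")
    lapply(pops, function(ids) colMeans(ra[ids, , drop = FALSE]))
  else
    with_seed(seed, lapply(pops, function(ids)
      ra[if (length(ids) == 1) ids else sample(ids, 1), ]))
  out <- do.call(rbind, rows)
  rownames(out) <- names(pops)
  out
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree;
#' each merge sits at half the average-linkage distance, so cophenetic
#' distances reproduce ultrametric inputs exactly. Ties are broken by the
#' lexicographic order of cluster representative labels, making the
#' topology deterministic.
#'
#' @param dm Labelled distance matrix (>= 3 labels).
#' @return Ultrametric `phylo`.
#' @export
upgma <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3) ps_stop("UPGMA needs >= 3 labels", "config_error")
  ord <- order(rownames(dm))
  d <- dm[ord, ord]
  labs <- rownames(d)
  # cluster state: newick fragment, height, size, representative label
  nwk <- labs
  height <- rep(0, n)
  size <- rep(1L, n)
  rep_lab <- labs
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)[-length(active)])
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        dd <- d[a, b]
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(a, b) }
        else if (abs(dd - best_d) <= 1e-12) {
          # lexicographic tie-break on representative label pairs
          cand <- sort(c(rep_lab[a], rep_lab[b]))
          cur <- sort(c(rep_lab[best[1]], rep_lab[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(a, b)
          }
        }
      }
    a <- best[1]; b <- best[2]
    h <- best_d / 2
    merged <- sprintf("(%s:%.10f,%s:%.10f)", nwk[a], h - height[a],
                      nwk[b], h - height[b])
    # average-linkage update into slot a
    for (k in setdiff(active, c(a, b)))
      d[a, k] <- d[k, a] <- (size[a] * d[a, k] + size[b] * d[b, k]) /
        (size[a] + size[b])
    nwk[a] <- merged
    height[a] <- h
    size[a] <- size[a] + size[b]
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    active <- setdiff(active, b)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

# Canonical non-trivial split keys of a tree (compared as unrooted),
# relative to a fixed reference label order.
split_keys <- function(tree, ref_labels) {
  n <- length(ref_labels)
  idx <- match(tree$tip.label, ref_labels)
  if (anyNA(idx))
    ps_stop("tree leaves not in reference label set", "alignment_error")
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(idx[p])
    if (1 %in% side) side <- setdiff(seq_len(n), side)  # canonical side
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

#' Normalized Robinson-Foulds distance
#'
#' Trees are compared as unrooted; the symmetric difference of their
#' non-trivial bipartitions is divided by \eqn{2(n - 3)}, the maximum for
#' fully resolved trees, giving a value in `[0, 1]`.
#'
#' @param t1,t2 `phylo` trees over identical leaf sets (n >= 4).
#' @return Normalized RF distance.
#' @export
robinson_foulds_normalized <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    ps_stop(sprintf("leaf sets differ: %s",
                    paste(c(setdiff(t1$tip.label, t2$tip.label),
                            setdiff(t2$tip.label, t1$tip.label)),
                          collapse = ", ")), "alignment_error")
  n <- length(t1$tip.label)
  if (n < 4) ps_stop("RF comparison needs >= 4 leaves", "design_error")
  ref <- sort(t1$tip.label)
  s1 <- split_keys(t1, ref)
  s2 <- split_keys(t2, ref)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / (2 * (n - 3))
}

# Random sequential coalescence over 1..n; returns the canonical split
# keys of the resulting unrooted topology. Shares its distribution with
# random_topology().
coalesce_splits <- function(n) {
  clusters <- as.list(seq_len(n))
  keys <- character(0)
  while (length(clusters) > 1) {
    pick <- sample.int(length(clusters), 2)
    merged <- sort(c(clusters[[pick[1]]], clusters[[pick[2]]]))
    clusters[[pick[1]]] <- merged
    clusters[[pick[2]]] <- NULL
    side <- merged
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

#' Random binary topology
#'
#' Random sequential coalescence of lineage pairs over a randomly
#' permuted label assignment; branch lengths are set to 1 (topology is
#' all that RF uses).
#'
#' @param labels Leaf labels (>= 4).
#' @param seed RNG seed.
#' @return Rooted binary `phylo`.
#' @export
random_topology <- function(labels, seed = 1L) {
  n <- length(labels)
  if (n < 4) ps_stop("need >= 4 labels", "design_error")
  with_seed(seed, {
    labs <- sample(labels)
    nwk <- labs
    while (length(nwk) > 1) {
      pick <- sample.int(length(nwk), 2)
      nwk[pick[1]] <- sprintf("(%s:1,%s:1)", nwk[pick[1]], nwk[pick[2]])
      nwk <- nwk[-pick[2]]
    }
    ape::read.tree(text = paste0(nwk, ";"))
  })
}

#' Co-dendrogram phylosymbiosis test
#'
#' Builds a UPGMA dendrogram of population-level microbial dissimilarity,
#' measures its normalized RF distance to the host phylogeny, and
#' compares it against `n_random` randomized topologies. The p-value
#' counts random trees at least as congruent as observed:
#' \eqn{p = (\#\{RF_{rand} \le RF_{obs}\} + 1) / (n_{rand} + 1)}.
#'
#' For `mode = "random_pick"` the dendrogram is rebuilt `n_picks` times
#' from single randomly chosen samples per population and the mean RF is
#' the observed statistic.
#'
#' @param host_tree Host `phylo`; pruned to the populations present.
#' @param beta_dm Population-level distance matrix (`population_mean`
#'   path); or supply `table` + `mapping` to compute representatives.
#' @param table,mapping,metric,tree Sample-level inputs used when
#'   `beta_dm` is NULL (and always for `random_pick`).
#' @param mode Representative mode.
#' @param n_random Number of randomized topologies.
#' @param n_picks Random-pick replicates.
#' @param seed RNG seed.
#' @return A `phylosymbiosis_result`: `rf_observed`, `p`, `n_random`,
#'   `metric`, `mode`, and `rf_replicates` (random_pick).
#' @export
phylosymbiosis_test <- function(host_tree, beta_dm = NULL, table = NULL,
                                mapping = NULL, metric = "bray_curtis",
                                tree = NULL,
                                mode = c("population_mean", "random_pick"),
                                n_random = 10000, n_picks = 100, seed = 1L) {
  mode <- match.arg(mode)
  rf_replicates <- NULL
  if (mode == "random_pick" || is.null(beta_dm)) {
    if (is.null(table) || is.null(mapping))
      ps_stop("need table + mapping when beta_dm is absent or mode is random_pick",
              "config_error")
  }
  pops <- if (!is.null(beta_dm)) rownames(beta_dm) else
    unique(unname(mapping[rownames(table)]))
  shared <- intersect(host_tree$tip.label, pops)
  if (length(shared) < 4)
    ps_stop("fewer than 4 shared populations", "design_error")
  host <- if (length(shared) < length(host_tree$tip.label))
    ape::keep.tip(host_tree, shared) else host_tree
  make_dend <- function(dm) upgma(dm[shared, shared])
  if (mode == "population_mean") {
    if (is.null(beta_dm)) {
      reps <- population_representatives(table, mapping, "population_mean")
      beta_dm <- beta(reps, metric = metric, tree = tree)
    }
    rf_obs <- robinson_foulds_normalized(make_dend(beta_dm), host)
  } else {
    rf_replicates <- vapply(seq_len(n_picks), function(k) {
      reps <- population_representatives(
        table, mapping, "random_pick",
        seed = derive_seed(seed, sprintf("pick%04d", k)))
      dmk <- beta(reps, metric = metric, tree = tree)
      robinson_foulds_normalized(make_dend(dmk), host)
    }, numeric(1))
    rf_obs <- mean(rf_replicates)
  }
  # null: RF between the host phylogeny and randomized topologies
  ref <- sort(shared)
  host_keys <- split_keys(host, ref)
  n <- length(ref)
  denom <- 2 * (n - 3)
  rf_rand <- with_seed(derive_seed(seed, "null"), vapply(
    seq_len(n_random), function(k) {
      rk <- coalesce_splits(n)
      (length(setdiff(rk, host_keys)) + length(setdiff(host_keys, rk))) /
        denom
    }, numeric(1)))
  p <- (sum(rf_rand <= rf_obs + 1e-12) + 1) / (n_random + 1)
  structure(list(rf_observed = rf_obs, p = p, n_random = n_random,
                 metric = metric, mode = mode,
                 rf_replicates = rf_replicates,
                 rf_null_mean = mean(rf_rand)),
            class = "phylosymbiosis_result")
}
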