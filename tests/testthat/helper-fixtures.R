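# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately use different code paths from the package
# (per-tip root paths, direct enumeration, normal equations).

toy_table <- function() {
  m <- matrix(c(3L, 0L, 1L, 2L), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("T1", "T2")))
  m
}

random_table <- function(n_samples, n_taxa, depth = 500, seed = 1) {
  set.seed(seed)
  m <- t(stats::rmultinom(n_samples, depth,
                          prob = stats::rgamma(n_taxa, 1)))
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      sprintf("T%03d", seq_len(n_taxa)))
  m
}

random_dm <- function(n, seed = 1, labels = sprintf("L%02d", seq_len(n))) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 3), n)
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

# For each tip, the set of edges on its root path (by independent
# edge-matrix walking); then UniFrac by direct edge enumeration.
edge_sets_by_tip <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

oracle_unifrac <- function(tree, pres_a, pres_b, weighted = FALSE,
                           ra_a = NULL, ra_b = NULL) {
  es <- edge_sets_by_tip(tree)
  tips <- tree$tip.label
  n_edge <- nrow(tree$edge)
  if (!weighted) {
    in_a <- in_b <- rep(FALSE, n_edge)
    for (t in which(tips %in% pres_a)) in_a[es[[t]]] <- TRUE
    for (t in which(tips %in% pres_b)) in_b[es[[t]]] <- TRUE
    len <- tree$edge.length
    sum(len[xor(in_a, in_b)]) / sum(len[in_a | in_b])
  } else {
    pa <- pb <- rep(0, n_edge)
    for (t in seq_along(tips)) {
      pa[es[[t]]] <- pa[es[[t]]] + ra_a[tips[t]]
      pb[es[[t]]] <- pb[es[[t]]] + ra_b[tips[t]]
    }
    sum(tree$edge.length * abs(pa - pb))
  }
}

# Exhaustive Mantel enumeration: permute A's labels every possible way.
oracle_mantel_exact <- function(A, B, method = "spearman") {
  n <- nrow(A)
  perms <- gtools_permutations(n)
  unf <- function(m) m[lower.tri(m)]
  x0 <- unf(A); y <- unf(B)
  if (method == "spearman") y <- rank(y)
  r_obs <- if (method == "spearman") cor(rank(x0), y) else cor(x0, y)
  rs <- apply(perms, 1, function(p) {
    xp <- unf(A[p, p])
    if (method == "spearman") xp <- rank(xp)
    cor(xp, y)
  })
  mean(rs >= r_obs - 1e-12)
}

# Base-R permutation enumeration (recursive), independent of the package.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))))
}

oracle_permanova_exact <- function(dm, groups) {
  n <- length(groups)
  f_of <- function(g) {
    d2 <- dm^2
    sst <- sum(d2[lower.tri(d2)]) / n
    ssw <- 0
    for (u in unique(g)) {
      i <- which(g == u)
      ssw <- ssw + sum(d2[i, i][lower.tri(d2[i, i])]) / length(i)
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  perms <- gtools_permutations(n)
  fs <- apply(perms, 1, function(p) f_of(groups[p]))
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}

null_config <- function(seed, n_populations = 8, samples_per_population = 3,
                        n_taxa = 40, depth = 2000) {
  simulation_config(n_populations = n_populations,
                    samples_per_population = samples_per_population,
                    n_taxa = n_taxa, depth = depth,
                    sigma_phylo = 0, sigma_diet = 0, sigma_noise = 0.5,
                    seed = seed)
}

# Planted 3-block abundance table for co-occurrence tests: orthogonal
# block factors, row-centered signal (constant row totals) so closure to
# relative abundances preserves the planted correlation structure.
planted_block_table <- function(n = 30, per_block = 8, seed = 9) {
  set.seed(seed)
  base <- qr.Q(qr(matrix(stats::rnorm(n * 3), n, 3))) * sqrt(n)
  X <- do.call(cbind, lapply(1:3, function(b)
    vapply(seq_len(per_block), function(k)
      base[, b] + stats::rnorm(n, sd = 0.3), numeric(n))))
  X <- X - rowMeans(X)
  colnames(X) <- sprintf("B%d_%02d", rep(1:3, each = per_block),
                         rep(seq_len(per_block), 3))
  rownames(X) <- paste0("s", seq_len(n))
  tab <- round(1000 + 30 * X)
  storage.mode(tab) <- "integer"
  tab
}
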