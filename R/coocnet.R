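# Co-occurrence network construction and module-based topological roles
# (Zi-Pi) for keystone-taxon classification.

#' Occurrence and abundance filtering for network construction
#'
#' Drops taxa present (count > 0) in fewer than `min_occurrence` samples,
#' then keeps the `top_n` taxa by mean relative abundance, ties at the
#' cutoff broken by taxon id order.
#'
#' @param table Feature table.
#' @param min_occurrence Minimum number of samples with a positive count.
#' @param top_n Number of taxa retained by mean relative abundance.
#' @return Filtered feature table.
#' @export
filter_taxa <- function(table, min_occurrence = 5, top_n = 100) {
  table <- validate_feature_table(table)
  occ <- colSums(table > 0)
  table <- table[, occ >= min_occurrence, drop = FALSE]
  if (ncol(table) == 0)
    ps_stop("no taxon passes the occurrence filter", "empty_result_error")
  mean_ra <- colMeans(relative_abundance(table))
  keep <- order(-mean_ra, colnames(table))[seq_len(min(top_n, ncol(table)))]
  table[, sort(colnames(table)[keep]), drop = FALSE]
}

#' Pearson correlation co-occurrence network
#'
#' Pearson correlation of per-sample relative abundances for every taxon
#' pair; an edge is kept iff \eqn{|r| >} `r_threshold` and the two-sided
#' t-test p < `p_threshold`. Zero-variance taxa are excluded with a
#' warning.
#'
#' @param table Feature table (>= 4 samples).
#' @param r_threshold Absolute correlation threshold.
#' @param p_threshold Two-sided p-value threshold.
#' @param p_adjust Apply Benjamini-Hochberg to edge p-values first.
#' @param clr Use a centered log-ratio transform (pseudocount 0.5) instead
#'   of relative abundances, for compositionality-aware correlations.
#' @return A `cooccurrence_graph` list: `graph` (igraph), `edges`
#'   (data.frame: source, target, r, p), `nodes` (character).
#' @export
correlation_network <- function(table, r_threshold = 0.6, p_threshold = 0.05,
                                p_adjust = FALSE, clr = FALSE) {
  if (nrow(table) < 4)
    ps_stop("need >= 4 samples for edge p-values", "design_error")
  X <- if (clr) {
    lx <- log(table + 0.5)
    sweep(lx, 1, rowMeans(lx))
  } else relative_abundance(table)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    ps_warn(sprintf("excluding %d zero-variance taxa", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  taxa <- colnames(X)
  R <- stats::cor(X)
  n <- nrow(X)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, 1e-300))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  edges <- data.frame(source = taxa[iu[, 1]], target = taxa[iu[, 2]],
                      r = R[iu], p = P[iu], stringsAsFactors = FALSE)
  if (p_adjust) edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- edges[abs(edges$r) > r_threshold & edges$p < p_threshold, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = taxa))
  structure(list(graph = g, edges = edges, nodes = taxa),
            class = "cooccurrence_graph")
}

#' Greedy-modularity module detection
#'
#' Fast-greedy modularity maximization on the (unweighted) network;
#' isolated nodes become singleton modules.
#'
#' @param net A `cooccurrence_graph` or igraph object.
#' @return Named integer vector: node -> module id.
#' @export
detect_modules <- function(net) {
  g <- if (inherits(net, "cooccurrence_graph")) net$graph else net
  comp <- igraph::components(g)
  nodes <- igraph::V(g)$name
  modules <- integer(length(nodes))
  names(modules) <- nodes
  next_id <- 0L
  for (c_id in seq_len(comp$no)) {
    members <- nodes[comp$membership == c_id]
    if (length(members) == 1) {
      next_id <- next_id + 1L
      modules[members] <- next_id
    } else {
      sub <- igraph::induced_subgraph(g, members)
      cl <- igraph::cluster_fast_greedy(sub)
      mem <- igraph::membership(cl)
      # a split is only kept when it beats the trivial one-community
      # partition (whose modularity is 0)
      if (igraph::modularity(sub, mem) <= 0)
        mem[] <- 1L
      modules[names(mem)] <- next_id + as.integer(mem)
      next_id <- next_id + max(as.integer(mem))
    }
  }
  modules
}

#' Within-module degree z-score (Zi) and participation coefficient (Pi)
#'
#' \eqn{Z_i = (k_{i,own} - \bar k_{own}) / sd(k_{own})} over the node's
#' module (0 when the sd is 0 or the module has < 3 members);
#' \eqn{P_i = 1 - \sum_m (k_{im}/k_i)^2} (0 for isolated nodes).
#'
#' @param net A `cooccurrence_graph` or igraph object.
#' @param modules Named module assignment covering all nodes.
#' @return data.frame: node, degree, module, Zi, Pi.
#' @export
zi_pi <- function(net, modules) {
  g <- if (inherits(net, "cooccurrence_graph")) net$graph else net
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, names(modules))
  if (length(missing))
    ps_stop(sprintf("node(s) missing from module assignment: %s",
                    paste(missing, collapse = ", ")), "coverage_error")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- adj[nodes, nodes]
  mod <- modules[nodes]
  deg <- rowSums(adj)
  # k_im: links from each node into each module
  mods <- sort(unique(mod))
  kim <- vapply(mods, function(m)
    rowSums(adj[, mod == m, drop = FALSE]), numeric(length(nodes)))
  if (is.null(dim(kim))) kim <- matrix(kim, nrow = length(nodes))
  k_own <- kim[cbind(seq_along(nodes), match(mod, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    idx <- which(mod == m)
    if (length(idx) >= 3 && stats::sd(k_own[idx]) > 0)
      zi[idx] <- (k_own[idx] - mean(k_own[idx])) / stats::sd(k_own[idx])
  }
  pi <- ifelse(deg > 0, 1 - rowSums((kim / pmax(deg, 1))^2), 0)
  data.frame(node = nodes, degree = deg, module = unname(mod),
             Zi = zi, Pi = pi, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify topological roles from Zi-Pi values
#'
#' Peripheral (Zi <= zi_cut, Pi <= pi_cut), connector (Pi > pi_cut),
#' module hub (Zi > zi_cut), network hub (both exceeded) -- the
#' molecular-ecology network convention (cuts 2.5 / 0.62).
#'
#' @param stats data.frame from [zi_pi()] (columns `Zi`, `Pi`).
#' @param zi_cut,pi_cut Role thresholds.
#' @return `stats` with an added `role` factor column.
#' @export
classify_roles <- function(stats, zi_cut = 2.5, pi_cut = 0.62) {
  role <- ifelse(stats$Zi > zi_cut,
                 ifelse(stats$Pi > pi_cut, "network_hub", "module_hub"),
                 ifelse(stats$Pi > pi_cut, "connector", "peripheral"))
  stats$role <- factor(role, levels = c("peripheral", "connector",
                                        "module_hub", "network_hub"))
  stats
}

#' Full co-occurrence analysis
#'
#' [filter_taxa()] -> [correlation_network()] -> [detect_modules()] ->
#' [zi_pi()] -> [classify_roles()].
#'
#' @inheritParams filter_taxa
#' @inheritParams correlation_network
#' @param zi_cut,pi_cut Role thresholds (see [classify_roles()]).
#' @return List: `network` (`cooccurrence_graph`), `modules`, `node_stats`
#'   (with roles), `role_counts`.
#' @export
cooccurrence_analysis <- function(table, min_occurrence = 5, top_n = 100,
                                  r_threshold = 0.6, p_threshold = 0.05,
                                  zi_cut = 2.5, pi_cut = 0.62) {
  ft <- filter_taxa(table, min_occurrence, top_n)
  net <- correlation_network(ft, r_threshold, p_threshold)
  modules <- detect_modules(net)
  stats <- classify_roles(zi_pi(net, modules), zi_cut, pi_cut)
  list(network = net, modules = modules, node_stats = stats,
       role_counts = base::table(stats$role))
}
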