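# Paired host-phylogeny + microbiome simulator. Communities are generated
# from per-taxon latent log-abundances
#   mu_ij = b_i + sigma_phylo * g_i(j) + sigma_diet * delta_i * I(diet_j == A)
# where g_i is a Brownian-motion realization on the host tree (unit-time
# variance 1, root height 1), delta_i marks taxa carrying the diet effect,
# and b_i ~ N(0, 1). Each sample adds taxon-wise noise eps ~ N(0,
# sigma_noise^2) and draws counts ~ Multinomial(depth, softmax(mu + eps)).

# Run `code` under `seed` without disturbing the caller's RNG stream.
# `seed` is forced first: a lazily evaluated `seed = sample.int(...)`
# must consume the caller's stream before we snapshot it.
with_seed <- function(seed, code) {
  force(seed)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a master seed
#'
#' Stable hash-based derivation so every analysis stage gets an
#' independent stream and adding a stage never perturbs another stage's
#' randomness. Always below 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Defaults mirror a multi-population alpine butterfly survey: 12
#' populations of 4 pooled samples each, 150 ASVs, sequencing depth 35,701
#' reads (the rarefaction depth used downstream), moderate phylosymbiosis
#' and diet signals, and within-population log-abundance noise 0.5.
#'
#' @param n_populations Number of host populations (>= 4).
#' @param samples_per_population Samples per population (>= 3).
#' @param n_taxa Number of microbial taxa (>= 20).
#' @param depth Reads per sample (>= 100).
#' @param sigma_phylo Strength of the host-phylogeny (Brownian) effect.
#' @param sigma_diet Strength of the larval host-plant (diet) effect.
#' @param diet_clade_depth `"deep"` (effect loads on whole old microbial
#'   clades) or `"shallow"` (scattered singleton leaves).
#' @param sigma_noise Per-sample log-abundance noise sd.
#' @param diet_split Fraction of host populations assigned diet "A" by clade.
#' @param bbox Geographic bounding box `c(lat_min, lat_max, lon_min, lon_max)`
#'   in degrees.
#' @param altitude_range Altitude range in meters.
#' @param altitude_diet_shift Additive altitude shift (m) for diet-A
#'   populations (0 = altitude independent of diet).
#' @param seed Master RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_populations = 12, samples_per_population = 4,
                              n_taxa = 150, depth = 35701,
                              sigma_phylo = 1, sigma_diet = 1,
                              diet_clade_depth = c("deep", "shallow"),
                              sigma_noise = 0.5, diet_split = 0.5,
                              bbox = c(28, 40, 85, 105),
                              altitude_range = c(1500, 4500),
                              altitude_diet_shift = 0, seed = 1L) {
  diet_clade_depth <- match.arg(diet_clade_depth)
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_population = as.integer(samples_per_population),
              n_taxa = as.integer(n_taxa), depth = as.integer(depth),
              sigma_phylo = sigma_phylo, sigma_diet = sigma_diet,
              diet_clade_depth = diet_clade_depth, sigma_noise = sigma_noise,
              diet_split = diet_split, bbox = bbox,
              altitude_range = altitude_range,
              altitude_diet_shift = altitude_diet_shift,
              seed = as.integer(seed))
  if (cfg$n_populations < 4)
    ps_stop("n_populations must be >= 4", "config_error")
  if (cfg$samples_per_population < 3)
    ps_stop("samples_per_population must be >= 3", "config_error")
  if (cfg$n_taxa < 20) ps_stop("n_taxa must be >= 20", "config_error")
  if (cfg$depth < 100) ps_stop("depth must be >= 100", "config_error")
  if (any(c(cfg$sigma_phylo, cfg$sigma_diet, cfg$sigma_noise) < 0))
    ps_stop("effect/noise sds must be >= 0", "config_error")
  class(cfg) <- "simulation_config"
  cfg
}

# Pure-birth ultrametric tree rescaled to root height 1.
yule_tree <- function(n, labels, seed) {
  with_seed(seed, {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$tip.label <- labels
    depths <- ape::node.depth.edgelength(tr)
    tr$edge.length <- tr$edge.length / max(depths)
    tr
  })
}

#' Simulate a host phylogeny
#'
#' Pure-birth (Yule) rooted binary tree over populations `P01..Pn`,
#' rescaled so the root-to-tip height is 1.
#'
#' @param n_populations Number of leaves (>= 4).
#' @param seed RNG seed.
#' @return `phylo` object.
#' @export
simulate_host_tree <- function(n_populations, seed = 1L) {
  if (n_populations < 4) ps_stop("need >= 4 populations", "config_error")
  yule_tree(n_populations, sprintf("P%02d", seq_len(n_populations)), seed)
}

#' Simulate a microbial phylogeny
#'
#' As [simulate_host_tree()] over taxa `T001..Tn` (>= 2 leaves).
#'
#' @param n_taxa Number of leaves.
#' @param seed RNG seed.
#' @return `phylo` object.
#' @export
simulate_microbial_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) ps_stop("need >= 2 taxa", "config_error")
  yule_tree(n_taxa, sprintf("T%03d", seq_len(n_taxa)), seed)
}

# Leaf sets of every internal node (node ids n+1 .. n+Nnode).
clade_leaf_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    tips <- ape::extract.clade(tree, n + i)$tip.label
    sets[[i]] <- tips
  }
  names(sets) <- as.character(n + seq_len(tree$Nnode))
  sets
}

#' Assign population-level covariates on a host tree
#'
#' Diet is clade-conserved: the internal clade whose leaf count is closest
#' to `diet_split * n` is labelled diet "A", the remainder "B". Coordinates
#' are uniform in the bounding box; altitude uniform in its range with an
#' optional additive shift for diet-A populations.
#'
#' @param host_tree `phylo` over populations.
#' @param config A [simulation_config()].
#' @param seed RNG seed (defaults to a stream derived from `config$seed`).
#' @return data.frame with population, diet, latitude, longitude, altitude.
#' @export
assign_covariates <- function(host_tree, config, seed = NULL) {
  n <- length(host_tree$tip.label)
  if (n < 4) ps_stop("host tree needs >= 4 leaves", "config_error")
  if (is.null(seed)) seed <- derive_seed(config$seed, "covariates")
  sets <- clade_leaf_sets(host_tree)
  sizes <- lengths(sets)
  target <- config$diet_split * n
  ok <- sizes < n  # exclude the root clade (everything)
  pick <- which(ok)[which.min(abs(sizes[ok] - target))]
  if (abs(sizes[pick] - target) > 1)
    message(sprintf(
      "no clade within 1 leaf of requested diet split %.2f; using clade of %d/%d leaves",
      config$diet_split, sizes[pick], n))
  dietA <- sets[[pick]]
  with_seed(seed, {
    data.frame(
      population = host_tree$tip.label,
      diet = ifelse(host_tree$tip.label %in% dietA, "A", "B"),
      latitude = stats::runif(n, config$bbox[1], config$bbox[2]),
      longitude = stats::runif(n, config$bbox[3], config$bbox[4]),
      altitude = stats::runif(n, config$altitude_range[1],
                              config$altitude_range[2]) +
        ifelse(host_tree$tip.label %in% dietA,
               config$altitude_diet_shift, 0),
      stringsAsFactors = FALSE)
  })
}

# Pick the diet-affected taxa. Deep mode: 1-3 clades whose stem originates
# in the oldest quartile of internal-node depths, jointly covering at most
# half the taxa. Shallow mode: scattered singleton leaves of matched count.
select_diet_taxa <- function(microbial_tree, mode, n_taxa, seed) {
  with_seed(seed, {
    if (mode == "deep") {
      sets <- clade_leaf_sets(microbial_tree)
      nd <- ape::node.depth.edgelength(microbial_tree)
      node_ids <- as.integer(names(sets))
      depths <- nd[node_ids]
      inner <- node_ids != (length(microbial_tree$tip.label) + 1)
      cut <- stats::quantile(depths[inner], 0.25)
      cand <- which(inner & depths <= cut & lengths(sets) <= n_taxa %/% 2)
      if (!length(cand))  # fall back to the oldest usable clade
        cand <- which(inner & lengths(sets) <= n_taxa %/% 2)[
          order(depths[which(inner & lengths(sets) <= n_taxa %/% 2)])][1]
      cand <- sample(cand)
      chosen <- character(0)
      k_target <- sample(1:3, 1)
      for (i in cand) {
        if (length(intersect(sets[[i]], chosen))) next
        if (length(chosen) + length(sets[[i]]) > n_taxa %/% 2) next
        chosen <- c(chosen, sets[[i]])
        k_target <- k_target - 1
        if (k_target <= 0) break
      }
      chosen
    } else {
      k <- max(1, round(n_taxa / 4))
      sample(microbial_tree$tip.label, k)
    }
  })
}

#' Simulate a paired host-microbiome dataset
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset` list: `host_tree`, `microbial_tree`,
#'   `table` (samples x taxa counts, every row summing to `depth`),
#'   `metadata`, `covariates` (population level) and `truth` (per-taxon
#'   effect assignments plus the generating config).
#' @export
simulate_communities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  host <- simulate_host_tree(config$n_populations,
                             derive_seed(config$seed, "host_tree"))
  micro <- simulate_microbial_tree(config$n_taxa,
                                   derive_seed(config$seed, "microbial_tree"))
  cov <- assign_covariates(host, config)
  diet_taxa <- select_diet_taxa(micro, config$diet_clade_depth, config$n_taxa,
                                derive_seed(config$seed, "diet_taxa"))
  delta <- as.numeric(micro$tip.label %in% diet_taxa)
  npop <- config$n_populations
  ntax <- config$n_taxa
  V <- ape::vcv(host)  # shared-path covariance; root height 1
  V <- V[host$tip.label, host$tip.label]
  L <- t(chol(V + diag(1e-10, npop)))
  mu <- with_seed(derive_seed(config$seed, "effects"), {
    b <- stats::rnorm(ntax)
    g <- L %*% matrix(stats::rnorm(npop * ntax), npop, ntax)  # BM on tree
    isA <- cov$diet[match(rownames(V), cov$population)] == "A"
    sweep(config$sigma_phylo * g, 2, b, "+") +
      config$sigma_diet * outer(isA, delta)
  })
  rownames(mu) <- rownames(V)
  sample_ids <- as.vector(t(outer(host$tip.label,
                                  seq_len(config$samples_per_population),
                                  function(p, k) sprintf("%s_S%d", p, k))))
  counts <- with_seed(derive_seed(config$seed, "counts"), {
    out <- matrix(0L, length(sample_ids), ntax,
                  dimnames = list(sample_ids, micro$tip.label))
    for (s in seq_along(sample_ids)) {
      pop <- sub("_S\\d+$", "", sample_ids[s])
      eta <- mu[pop, ] + stats::rnorm(ntax, 0, config$sigma_noise)
      eta <- eta - max(eta)  # softmax underflow guard
      p <- exp(eta) / sum(exp(eta))
      out[s, ] <- stats::rmultinom(1, config$depth, p)[, 1]
    }
    out
  })
  md <- data.frame(
    sample_id = sample_ids,
    population = sub("_S\\d+$", "", sample_ids),
    stringsAsFactors = FALSE)
  md <- cbind(md, cov[match(md$population, cov$population),
                      c("latitude", "longitude", "altitude", "diet")])
  md$species <- md$population  # one (sub)species per population in this design
  md$host_plant <- ifelse(md$diet == "A", "Crassulaceae", "Papaveraceae")
  rownames(md) <- NULL
  structure(list(host_tree = host, microbial_tree = micro,
                 table = counts, metadata = md, covariates = cov,
                 truth = list(config = config, diet_taxa = diet_taxa,
                              delta = stats::setNames(delta, micro$tip.label),
                              latent_mean = mu)),
            class = "synthetic_dataset")
}
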