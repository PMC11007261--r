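# End-to-end orchestration: simulate or ingest, rarefy, diversity,
# covariates, matrix inference, phylosymbiosis, network -- from a single
# validated config, with per-stage seeds derived from one master seed so
# adding a stage never perturbs another stage's randomness.

#' Analysis configuration
#'
#' Either `simulate` (a [simulation_config()]) or explicit input paths
#' (`table`, `metadata`, `host_tree`, `microbial_tree`). UniFrac metrics
#' require a microbial tree; that is checked here, before any computation.
#'
#' @param simulate Optional [simulation_config()].
#' @param table,metadata,host_tree,microbial_tree Input file paths
#'   (ignored when `simulate` is given).
#' @param rarefy_depth Rarefaction depth, or NULL to skip.
#' @param metrics Beta metrics to compute.
#' @param method Mantel correlation method.
#' @param n_perm Permutations for Mantel/MRM/PERMANOVA.
#' @param n_random Randomized trees for the phylosymbiosis test.
#' @param phylosymbiosis_metric Beta metric for the co-dendrogram test.
#' @param phylosymbiosis_mode Representative mode.
#' @param n_picks Random-pick replicates.
#' @param network Run the co-occurrence stage.
#' @param min_occurrence,top_n Network taxon filters.
#' @param seed Master seed (mandatory; every stochastic stage derives its
#'   own stream from it).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(simulate = NULL, table = NULL, metadata = NULL,
                            host_tree = NULL, microbial_tree = NULL,
                            rarefy_depth = NULL,
                            metrics = c("jaccard", "bray_curtis",
                                        "unweighted_unifrac",
                                        "weighted_unifrac"),
                            method = "spearman", n_perm = 999,
                            n_random = 10000,
                            phylosymbiosis_metric = "bray_curtis",
                            phylosymbiosis_mode = "population_mean",
                            n_picks = 100, network = TRUE,
                            min_occurrence = 5, top_n = 100, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(simulate)) {
    for (p in c("table", "metadata", "host_tree")) {
      if (is.null(cfg[[p]]))
        ps_stop(sprintf("config needs '%s' (or a simulation config)", p),
                "validation_error")
      if (!file.exists(cfg[[p]]))
        ps_stop(sprintf("input path does not exist: %s", cfg[[p]]),
                "validation_error")
    }
    needs_tree <- any(grepl("unifrac", c(metrics, phylosymbiosis_metric)))
    if (needs_tree && (is.null(microbial_tree) ||
                       !file.exists(microbial_tree)))
      ps_stop("UniFrac metrics requested but no microbial tree supplied",
              "validation_error")
  }
  if (is.null(seed)) ps_stop("seed is mandatory", "validation_error")
  class(cfg) <- "analysis_config"
  cfg
}

# Order-independent FNV-1a hash of the config's JSON form, for provenance.
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "simulate")],
                         auto_unbox = TRUE, force = TRUE)
  if (!is.null(cfg$simulate))
    js <- paste0(js, jsonlite::toJSON(unclass(cfg$simulate),
                                      auto_unbox = TRUE))
  h <- 2166136261
  for (k in utf8ToInt(js)) h <- (bitwXor(as.integer(h %% 2^31), k) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order and returns a
#' machine-readable report; rerunning with the same config and seed
#' reproduces the report bit-for-bit except the timestamp.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report` list with per-stage results and
#'   provenance (`config_hash`, `seed`, `generated_at`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  if (!is.null(config$simulate)) {
    ds <- simulate_communities(config$simulate)
    tab <- ds$table; md <- ds$metadata
    host <- ds$host_tree; mtree <- ds$microbial_tree
  } else {
    tab <- read_feature_table(config$table)
    md <- read_metadata(config$metadata)
    host <- read_newick(config$host_tree)
    mtree <- if (!is.null(config$microbial_tree))
      read_newick(config$microbial_tree) else NULL
    bad <- setdiff(rownames(tab), md$sample_id)
    if (length(bad))
      ps_stop(sprintf("samples without metadata: %s",
                      paste(bad, collapse = ", ")), "alignment_error")
  }
  if (!is.null(config$rarefy_depth)) {
    tab <- rarefy(tab, config$rarefy_depth,
                  seed = derive_seed(seed, "rarefy"))
    md <- md[md$sample_id %in% rownames(tab), , drop = FALSE]
  }
  md <- md[match(rownames(tab), md$sample_id), , drop = FALSE]
  mapping <- stats::setNames(md$population, md$sample_id)
  report <- list(provenance = list(config_hash = config_hash(config),
                                   seed = seed,
                                   package_version =
                                     as.character(utils::packageVersion("phylosym")),
                                   generated_at = format(Sys.time(),
                                                         tz = "UTC")))
  report$alpha <- alpha_table(tab)
  if ("host_plant" %in% names(md) && length(unique(md$host_plant)) > 1 &&
      all(base::table(md$host_plant) >= 2))
    report$alpha_group_tests <- lapply(
      c(chao1 = "chao1", shannon = "shannon"),
      function(m) group_tests(report$alpha[[m]], md$host_plant))
  dms <- lapply(stats::setNames(config$metrics, config$metrics),
                function(m) beta(tab, metric = m, tree = mtree))
  report$beta <- dms
  cov <- covariate_set(md, host_tree = host)
  report$inference <- lapply(dms, function(dm) {
    pm <- partial_mantel(cov$genetics, dm,
                         cov[c("geography", "altitude", "host_plant")],
                         method = config$method, n_perm = config$n_perm,
                         seed = derive_seed(seed, "partial_mantel"))
    fit <- mrm(dm, cov, n_perm = config$n_perm,
               seed = derive_seed(seed, "mrm"))
    pv <- permanova(dm, stats::setNames(md$host_plant, md$sample_id),
                    n_perm = config$n_perm,
                    seed = derive_seed(seed, "permanova"))
    list(partial_mantel_genetics = unclass(pm), mrm = unclass(fit),
         permanova_host_plant = unclass(pv))
  })
  report$phylosymbiosis <- unclass(phylosymbiosis_test(
    host, table = tab, mapping = mapping,
    metric = config$phylosymbiosis_metric, tree = mtree,
    mode = config$phylosymbiosis_mode, n_random = config$n_random,
    n_picks = config$n_picks,
    seed = derive_seed(seed, "phylosymbiosis")))
  if (isTRUE(config$network)) {
    cca <- cooccurrence_analysis(tab, config$min_occurrence, config$top_n)
    report$network <- list(
      n_nodes = length(cca$network$nodes),
      n_edges = nrow(cca$network$edges),
      n_modules = length(unique(cca$modules)),
      role_counts = as.list(cca$role_counts),
      node_stats = cca$node_stats)
  }
  class(report) <- "analysis_report"
  report
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
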