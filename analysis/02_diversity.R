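#!/usr/bin/env Rscript
# Rarefy to even depth and compute alpha diversity (with host-plant group
# tests) and the four beta-diversity matrices used throughout.

suppressMessages(library(phylosym))

seed <- 2026L
dat <- "results/data"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_feature_table(file.path(dat, "table.tsv"))
md <- read_metadata(file.path(dat, "metadata.tsv"))
mtree <- read_newick(file.path(dat, "microbial_tree.nwk"))

tab <- rarefy(tab, 35701, seed = derive_seed(seed, "rarefy"))
md <- md[match(rownames(tab), md$sample_id), ]

av <- alpha_table(tab)
write.table(av, file.path(out, "alpha.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("alpha diversity over %d samples: mean observed %.1f, mean Shannon %.2f, mean Good's %.4f\n",
            nrow(av), mean(av$observed), mean(av$shannon),
            mean(av$goods_coverage)))

gt <- group_tests(av$shannon, md$host_plant)
cat(sprintf("Shannon by host plant: Kruskal-Wallis H = %.2f, p = %.3g; Wilcoxon p = %.3g\n",
            gt$kruskal$H, gt$kruskal$p, gt$wilcoxon))

for (m in c("jaccard", "bray_curtis", "unweighted_unifrac",
            "weighted_unifrac")) {
  dm <- beta(tab, metric = m, tree = mtree)
  write_distance_matrix(dm, file.path(out, paste0(m, ".tsv")))
  ord <- pcoa(dm)
  cat(sprintf("%s: mean distance %.3f; PCoA axis 1 explains %.1f%%\n",
              m, mean(dm[lower.tri(dm)]),
              100 * ord$proportion_explained[1]))
}
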