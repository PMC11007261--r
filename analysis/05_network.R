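#!/usr/bin/env Rscript
# Co-occurrence network and keystone-taxon candidates: occurrence >= 5
# filter, top-100 mean-abundance ASVs, Pearson |r| > .6 & p < .05 edges,
# greedy-modularity modules, and Zi-Pi topological roles.

suppressMessages(library(phylosym))

dat <- "results/data"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_feature_table(file.path(dat, "table.tsv"))
cca <- cooccurrence_analysis(tab, min_occurrence = 5, top_n = 100,
                             r_threshold = 0.6, p_threshold = 0.05)

write.table(cca$network$edges, file.path(out, "edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cca$node_stats, file.path(out, "nodes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("network: %d nodes, %d edges, %d modules\n",
            length(cca$network$nodes), nrow(cca$network$edges),
            length(unique(cca$modules))))
print(cca$role_counts)
hubs <- cca$node_stats[cca$node_stats$role != "peripheral", ]
if (nrow(hubs)) {
  cat("keystone candidates (non-peripheral nodes):\n")
  print(hubs[order(-hubs$Pi, -hubs$Zi), c("node", "degree", "module",
                                          "Zi", "Pi", "role")],
        row.names = FALSE)
}
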