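#!/usr/bin/env Rscript
# Aggregate the individual maps into the social cognitive map, apply the
# display thresholds (components cited by >10% of respondents; links cited
# by >10 respondents), classify components into the four representation
# zones with the centrality-frequency method, and extract the focal
# subgraph around the first negative-human-action type.

suppressPackageStartupMessages(library(repmap))

dir.create("results", showWarnings = FALSE)
col <- read_edge_list("results/data/maps_edges.csv",
                      metadata = read_metadata("results/data/metadata.csv"),
                      level = "component",
                      catalog = read_catalog("results/data/catalog.csv"))

scm <- build_social_map(col)
shown <- filter_social_map(scm, node_freq_min = 0.10, edge_occ_min = 10)
write.table(shown$nodes, "results/scm_nodes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(shown$edges, "results/scm_edges.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_social_map_graphml(shown, "results/scm.graphml")
write_social_map_dot(shown, "results/scm.dot")

zones <- representation_zones(col)
write.table(as.data.frame(zones), "results/zones.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
zs <- zone_summary(zones, col$catalog)
write.table(zs$by_type, "results/zone_summary_by_type.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

focal <- focus_subgraph(scm, focal_types = "type_nha_01", edge_occ_min = 2)
write.table(focal$edges, "results/focal_edges.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf(
  "social map: %d components (%d shown at >10%% citation), %d link records (%d shown at >10 respondents)\n",
  nrow(scm$nodes), nrow(shown$nodes), nrow(scm$edges), nrow(shown$edges)))
cat("zone sizes:",
    paste(names(zs$zone_counts), zs$zone_counts, collapse = ", "), "\n")
cat(sprintf("focal subgraph (negative-action type, links >2 respondents): %d nodes, %d links\n",
            nrow(focal$nodes), nrow(focal$edges)))
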