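#!/usr/bin/env Rscript
# Respondent ordination and clustering: correlation PCA of the nine map
# metrics with stakeholder group as supplementary variable, Ward clustering
# on the retained principal components, the Table-1-style cluster
# comparison, per-cluster group maps, and the overlap between the two
# clusters' core zones.

suppressPackageStartupMessages(library(repmap))

dir.create("results", showWarnings = FALSE)
col <- read_edge_list("results/data/maps_edges.csv",
                      metadata = read_metadata("results/data/metadata.csv"),
                      level = "component",
                      catalog = read_catalog("results/data/catalog.csv"))
mt <- metrics_table(col)

pca <- run_pca(mt)
cat(sprintf("PCA: axis 1 %.1f%%, axis 2 %.1f%% of total variance (%.1f%% cumulative)\n",
            pca$percent_variance[1], pca$percent_variance[2],
            pca$cumulative_percent[2]))

cl <- hcpc(pca, retained = 0.8, k = "auto")
cat(sprintf("HCPC: k = %d on %d retained axes (between/total inertia %.2f)\n",
            cl$k, cl$retained_axes, cl$between_inertia / cl$total_inertia))
write.table(data.frame(respondent_id = names(cl$labels),
                       cluster = unname(cl$labels)),
            "results/clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cmp <- compare_clusters(mt, hcpc(pca, retained = 0.8, k = 2))
write.table(cmp$metrics, "results/cluster_comparison.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(cmp$composition)
sig <- cmp$metrics$metric[!is.na(cmp$metrics$p) & cmp$metrics$p < 0.05]
cat("metrics differing between clusters at p<0.05:",
    paste(sig, collapse = ", "), "\n")

labels2 <- hcpc(pca, retained = 0.8, k = 2)$labels
gmaps <- group_social_maps(col, labels2)
for (nm in names(gmaps)) {
  write.table(gmaps[[nm]]$edges,
              sprintf("results/group_%s_edges.tsv", nm),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
tabs <- lapply(split(names(labels2), labels2), function(ids) {
  representation_zones(map_collection(unname(col$maps[ids]),
                                      catalog = col$catalog))
})
ov <- compare_zone_tables(tabs[[1]], tabs[[2]])
write.table(ov, "results/zone_overlap.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
core <- ov[ov$zone == "core", ]
cat(sprintf(
  "core zones: %d shared components = %.0f%% of cluster 1's and %.0f%% of cluster 2's core\n",
  core$n_shared, 100 * core$frac_a, 100 * core$frac_b))
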