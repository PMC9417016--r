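#!/usr/bin/env Rscript
# Per-respondent structural metrics (the nine PCA-active variables) and the
# component accumulation curve used as the sampling saturation diagnostic.

suppressPackageStartupMessages(library(repmap))

seed <- 42
dir.create("results", showWarnings = FALSE)

col <- read_edge_list("results/data/maps_edges.csv",
                      metadata = read_metadata("results/data/metadata.csv"),
                      level = "component",
                      catalog = read_catalog("results/data/catalog.csv"))

mt <- metrics_table(col)
write.table(mt, "results/metrics.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

curve <- accumulation_curve(col, n_permutations = 100, seed = seed)
write.table(curve, "results/accumulation_curve.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

plateau <- curve$mean_components[col$R] - curve$mean_components[col$R - 5]
cat(sprintf(
  "metrics for %d respondents: mean size %.1f, mean links %.1f, mean density %.3f\n",
  col$R, mean(mt$n_components), mean(mt$n_links), mean(mt$density)))
cat(sprintf(
  "saturation: last 5 respondents add %.1f new components on average (curve endpoint %.0f)\n",
  plateau, curve$mean_components[col$R]))
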