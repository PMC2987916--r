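#!/usr/bin/env Rscript
# Step 4: per-node metrics (degree, clustering, betweenness) and hub tables
# for each group network at the analysis sparsity. A region is a hub when
# its normalized betweenness exceeds 2.
# Usage: Rscript analysis/04_hubs.R [sparsity]
# Requires results/cohorts/ from step 1.

suppressPackageStartupMessages(library(covnet))

args <- commandArgs(trailingOnly = TRUE)
sparsity <- if (length(args) >= 1) as.numeric(args[[1]]) else 0.15

dir.create("results/nodes", recursive = TRUE, showWarnings = FALSE)

hub_rows <- list()
for (g in c("NC", "MCI", "AD")) {
  co <- read_cohort(file.path("results/cohorts", paste0(g, ".csv")),
                    group_label = g)
  net <- threshold_by_sparsity(cohort_correlation(co), sparsity)
  nm <- node_betweenness(net)
  utils::write.csv(nm, file.path("results/nodes",
                                 paste0(g, "_node_metrics.csv")),
                   row.names = FALSE)
  hubs <- detect_hubs(nm)
  if (nrow(hubs) > 0)
    hub_rows[[g]] <- cbind(group = g, hubs)
  cat(sprintf("%-4s %d hubs: %s\n", g, nrow(hubs),
              paste(hubs$abbreviation, collapse = ", ")))
}
utils::write.csv(do.call(rbind, hub_rows), "results/hubs.csv",
                 row.names = FALSE)
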