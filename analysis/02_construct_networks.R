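#!/usr/bin/env Rscript
# Step 2: residualize each cohort (age, sex, total gray-matter volume),
# compute the interregional correlation matrix, threshold it at the analysis
# sparsity, and write the correlation matrix and binary edge list per group.
# Usage: Rscript analysis/02_construct_networks.R [sparsity]
# Requires results/cohorts/ from step 1.

suppressPackageStartupMessages(library(covnet))

args <- commandArgs(trailingOnly = TRUE)
sparsity <- if (length(args) >= 1) as.numeric(args[[1]]) else 0.15

dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)

for (g in c("NC", "MCI", "AD")) {
  co <- read_cohort(file.path("results/cohorts", paste0(g, ".csv")),
                    group_label = g)
  corr <- cohort_correlation(co)
  write_matrix(corr$r, file.path("results/networks",
                                 paste0(g, "_correlation.csv")))
  net <- threshold_by_sparsity(corr, sparsity)
  write_edge_list(net, file.path("results/networks",
                                 paste0(g, "_edges.csv")))
  cat(sprintf("%-4s K = %d edges at sparsity %.2f\n", g, net$K, sparsity))
}
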