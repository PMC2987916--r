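#!/usr/bin/env Rscript
# Step 5: between-group inference.
#  (a) edge-wise Fisher-z comparison with BH-FDR at q = 0.01 for NC-vs-MCI
#      and NC-vs-AD;
#  (b) label-permutation tests of the Cp and Lp differences;
#  (c) bootstrap confidence intervals for each group's Cp and Lp.
# Usage: Rscript analysis/05_group_differences.R [sparsity] [n_perm] [seed]
# Requires results/cohorts/ from step 1.

suppressPackageStartupMessages(library(covnet))

args <- commandArgs(trailingOnly = TRUE)
sparsity <- if (length(args) >= 1) as.numeric(args[[1]]) else 0.15
n_perm <- if (length(args) >= 2) as.integer(args[[2]]) else 1000L
seed <- if (length(args) >= 3) as.integer(args[[3]]) else 1L

dir.create("results/differences", recursive = TRUE, showWarnings = FALSE)

cohorts <- lapply(stats::setNames(nm = c("NC", "MCI", "AD")), function(g)
  read_cohort(file.path("results/cohorts", paste0(g, ".csv")),
              group_label = g))
corrs <- lapply(cohorts, cohort_correlation)

# (a) edge-difference maps
for (g in c("MCI", "AD")) {
  ed <- edge_difference_map(corrs$NC, corrs[[g]], q = 0.01)
  utils::write.csv(ed, file.path("results/differences",
                                 paste0("edges_NC_vs_", g, ".csv")),
                   row.names = FALSE)
  cat(sprintf("NC vs %-4s %d/%d significant edges at q = 0.01\n",
              g, sum(ed$significant), nrow(ed)))
}

# (b) permutation tests of Cp/Lp differences
perm_rows <- list()
for (g in c("MCI", "AD")) {
  pr <- permutation_test_metrics(cohorts$NC, cohorts[[g]],
                                 sparsity = sparsity, n_perm = n_perm,
                                 seed = seed)
  print(pr)
  perm_rows[[g]] <- data.frame(
    comparison = paste0("NC_vs_", g), metric = names(pr$observed),
    observed = unname(pr$observed), ci_lower = unname(pr$ci_lower),
    ci_upper = unname(pr$ci_upper), significant = unname(pr$significant),
    n_perm = n_perm)
}
utils::write.csv(do.call(rbind, perm_rows),
                 "results/differences/permutation_tests.csv",
                 row.names = FALSE)

# (c) bootstrap confidence intervals for Cp and Lp per group
boot_rows <- list()
for (g in names(cohorts)) {
  bt <- bootstrap_metric_ci(cohorts[[g]], sparsity = sparsity,
                            n_boot = 200L, seed = seed,
                            metrics = c("Cp", "Lp"))
  boot_rows[[g]] <- cbind(group = g, bt)
}
boot <- do.call(rbind, boot_rows)
utils::write.csv(boot, "results/differences/bootstrap_ci.csv",
                 row.names = FALSE)
print(boot, digits = 3)
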