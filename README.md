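# covnet

Structural covariance cortical networks from regional gray-matter volumes.

Across a population, the volumes of different brain regions rise and fall
together; the pattern of these across-subject correlations defines a
*structural covariance network*, one graph per diagnostic group. `covnet`
implements the full group-level analysis:

1. **Atlas** — a built-in 90-region cerebral parcellation (45 bilateral
   structures, homotopic pairing, anatomical blocks), plus reduced atlases
   for fast tests.
2. **Network construction** — per-group OLS residualization of volumes
   against age, sex, and total gray-matter volume; Pearson correlation of
   residuals over all 90 × 89 / 2 = 4005 region pairs; sparsity
   thresholding into a binary undirected graph (top |r| pairs,
   deterministic tie-break).
3. **Graph topology** — local clustering and its mean Cp, characteristic
   path length Lp, small-world indices γ = Cp/Cp_rand and λ = Lp/Lp_rand
   against degree-matched, connectivity-preserving rewired surrogates
   (C++ double-edge swap), and betweenness hubs (normalized betweenness
   b > 2).
4. **Group inference** — edge-wise Fisher-z comparison with
   Benjamini–Hochberg FDR at q = 0.01; label-permutation tests of ΔCp and
   ΔLp that re-run the *entire* pipeline on every relabeling; nodal
   betweenness permutation tests; subject-bootstrap confidence intervals.
5. **Synthetic cohorts** — a multivariate-normal generator with block,
   homotopic, and between-block covariance levels, confounds (age, sex,
   global size), and per-group effects, so the pipeline is testable end
   to end without restricted clinical data. `default_three_group_spec()`
   is a frozen NC/MCI/AD-like preset (98/113/91 subjects).

See `vignettes/covnet-methods.Rmd` for the methods in detail.

## Worked example

```r
library(covnet)

spec <- default_three_group_spec(seed = 1)
study <- generate_study(spec)
study$NC
#> <cohort> group 'NC': 98 subjects x 90 regions
#>   age 58.1-91.9, female/male 46/52

corr <- cohort_correlation(study$NC)   # residualize + correlate
net <- threshold_by_sparsity(corr, sparsity = 0.15)
net
#> <binary_network> 90 nodes, K = 601 edges (sparsity 0.150), group 'NC'

small_world_indices(net, n_random = 20, seed = 1)
#> <global_metrics> Cp = 0.2726, Lp = 2.0380, gamma = 1.760, lambda = 1.033 (20 surrogates)

detect_hubs(node_betweenness(net))
#>    region_id abbreviation degree clustering betweenness normalized_betweenness  hub
#> 86        86        MTG.R     22      0.221       125.4                   2.72 TRUE
#> 45        45        CUN.L     20      0.226       106.6                   2.31 TRUE
#> 52        52        MOG.R     19      0.222       106.6                   2.31 TRUE
#> 65        65        ANG.L     21      0.271        99.0                   2.14 TRUE
#> 66        66        ANG.R     23      0.304        97.5                   2.11 TRUE
#> 25        25  ORBsupmed.L     19      0.216        96.6                   2.09 TRUE

permutation_test_metrics(study$NC, study$AD, sparsity = 0.15,
                         n_perm = 1000, seed = 1)
#> <permutation_result> sparsity 0.15, 1000 permutations
#>   dCp = -0.0906, null 95% CI [-0.0766, +0.0995] -> significant
#>   dLp = -0.0674, null 95% CI [-0.1256, +0.1466] -> n.s.
```

## Analysis workflow

The numbered drivers under `analysis/` run the whole study on the default
preset and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohorts -> results/cohorts/
Rscript analysis/02_construct_networks.R   # correlations + edge lists
Rscript analysis/03_small_world.R          # Cp/Lp/gamma/lambda by sparsity
Rscript analysis/04_hubs.R                 # per-node metrics + hub tables
Rscript analysis/05_group_differences.R    # edge FDR, permutation, bootstrap
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "covnet", load_package = "installed")'
```

The suite includes brute-force enumeration oracles for every graph metric
and an acceptance file (`tests/testthat/test-acceptance.R`) covering the
pipeline's structural constants, oracle equivalence, small-world and
group-ordering recovery on the default preset, permutation calibration,
Fisher-z machinery, and FDR control.

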