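test_that("fisher_z matches the closed form and is odd", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("compare_edge matches closed-form hand computation", {
  # rA = 0.5, nA = 103, rB = 0, nB = 103: Z = 0.54931/sqrt(2/100)
  out <- compare_edge(0.5, 103, 0, 103)
  expect_equal(out$z_stat, 0.5 * log(3) / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(out$z_stat, 3.88416, tolerance = 1e-4)
  expect_equal(out$p_value, 2 * stats::pnorm(-0.5 * log(3) / sqrt(2 / 100)),
               tolerance = 1e-12)
  # equal correlations: Z = 0, p = 1
  eq <- compare_edge(0.3, 50, 0.3, 80)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_value, 1)
  # antisymmetry under group swap
  a <- compare_edge(0.6, 40, 0.2, 60)
  b <- compare_edge(0.2, 60, 0.6, 40)
  expect_equal(a$z_stat, -b$z_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(compare_edge(0.5, 3, 0.2, 50), "exceed 3")
})

test_that("null compare_edge p-values are uniform", {
  # bivariate draws with the same true correlation in both groups
  set.seed(51)
  n_rep <- 2000L
  n <- 50L
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    z <- matrix(stats::rnorm(2 * n), ncol = 2)
    x <- z[, 1]
    y1 <- 0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
    z2 <- matrix(stats::rnorm(2 * n), ncol = 2)
    y2 <- 0.5 * z2[, 1] + sqrt(1 - 0.25) * z2[, 2]
    p[i] <- compare_edge(stats::cor(x, y1), n,
                         stats::cor(z2[, 1], y2), n)$p_value
  }
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the FDR mask reproduces the step-up rule", {
  # oracle: hand-applied Benjamini-Hochberg on worked examples.
  # thresholds i/m * q = 0.0125, 0.025, 0.0375, 0.05; every ordered p-value
  # sits below its threshold, so the step-up rule rejects all four
  p <- c(0.001, 0.004, 0.019, 0.03)
  expect_equal(fdr_mask(p, 0.05), c(TRUE, TRUE, TRUE, TRUE))
  # mixed case: thresholds 0.0125, 0.025, 0.0375, 0.05 -> k = 2
  expect_equal(fdr_mask(c(0.001, 0.02, 0.1, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_mask(rep(0.5, 4005), 0.01), rep(FALSE, 4005))
  expect_true(fdr_mask(0.005, 0.01))
  # step-up property on random vectors: compare against direct enumeration
  set.seed(52)
  for (i in 1:20) {
    p <- stats::runif(50)^2
    q <- 0.05
    m <- length(p)
    o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
    oracle <- rep(FALSE, m)
    if (k > 0) oracle[o[seq_len(k)]] <- TRUE
    expect_equal(fdr_mask(p, q), oracle)
  }
  # BY is never more liberal than BH
  set.seed(53)
  p <- stats::runif(200)^3
  expect_true(all(fdr_mask(p, 0.05, "BY") <= fdr_mask(p, 0.05, "BH")))
})

test_that("edge_difference_map finds nothing when groups are identical", {
  set.seed(54)
  r <- stats::cor(matrix(stats::rnorm(40 * 10), 40))
  corr <- fake_corr(r, n_subjects = 40L)
  out <- edge_difference_map(corr, corr, q = 0.5)
  expect_equal(nrow(out), 45L)
  expect_false(any(out$significant))
  expect_true(all(is.na(out$direction)))
  expect_true(all(out$p_value == 1))
})

test_that("edge_difference_map localizes a planted block difference", {
  # two groups share the latent structure except one block's correlation
  atlas <- reduced_atlas(6)   # blocks: sensorimotor / prefrontal / orbitofrontal
  base <- synthetic_spec(
    n_subjects_per_group = c(A = 200L, B = 200L), atlas = atlas,
    within_block_corr = 0.2, homotopic_corr = 0.5,
    between_block_corr = 0.1,
    group_effects = list(B = list(
      within_block_corr = c(prefrontal = 0.6))),
    confound_betas = list(age = 0, sex = 0), global_sd = 0, seed = 55L)
  corrA <- cohort_correlation(generate_cohort(base, "A"))
  corrB <- cohort_correlation(generate_cohort(base, "B"))
  out <- edge_difference_map(corrA, corrB, q = 0.01)
  sig <- out[out$significant, ]
  expect_gt(nrow(sig), 0)
  blk <- function(x) atlas$block[match(x, atlas$abbreviation)]
  in_block <- blk(sig$region_i) == "prefrontal" &
    blk(sig$region_j) == "prefrontal"
  expect_gte(mean(in_block), 0.8)
  # homotopic pairs keep their own correlation level in both groups, so only
  # the non-homotopic within-block pairs carry the planted increase
  id_i <- atlas$region_id[match(sig$region_i, atlas$abbreviation)]
  id_j <- atlas$region_id[match(sig$region_j, atlas$abbreviation)]
  homot <- atlas$homotopic_partner_id[match(id_i, atlas$region_id)] == id_j
  expect_true(all(sig$direction[in_block & !homot] == "increase"))
  # swapping the groups flips direction, keeps p-values
  rev <- edge_difference_map(corrB, corrA, q = 0.01)
  expect_equal(rev$p_value, out$p_value, tolerance = 1e-12)
  expect_equal(rev$significant, out$significant)
})

test_that("mismatched atlases are refused", {
  rA <- fake_corr(diag(10), atlas = reduced_atlas(5))
  rB <- fake_corr(diag(12), atlas = reduced_atlas(6))
  expect_error(edge_difference_map(rA, rB, 0.05), "different atlases")
})

test_that("permutation test accepts the null on an exchangeable split", {
  spec <- small_spec(n = c(A = 80L), n_pairs = 5L, seed = 61L)
  co <- generate_cohort(spec, "A")
  half <- seq_len(40)
  mk <- function(idx, lab) new_cohort(co$volumes[idx, ],
                                      co$covariates[idx, ], lab,
                                      atlas = co$atlas)
  a <- mk(half, "A1"); b <- mk(-half, "A2")
  res <- permutation_test_metrics(a, b, sparsity = 0.5, n_perm = 200L,
                                  seed = 62L)
  expect_false(any(res$significant))
  expect_equal(nrow(res$null), 200L)
  # the spec invariant: swapping the groups flips signs, keeps decisions
  res2 <- permutation_test_metrics(b, a, sparsity = 0.5, n_perm = 200L,
                                   seed = 62L)
  expect_equal(res2$observed, -res$observed, tolerance = 1e-12)
  expect_equal(res2$significant, res$significant)
})

test_that("permutation test detects a strong planted covariance difference", {
  atlas <- reduced_atlas(8)
  spec <- synthetic_spec(
    n_subjects_per_group = c(NC = 200L, AD = 200L), atlas = atlas,
    within_block_corr = 0.25, homotopic_corr = 0.6,
    between_block_corr = 0.15,
    group_effects = list(AD = list(within_block_corr = 0.55)),
    seed = 63L)
  study <- generate_study(spec)
  res <- permutation_test_metrics(study$NC, study$AD, sparsity = 0.5,
                                  n_perm = 200L, seed = 64L)
  # stronger within-block covariance in AD segregates the network: longer
  # characteristic paths (clearly outside the null band) and larger Cp
  expect_true(res$significant[["dLp"]])
  expect_lt(res$observed[["dLp"]], 0)  # AD has the longer paths
  expect_lt(res$observed[["dCp"]], 0)  # AD has the larger Cp
})

test_that("nodal permutation test returns calibrated per-node p-values", {
  spec <- small_spec(n = c(A = 80L), n_pairs = 5L, seed = 65L)
  co <- generate_cohort(spec, "A")
  half <- seq_len(40)
  mk <- function(idx, lab) new_cohort(co$volumes[idx, ],
                                      co$covariates[idx, ], lab,
                                      atlas = co$atlas)
  out <- permutation_test_nodal(mk(half, "A1"), mk(-half, "A2"),
                                sparsity = 0.5, n_perm = 99L, seed = 66L)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$p_uncorrected > 0 & out$p_uncorrected <= 1))
  expect_true(all(out$p_bh >= out$p_uncorrected - 1e-12))
  # under the null nothing should survive BH at a strict level
  expect_false(any(out$p_bh < 0.01))
})

test_that("bootstrap intervals are reproducible and degenerate at n_boot = 1", {
  spec <- small_spec(n = c(A = 60L), n_pairs = 5L, seed = 71L)
  co <- generate_cohort(spec, "A")
  b1 <- bootstrap_metric_ci(co, sparsity = 0.5, n_boot = 1L, seed = 72L,
                            metrics = c("Cp", "Lp"))
  expect_equal(b1$ci_lower, b1$ci_upper, tolerance = 1e-12)
  b2 <- bootstrap_metric_ci(co, sparsity = 0.5, n_boot = 30L, seed = 73L,
                            metrics = c("Cp", "Lp"))
  b3 <- bootstrap_metric_ci(co, sparsity = 0.5, n_boot = 30L, seed = 73L,
                            metrics = c("Cp", "Lp"))
  expect_identical(b2, b3)
  expect_true(all(b2$se > 0))
})

test_that("the bootstrap SE of Cp shrinks with larger cohorts", {
  se_at <- function(n, seed) {
    spec <- synthetic_spec(n_subjects_per_group = c(A = n),
                           atlas = reduced_atlas(5), seed = seed)
    co <- generate_cohort(spec, "A")
    b <- bootstrap_metric_ci(co, sparsity = 0.5, n_boot = 100L, seed = 74L,
                             metrics = "Cp")
    b$se
  }
  # a tenfold larger cohort shrinks the bootstrap SE; shrinkage is damped by
  # rank ties at the sparsity cutoff, so average over two cohort draws
  expect_lt(mean(c(se_at(500L, 75L), se_at(500L, 76L))),
            mean(c(se_at(50L, 75L), se_at(50L, 76L))))
})
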