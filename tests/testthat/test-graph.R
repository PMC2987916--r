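test_that("sparsity thresholding selects the top-|r| pairs deterministically", {
  # 5-node toy (odd n not needed; use a 3-pair reduced atlas = 6 nodes)
  set.seed(41)
  r <- matrix(stats::runif(36, -1, 1), 6)
  r <- (r + t(r)) / 2
  corr <- fake_corr(r, atlas = reduced_atlas(3))
  K <- 3L
  net <- threshold_by_sparsity(corr, K / 15)
  expect_equal(net$K, K)
  # oracle: exhaustive sort of |r| over the upper triangle
  ut <- which(upper.tri(r), arr.ind = TRUE)
  top <- ut[order(-abs(r[ut]))[seq_len(K)], , drop = FALSE]
  expect_true(all(net$adjacency[top]))
  expect_equal(sum(net$adjacency) / 2, K)
})

test_that("thresholding at sparsity 1 yields the complete graph (4005 edges)", {
  set.seed(42)
  r <- matrix(stats::rnorm(90 * 90), 90)
  r <- (r + t(r)) / 2
  corr <- fake_corr(r, atlas = aal_region_table())
  net <- threshold_by_sparsity(corr, 1)
  expect_equal(net$K, 4005L)
  expect_true(all(net$adjacency[upper.tri(net$adjacency)]))
  expect_warning(empty <- threshold_by_sparsity(corr, 1e-5), "K = 0")
  expect_equal(empty$K, 0L)
  expect_error(threshold_by_sparsity(corr, 0), "sparsity")
  expect_error(threshold_by_sparsity(corr, 1.2), "sparsity")
})

test_that("edge sets are nested across increasing sparsity", {
  set.seed(43)
  r <- matrix(stats::rnorm(20 * 20), 20)
  r <- (r + t(r)) / 2
  corr <- fake_corr(r, atlas = reduced_atlas(10))
  nets <- lapply(c(0.1, 0.2, 0.4, 0.8), function(s)
    threshold_by_sparsity(corr, s)$adjacency)
  for (i in 1:3)
    expect_true(all(nets[[i + 1]][nets[[i]]]))
})

test_that("positive-only ranking drops strong negative correlations", {
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- -0.9
  r[3, 4] <- r[4, 3] <- 0.5
  r[5, 6] <- r[6, 5] <- 0.4
  corr <- fake_corr(r, atlas = reduced_atlas(3))
  by_mag <- threshold_by_sparsity(corr, 1 / 15)
  expect_true(by_mag$adjacency[1, 2])
  by_pos <- threshold_by_sparsity(corr, 1 / 15, rank_by = "positive")
  expect_false(by_pos$adjacency[1, 2])
  expect_true(by_pos$adjacency[3, 4])
})

test_that("clustering matches hand-enumerated cases", {
  # complete graph on 4 nodes: all C_i = 1
  k4 <- toy_network(matrix(1, 4, 4) - diag(4))
  cc <- clustering_coefficient(k4)
  expect_equal(cc$per_node, rep(1, 4))
  expect_equal(cc$Cp, 1)
  # star: no neighbour-neighbour edges anywhere
  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  cs <- clustering_coefficient(toy_network(star))
  expect_equal(cs$per_node, rep(0, 6))
  # triangle plus pendant on one corner: that corner has C = 1/3
  tri <- matrix(0, 4, 4)
  tri[1, 2] <- tri[2, 3] <- tri[1, 3] <- tri[1, 4] <- 1
  tri <- tri + t(tri)
  ct <- clustering_coefficient(toy_network(tri))
  expect_equal(ct$per_node, c(1 / 3, 1, 1, 0))
})

test_that("path lengths match enumeration and disconnection is an error", {
  k5 <- toy_network(matrix(1, 5, 5) - diag(5))
  expect_equal(mean_path_length(k5)$Lp, 1)
  # path graph on 3 nodes: per-node means (1.5, 1, 1.5)
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  lp <- mean_path_length(toy_network(p3))
  expect_equal(lp$per_node, c(1.5, 1, 1.5))
  expect_equal(lp$Lp, 4 / 3)
  # two disjoint edges: error carries component sizes
  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[3, 4] <- 1
  disc <- disc + t(disc)
  expect_error(mean_path_length(toy_network(disc)), "2, 2")
})

test_that("betweenness matches hand-derived values and the hub rule", {
  # star with 5 leaves: center B = choose(5,2) = 10, b = 6, sole hub
  star <- matrix(0, 6, 6); star[1, 2:6] <- star[2:6, 1] <- 1
  nm <- node_betweenness(toy_network(star))
  expect_equal(nm$betweenness, c(10, rep(0, 5)))
  expect_equal(nm$normalized_betweenness, c(6, rep(0, 5)))
  expect_equal(which(nm$hub), 1L)
  hubs <- detect_hubs(nm)
  expect_equal(nrow(hubs), 1L)
  # cycle: all nodes equivalent, b = 1, no hubs
  cyc <- ring_lattice(7, 1)
  nc <- node_betweenness(toy_network(cyc))
  expect_equal(nc$normalized_betweenness, rep(1, 7))
  expect_false(any(nc$hub))
  # complete graph: all-zero betweenness handled with a warning
  k4 <- toy_network(matrix(1, 4, 4) - diag(4))
  expect_warning(nk <- node_betweenness(k4), "zero")
  expect_equal(nk$normalized_betweenness, rep(0, 4))
})

test_that("Cp, Lp and betweenness agree with brute-force oracles on random
           small graphs", {
  set.seed(44)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    adj <- random_connected_graph(n, p = stats::runif(1, 0.3, 0.8))
    net <- toy_network(adj)
    expect_equal(clustering_coefficient(net)$per_node, bf_clustering(adj))
    d <- bf_distances(adj)
    expect_equal(mean_path_length(net)$Lp,
                 mean(rowSums(d) / (n - 1)))
    nm <- suppressWarnings(node_betweenness(net))
    expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("rewiring preserves the degree sequence and connectivity", {
  set.seed(45)
  spec <- default_three_group_spec(seed = 2L)
  co <- generate_cohort(spec, "NC")
  net <- threshold_by_sparsity(cohort_correlation(co), 0.15)
  deg <- rowSums(net$adjacency)
  for (s in 1:3) {
    r <- rewire_preserving_degrees(net, n_swaps = 200L, seed = s)
    expect_equal(rowSums(r$adjacency), deg)
    expect_true(covnet:::is_connected_network(r))
    expect_false(identical(r$adjacency, net$adjacency))
  }
  # determinism under a fixed seed
  r1 <- rewire_preserving_degrees(net, n_swaps = 100L, seed = 9L)
  r2 <- rewire_preserving_degrees(net, n_swaps = 100L, seed = 9L)
  expect_identical(r1$adjacency, r2$adjacency)
})

test_that("a triangle cannot be rewired", {
  tri <- matrix(1, 3, 3) - diag(3)
  net <- toy_network(tri)
  expect_warning(r <- rewire_preserving_degrees(net, n_swaps = 5L,
                                                seed = 1L,
                                                max_tries = 200),
                 "budget")
  expect_identical(r$adjacency, net$adjacency)
})

test_that("rewiring destroys lattice clustering", {
  # ring lattice, 90 nodes, degree 6: high clustering by construction
  adj <- ring_lattice(90, 3)
  net <- toy_network(adj)
  cp0 <- clustering_coefficient(net)$Cp
  below <- 0
  for (s in 1:100) {
    r <- rewire_preserving_degrees(net, seed = s)  # 10 * K swaps
    if (clustering_coefficient(r)$Cp < cp0) below <- below + 1
  }
  expect_gte(below, 95)
})

test_that("small-world indices are 1 against the network itself and
           reproducible under a seed", {
  spec <- default_three_group_spec(seed = 3L)
  co <- generate_cohort(spec, "NC")
  net <- threshold_by_sparsity(cohort_correlation(co), 0.15)
  self <- small_world_indices(net, n_random = 1L, seed = 1L, n_swaps = 0L)
  expect_equal(self$gamma, 1)
  expect_equal(self$lambda, 1)
  sw1 <- small_world_indices(net, n_random = 5L, seed = 17L)
  sw2 <- small_world_indices(net, n_random = 5L, seed = 17L)
  expect_identical(sw1, sw2)
  expect_gt(sw1$gamma, 1)
})

test_that("a lightly rewired ring lattice is small-world", {
  # ~90 nodes, K ~ 600: a lattice with a few shortcuts
  adj <- ring_lattice(90, 7)   # degree 14, K = 630
  net <- toy_network(adj)
  light <- rewire_preserving_degrees(net, n_swaps = 60L, seed = 5L)
  sw <- small_world_indices(light, n_random = 10L, seed = 6L)
  expect_gt(sw$gamma, 1)
  expect_gte(sw$lambda, 0.9)
  expect_lte(sw$lambda, 1.3)
})
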