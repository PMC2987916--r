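# Sparsity thresholding, small-world metrics, degree-matched null models and
# betweenness hub detection.

#' @useDynLib covnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a correlation matrix into a binary network at a given sparsity
#'
#' Sparsity S is the edge count K divided by the maximum possible number of
#' edges N(N-1)/2 (4005 for 90 regions). The K = round(S * N(N-1)/2) region
#' pairs with the largest correlations become the edges of an undirected,
#' unweighted graph; every group network thresholded at the same sparsity
#' therefore has the same number of nodes and edges.
#'
#' @param corr a `correlation_matrix`.
#' @param sparsity target sparsity in (0, 1].
#' @param rank_by `"magnitude"` (default) ranks pairs by |r|, so strong
#'   negative correlations also form edges; `"positive"` ranks by signed r.
#' @return an object of class `binary_network`: list with `adjacency`
#'   (logical regions x regions, zero diagonal), `K`, `sparsity` (realized
#'   K / N(N-1)/2), `atlas`, `group_label`.
#' @export
threshold_by_sparsity <- function(corr, sparsity,
                                  rank_by = c("magnitude", "positive")) {
  stopifnot(inherits(corr, "correlation_matrix"))
  rank_by <- match.arg(rank_by)
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1)
    stop("sparsity must lie in (0, 1]")
  n <- nrow(corr$r)
  max_k <- n * (n - 1L) / 2L
  K <- as.integer(round_half_up(sparsity * max_k))
  if (K == 0L)
    warning("requested sparsity yields K = 0; returning an empty network")
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  score <- corr$r[ut]
  if (rank_by == "magnitude") score <- abs(score)
  # largest score first; ties broken lexicographically by (i, j)
  ord <- order(-score, ut[, 1L], ut[, 2L])
  adj <- matrix(FALSE, n, n, dimnames = dimnames(corr$r))
  if (K > 0L) {
    sel <- ut[ord[seq_len(K)], , drop = FALSE]
    adj[sel] <- TRUE
    adj[sel[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  structure(
    list(adjacency = adj, K = K, sparsity = K / max_k,
         atlas = corr$atlas, group_label = corr$group_label),
    class = "binary_network")
}

#' Build a binary network directly from an adjacency matrix
#'
#' @param adjacency symmetric logical/0-1 matrix with zero diagonal.
#' @param atlas atlas for the nodes; defaults to a reduced atlas sized to fit
#'   when `nrow(adjacency)` is even, else labels nodes `V1..Vn`.
#' @param group_label optional label.
#' @return a `binary_network`.
#' @export
binary_network <- function(adjacency, atlas = NULL, group_label = "") {
  adj <- adjacency != 0
  n <- nrow(adj)
  stopifnot(ncol(adj) == n)
  if (!isSymmetric(unname(adj * 1)))
    stop("adjacency must be symmetric")
  diag(adj) <- FALSE
  K <- sum(adj) / 2L
  structure(
    list(adjacency = adj, K = as.integer(K),
         sparsity = if (n > 1L) K / (n * (n - 1L) / 2L) else 0,
         atlas = atlas, group_label = group_label),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat("<binary_network> ", nrow(x$adjacency), " nodes, K = ", x$K,
      " edges (sparsity ", sprintf("%.3f", x$sparsity), ")",
      if (nzchar(x$group_label)) paste0(", group '", x$group_label, "'"),
      "\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency * 1,
                                      mode = "undirected", diag = FALSE)
}

#' Per-node clustering coefficients and their network mean Cp
#'
#' C_i is the number of edges among node i's neighbors divided by the number
#' of possible such edges, k_i(k_i-1)/2; nodes of degree < 2 get C_i = 0 and
#' are included in the mean.
#'
#' @param net a `binary_network`.
#' @return list with `per_node` (numeric vector) and `Cp` (mean).
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  # integer triangle and degree counts keep the ratio exact (a single
  # correctly rounded division per node)
  tri <- igraph::count_triangles(g)
  k <- igraph::degree(g)
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(per_node = ci, Cp = mean(ci))
}

#' All-pairs shortest-path distances of a binary network
#'
#' Unweighted breadth-first distances in edge-count units. The network must
#' be connected (the sparsity range is chosen in practice so that group
#' networks are fully connected).
#'
#' @param net a `binary_network`.
#' @return integer-valued distance matrix.
#' @export
shortest_path_matrix <- function(net) {
  assert_connected(net)
  igraph::distances(as_igraph(net))
}

#' Characteristic (absolute) path length Lp
#'
#' L_i is node i's mean shortest-path distance to the other N-1 nodes; Lp is
#' the mean of L_i over nodes (equivalently the mean pairwise distance).
#'
#' @param net a connected `binary_network`.
#' @return list with `per_node` and `Lp`.
#' @export
mean_path_length <- function(net) {
  d <- shortest_path_matrix(net)
  n <- nrow(d)
  li <- rowSums(d) / (n - 1L)
  list(per_node = li, Lp = mean(li))
}

assert_connected <- function(net) {
  comp <- igraph::components(as_igraph(net))
  if (comp$no > 1L)
    stop("network is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "), ")")
  invisible(net)
}

is_connected_network <- function(net) {
  igraph::is_connected(as_igraph(net))
}

#' Betweenness centrality, normalized betweenness and hub flags
#'
#' Raw betweenness B_i credits node i fractionally over multiple shortest
#' paths: for each unordered pair (s, t) with s, t != i, i receives
#' sigma_st(i) / sigma_st. Normalized betweenness is b_i = B_i / mean(B); a
#' node with b_i > 2 (more than twice the network-average betweenness) is a
#' hub. If every B_i is zero (e.g. a complete graph) all b_i are defined as 0
#' and no hubs are reported, with a warning.
#'
#' @param net a connected `binary_network`.
#' @return a data frame with one row per node: `region_id`, `abbreviation`
#'   (when the network has an atlas), `degree`, `clustering`, `betweenness`,
#'   `normalized_betweenness`, `hub`.
#' @export
node_betweenness <- function(net) {
  assert_connected(net)
  g <- as_igraph(net)
  B <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  mB <- mean(B)
  if (mB == 0) {
    warning("all betweenness values are zero; normalized betweenness set ",
            "to 0, no hubs")
    b <- rep(0, length(B))
  } else {
    b <- B / mB
  }
  out <- data.frame(
    region_id = seq_along(B),
    degree = as.integer(rowSums(net$adjacency)),
    clustering = clustering_coefficient(net)$per_node,
    betweenness = as.numeric(B),
    normalized_betweenness = b,
    hub = b > 2)
  if (!is.null(net$atlas)) {
    out$region_id <- net$atlas$region_id
    out <- cbind(out[1L], abbreviation = net$atlas$abbreviation,
                 out[-1L])
  }
  rownames(out) <- NULL
  out
}

#' Hub regions of a network
#'
#' @param metrics the data frame from [node_betweenness()] (a
#'   `binary_network` is also accepted).
#' @return the rows with `hub = TRUE`, sorted by descending normalized
#'   betweenness — the layout of a hub table.
#' @export
detect_hubs <- function(metrics) {
  if (inherits(metrics, "binary_network")) metrics <- node_betweenness(metrics)
  hubs <- metrics[metrics$hub, , drop = FALSE]
  hubs[order(-hubs$normalized_betweenness), , drop = FALSE]
}

#' Degree-preserving, connectivity-preserving rewiring
#'
#' Randomizes topology by repeated double-edge swaps: edges (a,b) and (c,d)
#' are replaced by (a,d) and (c,b), rejecting proposals that would create a
#' self-loop or multi-edge or disconnect the graph. The degree sequence is
#' exactly preserved, giving the degree-matched random surrogates that
#' small-world ratios are computed against.
#'
#' @param net a connected `binary_network` with at least 2 edges.
#' @param n_swaps accepted swaps to perform (default 10 * K).
#' @param seed optional seed (caller RNG state is preserved).
#' @param max_tries proposal budget; if exhausted first, the current network
#'   is returned with a warning and the accepted count as attribute
#'   `"accepted"`.
#' @return a rewired `binary_network`.
#' @export
rewire_preserving_degrees <- function(net, n_swaps = 10L * net$K,
                                      seed = NULL,
                                      max_tries = 100 * n_swaps) {
  stopifnot(inherits(net, "binary_network"), net$K >= 2L)
  assert_connected(net)
  edges <- which(upper.tri(net$adjacency) & net$adjacency, arr.ind = TRUE)
  run <- function() rewire_edges_cpp(unname(edges), nrow(net$adjacency),
                                     as.integer(n_swaps),
                                     as.double(max_tries))
  out <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  accepted <- attr(out, "accepted")
  if (accepted < n_swaps)
    warning("rewiring budget exhausted after ", accepted, " of ", n_swaps,
            " swaps")
  adj <- matrix(FALSE, nrow(net$adjacency), ncol(net$adjacency),
                dimnames = dimnames(net$adjacency))
  adj[out] <- TRUE
  adj[out[, c(2L, 1L), drop = FALSE]] <- TRUE
  res <- net
  res$adjacency <- adj
  attr(res, "accepted") <- accepted
  res
}

#' Small-world indices against degree-matched random surrogates
#'
#' Computes Cp and Lp of the network and of `n_random` rewired surrogates
#' (each rewired with `10 * K` accepted double-edge swaps), then the
#' small-world ratios gamma = Cp / mean(Cp_rand) and
#' lambda = Lp / mean(Lp_rand). A network is small-world when gamma > 1 and
#' lambda is close to 1.
#'
#' @param net a connected `binary_network`.
#' @param n_random number of surrogates (>= 1).
#' @param seed seed making the surrogate ensemble reproducible.
#' @param n_swaps accepted swaps per surrogate; `0` compares the network
#'   against itself (gamma = lambda = 1).
#' @return list of class `global_metrics`: `Cp`, `Lp`, `Cp_rand`, `Lp_rand`,
#'   `gamma`, `lambda`, `n_random`, `connected`.
#' @export
small_world_indices <- function(net, n_random = 100L, seed = NULL,
                                n_swaps = 10L * net$K) {
  stopifnot(n_random >= 1L)
  assert_connected(net)
  cp <- clustering_coefficient(net)$Cp
  lp <- mean_path_length(net)$Lp
  compute <- function() {
    vapply(seq_len(n_random), function(i) {
      r <- if (n_swaps == 0L) net
           else rewire_preserving_degrees(net, n_swaps = n_swaps)
      c(clustering_coefficient(r)$Cp, mean_path_length(r)$Lp)
    }, numeric(2L))
  }
  rand <- if (is.null(seed)) compute()
          else with_preserved_seed(seed, compute())
  cp_rand <- mean(rand[1L, ])
  lp_rand <- mean(rand[2L, ])
  structure(
    list(Cp = cp, Lp = lp, Cp_rand = cp_rand, Lp_rand = lp_rand,
         gamma = cp / cp_rand, lambda = lp / lp_rand,
         n_random = as.integer(n_random), connected = TRUE),
    class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(
    "<global_metrics> Cp = %.4f, Lp = %.4f, gamma = %.3f, lambda = %.3f (%d surrogates)\n",
    x$Cp, x$Lp, x$gamma, x$lambda, x$n_random))
  invisible(x)
}
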