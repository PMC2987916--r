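# Independent brute-force oracles for graph metrics, plus small fixture
# builders. These deliberately avoid igraph and the package's own code paths.

# per-node clustering by direct neighbour-pair enumeration
bf_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] != 0) e <- e + 1
    2 * e / (k * (k - 1))
  })
}

# all-pairs shortest path lengths by Floyd-Warshall
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# betweenness by explicit enumeration of every shortest path (tiny graphs
# only): DFS over all simple paths between each pair, keeping the shortest
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      for (u in which(adj[v, ] != 0))
        if (!u %in% path) walk(c(path, u))
    }
    walk(s)
    out
  }
  B <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    sigma <- length(sp)
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner) > 0) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      B[idx] <- B[idx] + as.numeric(tab) / sigma
    }
  }
  B
}

# random connected undirected simple graph on n nodes
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    d <- bf_distances(adj)
    if (all(is.finite(d))) return(adj)
  }
}

# wrap a plain symmetric matrix as a correlation_matrix on a fitting atlas
fake_corr <- function(r, n_subjects = 100L, group_label = "toy",
                      atlas = NULL) {
  if (is.null(atlas)) atlas <- reduced_atlas(nrow(r) / 2)
  diag(r) <- 1
  dimnames(r) <- list(atlas$abbreviation, atlas$abbreviation)
  structure(list(r = r, n_subjects = n_subjects,
                 group_label = group_label, atlas = atlas),
            class = "correlation_matrix")
}

# binary_network from a plain adjacency matrix without an atlas
toy_network <- function(adj) binary_network(adj)

# small synthetic spec on a reduced atlas, for fast end-to-end tests
small_spec <- function(n = c(A = 60L, B = 60L), n_pairs = 5L, seed = 1L,
                       ...) {
  synthetic_spec(n_subjects_per_group = n, atlas = reduced_atlas(n_pairs),
                 seed = seed, ...)
}

# ring lattice on n nodes, each connected to k nearest neighbours per side
ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k)) {
    j <- ((i - 1 + s) %% n) + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}
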