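# Between-group inference: Fisher-z edge comparison with FDR control,
# label-permutation tests of network metrics, and bootstrap error bars.

#' Fisher's z transformation of a correlation coefficient
#'
#' z = arctanh(r) = 0.5 * log((1 + r) / (1 - r)); for a Pearson correlation
#' from n subjects, z is approximately normal with variance 1 / (n - 3).
#'
#' @param r correlation value(s), |r| < 1.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisher_z is defined only for |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Compare two independent correlation coefficients
#'
#' Z = (z(rA) - z(rB)) / sqrt(1/(nA-3) + 1/(nB-3)), with a two-tailed
#' standard-normal p-value — the classical test for the difference of two
#' correlations after Fisher's z transformation.
#'
#' @param rA,rB correlations, |r| < 1.
#' @param nA,nB group sizes (>= 4).
#' @return list with `z_stat` and `p_value` (vectors if inputs are vectors).
#' @export
compare_edge <- function(rA, nA, rB, nB) {
  if (any(c(nA, nB) <= 3L))
    stop("group sizes must exceed 3 (Fisher-z variance undefined)")
  z <- (fisher_z(rA) - fisher_z(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  list(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' False-discovery-rate rejection mask
#'
#' Benjamini–Hochberg step-up control at level `q` (default): with m ordered
#' p-values, reject the k largest-ranked with p_(k) <= k q / m.
#' `method = "BY"` applies the Benjamini–Yekutieli variant, valid under
#' arbitrary dependence.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @param method `"BH"` (default) or `"BY"`.
#' @return logical rejection vector of the same length.
#' @export
fdr_mask <- function(p_values, q, method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  stats::p.adjust(p_values, method = method) <= q
}

#' Edge-wise between-group correlation differences with FDR control
#'
#' Applies [compare_edge()] to every unordered region pair of two group
#' correlation matrices and controls the false discovery rate over the
#' N(N-1)/2 tests (4005 on the full atlas). Direction is the sign of
#' rB - rA: `increase` means the correlation is larger in group B.
#'
#' @param corrA,corrB `correlation_matrix` objects on the same atlas.
#' @param q FDR level (the reference analysis uses q = 0.01).
#' @param method FDR procedure, see [fdr_mask()].
#' @return data frame with one row per pair: `region_i`, `region_j` (atlas
#'   abbreviations, i < j), `rA`, `rB`, `z_stat`, `p_value`, `significant`,
#'   `direction` (`NA` for non-significant pairs).
#' @export
edge_difference_map <- function(corrA, corrB, q = 0.01,
                                method = c("BH", "BY")) {
  stopifnot(inherits(corrA, "correlation_matrix"),
            inherits(corrB, "correlation_matrix"))
  if (!identical(corrA$atlas$abbreviation, corrB$atlas$abbreviation))
    stop("the two correlation matrices are on different atlases")
  ut <- which(upper.tri(corrA$r), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  rA <- corrA$r[ut]
  rB <- corrB$r[ut]
  cmp <- compare_edge(rA, corrA$n_subjects, rB, corrB$n_subjects)
  sig <- fdr_mask(cmp$p_value, q, method = method)
  direction <- ifelse(sig, ifelse(rB > rA, "increase", "decrease"),
                      NA_character_)
  data.frame(
    region_i = corrA$atlas$abbreviation[ut[, 1L]],
    region_j = corrA$atlas$abbreviation[ut[, 2L]],
    rA = rA, rB = rB,
    z_stat = cmp$z_stat, p_value = cmp$p_value,
    significant = sig, direction = direction,
    stringsAsFactors = FALSE)
}

# ---- fast internal pipeline: volumes + covariates -> Cp/Lp -----------------

# OLS residuals against intercept + age + sex + total volume (constant
# covariates silently dropped here: the permutation loop may produce them).
.residualize_mat <- function(vol, age, sex, tgv) {
  X <- cbind(1, age, sex, tgv)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2L,
                        function(v) stats::var(v) > 0))
  qr.resid(qr(X[, keep, drop = FALSE]), vol)
}

# Adjacency at edge count K from a correlation matrix (deterministic ties).
.threshold_adj <- function(rmat, K, rank_by = "magnitude") {
  n <- nrow(rmat)
  ut <- which(upper.tri(rmat), arr.ind = TRUE)
  score <- rmat[ut]
  if (rank_by == "magnitude") score <- abs(score)
  ord <- order(-score, ut[, 1L], ut[, 2L])
  adj <- matrix(FALSE, n, n)
  if (K > 0L) {
    sel <- ut[ord[seq_len(K)], , drop = FALSE]
    adj[sel] <- TRUE
    adj[sel[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  adj
}

# c(Cp, Lp) of an adjacency matrix, or c(NA, NA) if disconnected.
.global_cp_lp <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  if (!igraph::is_connected(g)) return(c(NA_real_, NA_real_))
  tri <- igraph::count_triangles(g)
  k <- igraph::degree(g)
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  d <- igraph::distances(g)
  n <- nrow(adj)
  c(mean(ci), mean(rowSums(d) / (n - 1L)))
}

# Normalized betweenness vector of an adjacency matrix (NA if disconnected).
.normalized_betweenness <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  if (!igraph::is_connected(g)) return(rep(NA_real_, nrow(adj)))
  B <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  if (mean(B) == 0) rep(0, length(B)) else B / mean(B)
}

# Full per-group pipeline on raw pieces; statistic = "global" gives c(Cp,Lp),
# "node-betweenness" gives the per-node normalized betweenness vector.
.pipeline_stat <- function(vol, age, sex, tgv, K, rank_by, statistic) {
  res <- .residualize_mat(vol, age, sex, tgv)
  sds <- matrixStats_colSds(res)
  if (any(sds == 0)) return(NULL)
  adj <- .threshold_adj(stats::cor(res), K, rank_by)
  if (statistic == "global") .global_cp_lp(adj)
  else .normalized_betweenness(adj)
}

matrixStats_colSds <- function(m) {
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1L))
}

# ---- permutation tests -----------------------------------------------------

#' Label-permutation test of between-group network metric differences
#'
#' Computes the observed difference (group A minus group B) in Cp and Lp at
#' a fixed sparsity, running the full per-group pipeline (residualize,
#' correlate, threshold, metrics), then builds a null distribution by
#' pooling the subjects, randomly relabeling them into pseudo-groups of the
#' original sizes `n_perm` times, and re-running the full pipeline — with
#' residualization recomputed within each pseudo-group — for every
#' relabeling. The observed difference is declared significant at the 5%
#' level (two-tailed) when it falls outside the null's 2.5th–97.5th
#' percentile interval. Relabelings whose pseudo-networks are disconnected
#' at the given sparsity are redrawn (the count is returned).
#'
#' @param cohortA,cohortB `cohort` objects on the same atlas.
#' @param sparsity sparsity used for every (pseudo-)network.
#' @param n_perm number of relabelings (the reference analysis uses 1000;
#'   fewer than 100 draws a warning).
#' @param seed integer seed.
#' @param rank_by edge ranking rule, see [threshold_by_sparsity()].
#' @return object of class `permutation_result`: list with `sparsity`,
#'   `observed` (named `dCp`, `dLp`), `null` (n_perm x 2 matrix), `ci_lower`,
#'   `ci_upper`, `significant` (named logical), `n_perm`, `seed`,
#'   `n_redrawn`.
#' @export
permutation_test_metrics <- function(cohortA, cohortB, sparsity,
                                     n_perm = 1000L, seed = 1L,
                                     rank_by = "magnitude") {
  stopifnot(inherits(cohortA, "cohort"), inherits(cohortB, "cohort"))
  if (!identical(cohortA$atlas$abbreviation, cohortB$atlas$abbreviation))
    stop("cohorts are on different atlases")
  if (n_perm < 100L)
    warning("n_perm < 100 gives unstable 2.5/97.5 percentiles")
  n_reg <- ncol(cohortA$volumes)
  K <- as.integer(round_half_up(sparsity * n_reg * (n_reg - 1L) / 2L))
  pieces <- function(co) list(vol = co$volumes, age = co$covariates$age,
                              sex = co$covariates$sex,
                              tgv = co$covariates$total_gm_volume)
  a <- pieces(cohortA); b <- pieces(cohortB)
  obs_a <- .pipeline_stat(a$vol, a$age, a$sex, a$tgv, K, rank_by, "global")
  obs_b <- .pipeline_stat(b$vol, b$age, b$sex, b$tgv, K, rank_by, "global")
  if (is.null(obs_a) || is.null(obs_b) || anyNA(c(obs_a, obs_b)))
    stop("a group network is disconnected (or degenerate) at sparsity ",
         sparsity)
  observed <- c(dCp = obs_a[1L] - obs_b[1L], dLp = obs_a[2L] - obs_b[2L])
  vol <- rbind(a$vol, b$vol)
  age <- c(a$age, b$age); sex <- c(a$sex, b$sex); tgv <- c(a$tgv, b$tgv)
  nA <- nrow(a$vol); nTot <- nrow(vol)
  null <- matrix(NA_real_, n_perm, 2L,
                 dimnames = list(NULL, c("dCp", "dLp")))
  n_redrawn <- 0L
  with_preserved_seed(seed, {
    for (p in seq_len(n_perm)) {
      repeat {
        idx <- sample.int(nTot, nA)
        pa <- .pipeline_stat(vol[idx, , drop = FALSE], age[idx], sex[idx],
                             tgv[idx], K, rank_by, "global")
        pb <- .pipeline_stat(vol[-idx, , drop = FALSE], age[-idx],
                             sex[-idx], tgv[-idx], K, rank_by, "global")
        if (!is.null(pa) && !is.null(pb) && !anyNA(c(pa, pb))) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 50L * n_perm)
          stop("too many disconnected pseudo-networks at this sparsity")
      }
      null[p, ] <- c(pa[1L] - pb[1L], pa[2L] - pb[2L])
    }
  })
  ci_lower <- apply(null, 2L, stats::quantile, probs = 0.025, names = FALSE)
  ci_upper <- apply(null, 2L, stats::quantile, probs = 0.975, names = FALSE)
  significant <- observed < ci_lower | observed > ci_upper
  structure(
    list(sparsity = sparsity, observed = observed, null = null,
         ci_lower = stats::setNames(ci_lower, c("dCp", "dLp")),
         ci_upper = stats::setNames(ci_upper, c("dCp", "dLp")),
         significant = significant, n_perm = as.integer(n_perm),
         seed = seed, n_redrawn = n_redrawn),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> sparsity ", x$sparsity, ", ", x$n_perm,
      " permutations\n", sep = "")
  for (m in c("dCp", "dLp")) {
    cat(sprintf("  %s = %+.4f, null 95%% CI [%+.4f, %+.4f] -> %s\n",
                m, x$observed[[m]], x$ci_lower[[m]], x$ci_upper[[m]],
                if (x$significant[[m]]) "significant" else "n.s."))
  }
  invisible(x)
}

#' Per-node permutation test of normalized betweenness differences
#'
#' Same relabeling scheme as [permutation_test_metrics()], with each node's
#' normalized betweenness b_i as the statistic. Two-sided permutation
#' p-values are reported both uncorrected and Benjamini–Hochberg-adjusted
#' across the nodes (the reference analysis states no across-node
#' correction, so both are given and labeled).
#'
#' @inheritParams permutation_test_metrics
#' @return data frame with `region_id`, `abbreviation`, `observed_diff`
#'   (A minus B), `p_uncorrected`, `p_bh`.
#' @export
permutation_test_nodal <- function(cohortA, cohortB, sparsity,
                                   n_perm = 1000L, seed = 1L,
                                   rank_by = "magnitude") {
  stopifnot(inherits(cohortA, "cohort"), inherits(cohortB, "cohort"))
  n_reg <- ncol(cohortA$volumes)
  K <- as.integer(round_half_up(sparsity * n_reg * (n_reg - 1L) / 2L))
  pieces <- function(co) list(vol = co$volumes, age = co$covariates$age,
                              sex = co$covariates$sex,
                              tgv = co$covariates$total_gm_volume)
  a <- pieces(cohortA); b <- pieces(cohortB)
  oa <- .pipeline_stat(a$vol, a$age, a$sex, a$tgv, K, rank_by,
                       "node-betweenness")
  ob <- .pipeline_stat(b$vol, b$age, b$sex, b$tgv, K, rank_by,
                       "node-betweenness")
  if (is.null(oa) || is.null(ob) || anyNA(c(oa, ob)))
    stop("a group network is disconnected at sparsity ", sparsity)
  observed <- oa - ob
  vol <- rbind(a$vol, b$vol)
  age <- c(a$age, b$age); sex <- c(a$sex, b$sex); tgv <- c(a$tgv, b$tgv)
  nA <- nrow(a$vol); nTot <- nrow(vol)
  exceed <- rep(0L, n_reg)
  done <- 0L; redrawn <- 0L
  with_preserved_seed(seed, {
    while (done < n_perm) {
      idx <- sample.int(nTot, nA)
      pa <- .pipeline_stat(vol[idx, , drop = FALSE], age[idx], sex[idx],
                           tgv[idx], K, rank_by, "node-betweenness")
      pb <- .pipeline_stat(vol[-idx, , drop = FALSE], age[-idx], sex[-idx],
                           tgv[-idx], K, rank_by, "node-betweenness")
      if (is.null(pa) || is.null(pb) || anyNA(c(pa, pb))) {
        redrawn <- redrawn + 1L
        if (redrawn > 50L * n_perm) stop("too many disconnected networks")
        next
      }
      exceed <- exceed + (abs(pa - pb) >= abs(observed))
      done <- done + 1L
    }
  })
  p_unc <- (exceed + 1L) / (n_perm + 1L)
  atlas <- cohortA$atlas
  data.frame(region_id = atlas$region_id,
             abbreviation = atlas$abbreviation,
             observed_diff = observed,
             p_uncorrected = p_unc,
             p_bh = stats::p.adjust(p_unc, "BH"),
             stringsAsFactors = FALSE)
}

#' Bootstrap error bars for network metrics
#'
#' Resamples the cohort's subjects with replacement `n_boot` times and runs
#' the full pipeline on each resample, giving a bootstrap distribution of
#' each requested metric at the stated sparsity. The standard error is the
#' standard deviation of that distribution; the interval is the 2.5th–97.5th
#' percentile range. Gamma and lambda additionally require `n_random`
#' rewired surrogates per resample and are correspondingly slower. A
#' resample producing a zero-variance region or a disconnected network is
#' redrawn (count reported).
#'
#' @param cohort a `cohort`.
#' @param sparsity network sparsity.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param metrics subset of `c("Cp", "Lp", "gamma", "lambda")`.
#' @param n_random surrogates per resample when gamma/lambda are requested.
#' @param rank_by edge ranking rule.
#' @return data frame with one row per metric: `metric`, `estimate` (from
#'   the original cohort), `se`, `ci_lower`, `ci_upper`, plus attributes
#'   `n_boot` and `n_redrawn`.
#' @export
bootstrap_metric_ci <- function(cohort, sparsity, n_boot = 1000L, seed = 1L,
                                metrics = c("Cp", "Lp", "gamma", "lambda"),
                                n_random = 20L, rank_by = "magnitude") {
  stopifnot(inherits(cohort, "cohort"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  need_sw <- any(metrics %in% c("gamma", "lambda"))
  n_reg <- ncol(cohort$volumes)
  K <- as.integer(round_half_up(sparsity * n_reg * (n_reg - 1L) / 2L))
  vol <- cohort$volumes
  age <- cohort$covariates$age
  sex <- cohort$covariates$sex
  n <- nrow(vol)
  one <- function(idx) {
    v <- vol[idx, , drop = FALSE]
    res <- .residualize_mat(v, age[idx], sex[idx], rowSums(v))
    if (any(matrixStats_colSds(res) == 0)) return(NULL)
    adj <- .threshold_adj(stats::cor(res), K, rank_by)
    gl <- .global_cp_lp(adj)
    if (anyNA(gl)) return(NULL)
    out <- c(Cp = gl[1L], Lp = gl[2L], gamma = NA_real_, lambda = NA_real_)
    if (need_sw) {
      net <- binary_network(adj, atlas = cohort$atlas,
                            group_label = cohort$group_label)
      sw <- small_world_indices(net, n_random = n_random)
      out["gamma"] <- sw$gamma
      out["lambda"] <- sw$lambda
    }
    out[metrics]
  }
  n_redrawn <- 0L
  boot <- matrix(NA_real_, n_boot, length(metrics),
                 dimnames = list(NULL, metrics))
  est <- NULL
  with_preserved_seed(seed, {
    est <- one(seq_len(n))
    for (i in seq_len(n_boot)) {
      repeat {
        r <- one(sample.int(n, n, replace = TRUE))
        if (!is.null(r)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 50L * n_boot)
          stop("too many degenerate bootstrap resamples")
      }
      boot[i, ] <- r
    }
  })
  if (is.null(est) || anyNA(est))
    stop("the original cohort's network is disconnected at sparsity ",
         sparsity)
  out <- data.frame(
    metric = metrics,
    estimate = as.numeric(est),
    se = apply(boot, 2L, stats::sd),
    ci_lower = apply(boot, 2L, stats::quantile, probs = 0.025,
                     names = FALSE),
    ci_upper = apply(boot, 2L, stats::quantile, probs = 0.975,
                     names = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "n_redrawn") <- n_redrawn
  rownames(out) <- NULL
  out
}
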