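# Synthetic multi-group cohort generator.
#
# Volumes are affine transforms of latent multivariate-normal scores, so the
# latent correlation matrix is exactly the ground-truth Pearson correlation
# of the noise component -- the pipeline can be validated against a known
# answer without any imaging data.

#' Specify a synthetic multi-group study
#'
#' Defines the generative model for one or more diagnostic groups sharing an
#' atlas: a block (community) correlation structure with elevated homotopic
#' (mirror-region) correlation, linear age/sex confound effects, a shared
#' per-subject global size factor, and per-group overrides of the correlation
#' levels and of per-region atrophy fractions.
#'
#' The implied latent correlation matrix of every group is checked for
#' positive semi-definiteness at construction.
#'
#' @param n_subjects_per_group named integer vector, subjects per group.
#' @param atlas the `region_atlas` used (its `block` column defines the
#'   communities).
#' @param within_block_corr latent correlation between distinct regions in the
#'   same block, in `[0, 1)`.
#' @param homotopic_corr latent correlation between homotopic partners, in
#'   `[0, 1)`; expected to be the strongest level.
#' @param between_block_corr latent correlation between regions of different
#'   blocks, in `[0, 1)`.
#' @param group_effects named list (one entry per non-baseline group) of lists
#'   with optional elements `within_block_corr` (a scalar replacing the level
#'   in every block, or a named vector replacing it only in the named
#'   blocks), `between_block_corr`, `homotopic_corr` (absolute replacement
#'   values) and `atrophy` (numeric vector of per-region atrophy fractions in
#'   `[0, 1)`, length 1 or `nrow(atlas)`).
#' @param confound_betas list with `age` and `sex`: per-region regression
#'   coefficients (length 1 or `nrow(atlas)`) of volume on centered age
#'   (years) and on sex.
#' @param noise_sd standard deviation (volume units) of the correlated latent
#'   component of each regional volume.
#' @param global_sd standard deviation of a per-subject global size factor
#'   added to every region, emulating overall brain-size variation; this is
#'   what the total-gray-matter regressor removes.
#' @param age_range age is drawn uniformly on this interval (years).
#' @param group_age_shift named numeric vector of per-group mean age offsets
#'   (years), so the age-confound path is exercised.
#' @param seed integer seed stored with the spec; generation is reproducible
#'   given (spec, group).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_group = c(A = 100, B = 100),
                           atlas = aal_region_table(),
                           within_block_corr = 0.35,
                           homotopic_corr = 0.8,
                           between_block_corr = 0.15,
                           group_effects = list(),
                           confound_betas = list(age = -0.02, sex = 0.15),
                           noise_sd = 0.5,
                           global_sd = 0.25,
                           age_range = c(56, 90),
                           group_age_shift = NULL,
                           seed = 1L) {
  validate_atlas(atlas)
  if (is.null(names(n_subjects_per_group)) ||
      any(names(n_subjects_per_group) == ""))
    stop("n_subjects_per_group must be a named vector")
  stopifnot(all(n_subjects_per_group >= 5))
  for (v in c(within_block_corr, homotopic_corr, between_block_corr))
    if (v < 0 || v >= 1) stop("correlation levels must lie in [0, 1)")
  stopifnot(noise_sd > 0, global_sd >= 0)
  bad <- setdiff(names(group_effects), names(n_subjects_per_group))
  if (length(bad) > 0L)
    stop("group_effects for unknown group(s): ", paste(bad, collapse = ", "))
  n_reg <- nrow(atlas)
  recycle <- function(x) {
    if (length(x) == 1L) rep(x, n_reg)
    else if (length(x) == n_reg) x
    else stop("per-region vectors must have length 1 or ", n_reg)
  }
  # region baselines: fixed, deterministic function of the atlas only
  baseline <- 4 + 5 * (seq_len(n_reg) %% 7) / 7 +
    2 * (seq_len(n_reg) %% 3) / 3
  spec <- structure(
    list(n_subjects_per_group = n_subjects_per_group,
         atlas = atlas,
         within_block_corr = within_block_corr,
         homotopic_corr = homotopic_corr,
         between_block_corr = between_block_corr,
         group_effects = group_effects,
         beta_age = recycle(confound_betas$age %||% 0),
         beta_sex = recycle(confound_betas$sex %||% 0),
         baseline = baseline,
         noise_sd = noise_sd,
         global_sd = global_sd,
         age_range = age_range,
         group_age_shift = group_age_shift,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  # PSD check of every group's implied latent matrix
  for (g in names(n_subjects_per_group)) {
    R <- build_latent_correlation(spec, g, check = FALSE)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop("latent correlation matrix for group '", g,
           "' is not positive semi-definite (smallest eigenvalue ",
           signif(ev, 4), ")")
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latent correlation matrix implied by a spec for one group
#'
#' Entry (i, j) equals the homotopic level if j is i's mirror region, else the
#' within-block level if i and j share a block, else the between-block level,
#' with the group's overrides applied; the diagonal is 1.
#'
#' @param spec a `synthetic_spec`.
#' @param group group name.
#' @param check if `TRUE` (default) refuse a non-PSD result.
#' @return a symmetric unit-diagonal correlation matrix.
#' @export
build_latent_correlation <- function(spec, group, check = TRUE) {
  if (!group %in% names(spec$n_subjects_per_group))
    stop("unknown group '", group, "'")
  eff <- spec$group_effects[[group]] %||% list()
  h <- eff$homotopic_corr %||% spec$homotopic_corr
  b <- eff$between_block_corr %||% spec$between_block_corr
  atlas <- spec$atlas
  n <- nrow(atlas)
  # per-block within level: baseline, overridden globally (unnamed scalar)
  # or per named block
  blocks <- unique(atlas$block)
  w_by_block <- stats::setNames(rep(spec$within_block_corr, length(blocks)),
                                blocks)
  wo <- eff$within_block_corr
  if (!is.null(wo)) {
    if (is.null(names(wo))) {
      w_by_block[] <- wo
    } else {
      bad <- setdiff(names(wo), blocks)
      if (length(bad) > 0L)
        stop("unknown block(s) in within_block_corr override: ",
             paste(bad, collapse = ", "))
      w_by_block[names(wo)] <- wo
    }
  }
  same_block <- outer(atlas$block, atlas$block, "==")
  R <- matrix(b, n, n)
  w_of_row <- matrix(w_by_block[atlas$block], n, n)  # value of block(i)
  R[same_block] <- w_of_row[same_block]
  partner <- match(atlas$homotopic_partner_id, atlas$region_id)
  R[cbind(seq_len(n), partner)] <- h
  R[cbind(partner, seq_len(n))] <- h
  diag(R) <- 1
  if (check) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop("latent correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", signif(ev, 4), ")")
  }
  R
}

#' Generate one synthetic cohort
#'
#' Draws covariates (age uniform on the spec's range plus any group offset;
#' sex Bernoulli(1/2)) and latent region scores from the group's latent
#' correlation matrix, then forms volumes as
#' `baseline * (1 - atrophy) + beta_age * (age - 75) + beta_sex * sex +
#' global + noise_sd * latent`. `total_gm_volume` is the row sum of the 90
#' regional volumes. Deterministic given `(spec$seed, group)`.
#'
#' @param spec a `synthetic_spec`.
#' @param group group name.
#' @return a [new_cohort()] object.
#' @export
generate_cohort <- function(spec, group) {
  if (!group %in% names(spec$n_subjects_per_group))
    stop("unknown group '", group, "'")
  n <- spec$n_subjects_per_group[[group]]
  atlas <- spec$atlas
  n_reg <- nrow(atlas)
  R <- build_latent_correlation(spec, group, check = FALSE)
  eff <- spec$group_effects[[group]] %||% list()
  atrophy <- eff$atrophy %||% 0
  atrophy <- if (length(atrophy) == 1L) rep(atrophy, n_reg) else atrophy
  stopifnot(length(atrophy) == n_reg, all(atrophy >= 0), all(atrophy < 1))
  # per-(spec, group) substream so groups are independent but reproducible
  sub <- (spec$seed + sum(utf8ToInt(group)) * 7919L) %% 2147483647L
  with_preserved_seed(sub, {
    age <- stats::runif(n, spec$age_range[1L], spec$age_range[2L]) +
      (spec$group_age_shift[[group]] %||% 0)
    sex <- stats::rbinom(n, 1L, 0.5)
    glob <- stats::rnorm(n, 0, spec$global_sd)
    Z <- MASS::mvrnorm(n, mu = rep(0, n_reg), Sigma = R)
    vols <- matrix(rep(spec$baseline * (1 - atrophy), each = n), nrow = n) +
      outer(age - 75, spec$beta_age) + outer(sex, spec$beta_sex) +
      glob + spec$noise_sd * Z
    cov <- data.frame(
      subject_id = sprintf("%s_%03d", group, seq_len(n)),
      age = age, sex = sex, total_gm_volume = rowSums(vols))
    new_cohort(vols, cov, group, atlas = atlas)
  })
}

#' Generate every group of a spec
#'
#' @param spec a `synthetic_spec`.
#' @return named list of cohorts, one per group.
#' @export
generate_study <- function(spec) {
  groups <- names(spec$n_subjects_per_group)
  stats::setNames(lapply(groups, function(g) generate_cohort(spec, g)),
                  groups)
}

#' Default three-group NC/MCI/AD preset
#'
#' Group sizes 98 (NC), 113 (MCI) and 91 (AD). The NC group is the baseline
#' covariance structure; relative to it, the disease groups show a monotone
#' increase in within-block (short-distance) correlation concentrated in the
#' temporal and limbic blocks and a decrease in between-block (long-distance)
#' correlation, strongest in AD with MCI intermediate, plus mild
#' temporal/limbic atrophy. With this preset the expected ordering at
#' sparsity 15% is Cp(AD) > Cp(MCI) > Cp(NC) and Lp(AD) > Lp(MCI) > Lp(NC),
#' while networks remain fully connected with small-world ratios (gamma > 1,
#' lambda near 1) across the 10-30% sparsity range. A small NC-vs-MCI
#' mean-age offset exercises the age-confound regression.
#'
#' @param seed integer seed for the spec.
#' @return a `synthetic_spec` with groups `NC`, `MCI`, `AD`.
#' @export
default_three_group_spec <- function(seed = 1L) {
  atlas <- aal_region_table()
  atrophy_regions <- atlas$block %in% c("temporal", "limbic")
  mci_atrophy <- ifelse(atrophy_regions, 0.05, 0.01)
  ad_atrophy <- ifelse(atrophy_regions, 0.12, 0.03)
  synthetic_spec(
    n_subjects_per_group = c(NC = 98L, MCI = 113L, AD = 91L),
    atlas = atlas,
    within_block_corr = 0.36,
    homotopic_corr = 0.80,
    between_block_corr = 0.22,
    group_effects = list(
      MCI = list(within_block_corr = c(temporal = 0.46, limbic = 0.46),
                 between_block_corr = 0.21,
                 atrophy = mci_atrophy),
      AD = list(within_block_corr = c(temporal = 0.54, limbic = 0.54),
                between_block_corr = 0.20,
                atrophy = ad_atrophy)),
    confound_betas = list(age = -0.02, sex = 0.15),
    noise_sd = 0.5,
    global_sd = 0.25,
    age_range = c(56, 90),
    group_age_shift = c(NC = 2, MCI = 0, AD = 1),
    seed = seed)
}

# Evaluate code under a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
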