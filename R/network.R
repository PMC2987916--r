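# Group-level network construction: confound regression, then Pearson
# correlation across subjects for every region pair.

#' Remove age, sex and total-volume effects from regional volumes
#'
#' Fits, for every region, an ordinary-least-squares regression of volume on
#' an intercept, age, sex and total gray-matter volume (one shared design for
#' all regions), and returns the residuals. These residuals are the corrected
#' regional volumes the correlation matrix is computed from.
#'
#' A covariate that is constant across subjects (e.g. a single-sex cohort) is
#' dropped from the design with a warning; `design_rank` records the number
#' of regressors actually retained.
#'
#' @param cohort a `cohort`.
#' @return an object of class `residual_matrix`: list with `residuals`
#'   (subjects x regions), `design_rank`, `group_label`, `atlas` and
#'   `n_subjects`.
#' @export
residualize <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cov <- cohort$covariates
  X <- cbind(intercept = 1, age = cov$age, sex = cov$sex,
             total_gm_volume = cov$total_gm_volume)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2L,
                        function(v) stats::var(v) > 0))
  if (!all(keep)) {
    dropped <- colnames(X)[!keep]
    warning("constant covariate(s) dropped from the design: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design; ", ncol(X) - qr_x$rank,
            " collinear regressor(s) ignored")
  }
  if (nrow(X) < qr_x$rank + 2L)
    stop("too few subjects (", nrow(X), ") for a design of rank ",
         qr_x$rank)
  res <- qr.resid(qr_x, cohort$volumes)
  structure(
    list(residuals = res,
         design_rank = qr_x$rank,
         group_label = cohort$group_label,
         atlas = cohort$atlas,
         n_subjects = nrow(res)),
    class = "residual_matrix")
}

#' Interregional Pearson correlation matrix
#'
#' Computes the Pearson correlation coefficient across subjects for every
#' unordered pair of regions (N(N-1)/2 pairs; 4005 on the full 90-region
#' atlas), with diagonal set exactly to 1.
#'
#' @param residuals a `residual_matrix` from [residualize()] (a `cohort` is
#'   also accepted and residualized first).
#' @param group_label optional label override.
#' @return an object of class `correlation_matrix`: list with `r` (regions x
#'   regions), `n_subjects`, `group_label`, `atlas`.
#' @export
correlation_matrix <- function(residuals, group_label = NULL) {
  if (inherits(residuals, "cohort")) residuals <- residualize(residuals)
  stopifnot(inherits(residuals, "residual_matrix"))
  m <- residuals$residuals
  if (nrow(m) < 5L) stop("need at least 5 subjects")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(residuals$atlas$abbreviation[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(residuals$atlas$abbreviation,
                      residuals$atlas$abbreviation)
  structure(
    list(r = r,
         n_subjects = residuals$n_subjects,
         group_label = group_label %||% residuals$group_label,
         atlas = residuals$atlas),
    class = "correlation_matrix")
}

#' Full construction step: cohort to correlation matrix
#'
#' Convenience composition of [residualize()] and [correlation_matrix()].
#'
#' @param cohort a `cohort`.
#' @return a `correlation_matrix`.
#' @export
cohort_correlation <- function(cohort) {
  correlation_matrix(residualize(cohort))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> group '", x$group_label, "', ",
      nrow(x$r), " regions, n = ", x$n_subjects, " subjects\n", sep = "")
  invisible(x)
}
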