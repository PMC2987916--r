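# Cohort container: subjects x regions volume matrix plus covariates.

#' Construct a cohort of regional gray-matter volumes
#'
#' A cohort holds one diagnostic group: a subjects-by-regions matrix of mean
#' regional gray-matter volumes (arbitrary but consistent volume units,
#' strictly positive) and per-subject covariates used for confound regression.
#'
#' @param volumes numeric matrix, subjects x regions, columns in atlas order.
#' @param covariates data frame with one row per subject and columns
#'   `subject_id`, `age` (years), `sex` (0 = female, 1 = male) and
#'   `total_gm_volume` (same units as `volumes`).
#' @param group_label free-text group label (e.g. `"NC"`, `"MCI"`, `"AD"`).
#' @param atlas the `region_atlas` the columns refer to.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(volumes, covariates, group_label,
                       atlas = aal_region_table()) {
  validate_atlas(atlas)
  volumes <- as.matrix(volumes)
  if (!is.numeric(volumes))
    stop("volumes must be a numeric matrix")
  if (ncol(volumes) != nrow(atlas))
    stop("volumes must have one column per atlas region (",
         nrow(atlas), "), got ", ncol(volumes))
  if (nrow(volumes) != nrow(covariates))
    stop("covariates must have one row per subject")
  if (nrow(volumes) < 5L)
    stop("a cohort needs at least 5 subjects; correlation estimation is ",
         "refused below that")
  needed <- c("subject_id", "age", "sex", "total_gm_volume")
  missing <- setdiff(needed, names(covariates))
  if (length(missing) > 0L)
    stop("covariates missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all regional volumes must be finite and strictly positive")
  if (!all(covariates$sex %in% c(0, 1)))
    stop("sex must be coded 0 (female) / 1 (male)")
  colnames(volumes) <- atlas$abbreviation
  structure(
    list(volumes = volumes,
         covariates = as.data.frame(covariates),
         group_label = as.character(group_label),
         atlas = atlas),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> group '", x$group_label, "': ", nrow(x$volumes),
      " subjects x ", ncol(x$volumes), " regions\n", sep = "")
  cat("  age ", sprintf("%.1f-%.1f", min(x$covariates$age),
                        max(x$covariates$age)),
      ", female/male ", sum(x$covariates$sex == 0), "/",
      sum(x$covariates$sex == 1), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `cohort`.
#' @return integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$volumes)
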