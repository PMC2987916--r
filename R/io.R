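# Delimited-text I/O for cohorts, matrices and edge lists.
#
# All writers prepend '#'-prefixed comment lines recording the package
# version and any parameters passed, so every output file is self-describing;
# all readers skip such lines.

.delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.comment_header <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("covnet"))
  lines <- paste0("# covnet version ", ver)
  if (length(params) > 0L) {
    lines <- c(lines, paste0(
      "# ", paste(names(params), unlist(params), sep = "=",
                  collapse = " ")))
  }
  lines
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row with columns `subject_id`, `age`, `sex`,
#' `total_gm_volume`, followed by one column per atlas region named by its
#' abbreviation (any order; columns are reordered into atlas order).
#' The delimiter is sniffed from the file extension (`.tsv` = tab, else
#' comma).
#'
#' @param path file path.
#' @param group_label group label to attach.
#' @param atlas target atlas; defaults to [aal_region_table()].
#' @return a [new_cohort()] object.
#' @export
read_cohort <- function(path, group_label, atlas = aal_region_table()) {
  delim <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("subject_id", "age", "sex", "total_gm_volume")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("cohort file missing covariate column(s): ",
         paste(missing, collapse = ", "))
  miss_reg <- setdiff(atlas$abbreviation, names(df))
  if (length(miss_reg) > 0L)
    stop("cohort file missing region column(s): ",
         paste(miss_reg, collapse = ", "))
  dup <- names(df)[duplicated(names(df))]
  dup <- intersect(dup, atlas$abbreviation)
  if (length(dup) > 0L)
    stop("cohort file has duplicate region column(s): ",
         paste(unique(dup), collapse = ", "))
  vol_df <- df[, atlas$abbreviation, drop = FALSE]
  for (cn in names(vol_df)) {
    v <- vol_df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L)
        stop("non-numeric value in region column '", cn, "' at data row ",
             bad[1L])
      vol_df[[cn]] <- vn
    }
  }
  for (cn in c("age", "sex", "total_gm_volume")) {
    if (!is.numeric(df[[cn]])) {
      suppressWarnings(vn <- as.numeric(df[[cn]]))
      bad <- which(is.na(vn) & !is.na(df[[cn]]))
      if (length(bad) > 0L)
        stop("non-numeric value in covariate column '", cn,
             "' at data row ", bad[1L])
      df[[cn]] <- vn
    }
  }
  new_cohort(as.matrix(vol_df), df[, needed, drop = FALSE], group_label,
             atlas = atlas)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]; values are written with full double precision
#' (17 significant digits) so a write/read round trip is lossless.
#'
#' @param cohort a `cohort`.
#' @param path output path (`.csv` or `.tsv`).
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  delim <- .delim_for(path)
  df <- cbind(cohort$covariates[, c("subject_id", "age", "sex",
                                    "total_gm_volume")],
              as.data.frame(cohort$volumes))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.comment_header(list(group = cohort$group_label)), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a square labeled matrix to delimited text
#'
#' @param matrix symmetric numeric matrix labeled by atlas abbreviations (an
#'   unlabeled matrix is accepted and labeled from `atlas`).
#' @param path output path.
#' @param atlas atlas providing labels when the matrix has none.
#' @param params named list recorded in the comment header.
#' @return the path, invisibly.
#' @export
write_matrix <- function(matrix, path, atlas = aal_region_table(),
                         params = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-10))
    stop("write_matrix requires a symmetric square matrix")
  if (is.null(rownames(m))) {
    stopifnot(nrow(m) == nrow(atlas))
    rownames(m) <- colnames(m) <- atlas$abbreviation
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.comment_header(params), con)
  df <- data.frame(region = rownames(m),
                   format(as.data.frame(m), digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix()]
#'
#' @param path file path.
#' @return a numeric matrix with row/column labels.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a network or edge table as a three-column edge list
#'
#' For a `binary_network` the value column is 1 for every edge; for a
#' symmetric numeric matrix it is the entry value; a data frame with columns
#' `region_i`, `region_j`, `value` is written as is. Rows satisfy i < j in
#' atlas order.
#'
#' @param x a `binary_network`, symmetric matrix, or edge data frame.
#' @param path output path.
#' @param atlas atlas for labels when `x` carries none.
#' @param params named list recorded in the comment header.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(x, path, atlas = aal_region_table(),
                            params = NULL) {
  if (inherits(x, "binary_network")) {
    atlas <- x$atlas
    m <- x$adjacency * 1
  } else if (is.matrix(x)) {
    if (!isSymmetric(unname(x), tol = 1e-10))
      stop("edge-list export requires a symmetric matrix")
    m <- x
  } else {
    df <- as.data.frame(x)
    stopifnot(all(c("region_i", "region_j", "value") %in% names(df)))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.comment_header(params), con)
    utils::write.table(df, con, sep = .delim_for(path), row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  ut <- upper.tri(m)
  keep <- which(ut & m != 0, arr.ind = TRUE)
  keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  df <- data.frame(region_i = atlas$abbreviation[keep[, 1L]],
                   region_j = atlas$abbreviation[keep[, 2L]],
                   value = m[keep])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.comment_header(params), con)
  utils::write.table(df, con, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
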