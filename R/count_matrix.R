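#' Two-group RNA-seq count matrix
#'
#' Bundles a genes-by-samples matrix of non-negative integer read counts with
#' a two-level group assignment of the samples. The first level of the group
#' factor is treated as the reference (control) condition throughout the
#' package: fold changes are reported as second level over first.
#'
#' @param counts numeric matrix of non-negative integers with gene identifiers
#'   as row names and sample identifiers as column names.
#' @param groups group assignment of the samples: either a factor/character
#'   vector of length \code{ncol(counts)} (in column order), or a named
#'   vector mapping sample identifier to group. Exactly two groups with at
#'   least two samples each are required.
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts} (the validated integer matrix) and \code{groups} (a factor
#'   aligned with the columns).
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c(s1 = "control", s2 = "control",
#'                         s3 = "test", s4 = "test"))
#' dim(cm)
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicate gene id '%s'",
                 rownames(counts)[duplicated(rownames(counts))][1L]))
  if (anyDuplicated(colnames(counts)))
    stop(sprintf("duplicate sample id '%s'",
                 colnames(counts)[duplicated(colnames(counts))][1L]))
  if (!is.numeric(counts))
    stop("'counts' must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "count for gene '%s' in sample '%s' is not a non-negative integer",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"

  groups <- .align_groups(groups, colnames(counts))
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

## normalize a group specification to a 2-level factor in column order
.align_groups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing))
      stop(sprintf("sample '%s' has no group assignment", missing[1L]))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("'groups' must be named by sample or have one entry per sample")
  }
  if (!is.factor(groups))
    groups <- factor(as.character(groups),
                     levels = unique(as.character(groups)))
  groups <- droplevels(groups)
  names(groups) <- sample_ids
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required, got ", nlevels(groups))
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  groups
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

## accept either a count_matrix or a bare matrix in lower-level functions
.as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}
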