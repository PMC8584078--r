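## File formats: count matrix TSV, sample sheet TSV, GMT gene sets,
## edge lists, and the generic table writer used by every stage.

#' Read a count matrix from a TSV file
#'
#' Expects a tab-separated file with a header row of sample identifiers and a
#' first column of gene identifiers (the convention written by read-counting
#' tools). All cells must parse as non-negative integers.
#'
#' @param path path to the TSV file.
#' @param group_map group assignment for the samples: a named vector
#'   (sample id -> group), or a two-column data frame (sample id, group) as
#'   returned by \code{\link{read_sample_sheet}}.
#' @return A \code{\link{count_matrix}} with row and column order preserved
#'   from the file.
#' @export
read_count_matrix <- function(path, group_map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("count matrix file needs a gene id column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id '%s' in '%s'",
                 genes[duplicated(genes)][1L], path))
  samples <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = list(genes, samples)))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "invalid count '%s' for gene '%s' in sample '%s'",
      as.character(raw[bad[1L, 1L], bad[1L, 2L]]),
      genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  if (is.data.frame(group_map)) {
    if (ncol(group_map) < 2L)
      stop("sample sheet needs columns (sample_id, group)")
    group_map <- stats::setNames(as.character(group_map[[2L]]),
                                 as.character(group_map[[1L]]))
  }
  count_matrix(num, group_map)
}

#' Write a count matrix to TSV
#'
#' @param cm a \code{\link{count_matrix}} or plain matrix.
#' @param path output path.
#' @param id_column header for the gene id column.
#' @export
write_count_matrix <- function(cm, path, id_column = "gene_id") {
  m <- .as_count_mat(cm)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  .write_tsv(df, path)
}

#' Read a two-column sample sheet (sample_id, group)
#'
#' @param path path to a headered TSV with columns sample id and group.
#' @return Named character vector mapping sample id to group.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("sample sheet needs columns (sample_id, group)")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a sample sheet for a count matrix
#' @param cm a \code{\link{count_matrix}}.
#' @param path output path.
#' @export
write_sample_sheet <- function(cm, path) {
  .write_tsv(data.frame(sample_id = names(cm$groups),
                        group = as.character(cm$groups),
                        stringsAsFactors = FALSE), path)
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description, and one or more member gene
#' identifiers, tab-separated. Duplicate genes within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @return A \code{\link{gene_set_collection}} (universe unset; the
#'   enrichment stage defaults the universe to the tested genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    sets[[fields[1L]]] <- unique(fields[-c(1L, 2L)])
  }
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#' @param collection a \code{\link{gene_set_collection}} or named list.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Named gene sets with an optional gene universe
#'
#' @param sets named list of character vectors of gene identifiers; every set
#'   must be non-empty.
#' @param universe optional character vector of all testable genes.
#' @return An object of class \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) > 0L) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set must be named")
    if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  structure(list(sets = sets,
                 universe = if (is.null(universe)) NULL
                            else unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets%s\n", length(x$sets),
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' Read a network edge list
#'
#' Two- or three-column TSV (source, target, sign). A missing sign column is
#' filled with "activation".
#'
#' @param path path to the edge TSV (with header).
#' @return data.frame with columns source, target, sign.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least (source, target) columns")
  out <- data.frame(source = as.character(df[[1L]]),
                    target = as.character(df[[2L]]),
                    sign = if (ncol(df) >= 3L) as.character(df[[3L]])
                           else rep("activation", nrow(df)),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$sign), c("activation", "inhibition"))
  if (length(bad))
    stop(sprintf("unknown edge sign '%s' (use activation/inhibition)",
                 bad[1L]))
  out
}

## One table writer for all stage outputs: tab-separated, no quoting, reals
## at 15 significant digits so a write/read round trip is exact to >=12.
.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !all(df[[j]] == round(df[[j]]), na.rm = TRUE))
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
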