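#' Hypergeometric upper-tail probability (Fisher exact enrichment p)
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\code{N} genes in the
#' universe, \code{K} in the set, \code{n} drawn in the list). This is the
#' one-sided Fisher exact test for over-representation of a gene set in a
#' gene list.
#'
#' @param k overlap between list and set.
#' @param K set size (within the universe).
#' @param n list size.
#' @param N universe size.
#' @return P(X >= k), vectorized over the arguments.
#' @examples
#' fisher_tail_p(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
fisher_tail_p <- function(k, K, n, N) {
  .check_margins(k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (one-gene-penalized Fisher exact p)
#'
#' The conservative enrichment score used by DAVID: the Fisher upper-tail
#' probability recomputed after removing one gene from the overlap,
#' \code{fisher_tail_p(max(k - 1, 0), K, n, N)}. Always >= the Fisher p.
#'
#' @inheritParams fisher_tail_p
#' @return The EASE score, vectorized.
#' @export
ease_p <- function(k, K, n, N) {
  .check_margins(k, K, n, N)
  stats::phyper(pmax(k - 1, 0) - 1, K, N - K, n, lower.tail = FALSE)
}

.check_margins <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0))
    stop("inconsistent margins: negative value")
  if (any(K > N | n > N))
    stop("inconsistent margins: set or list larger than universe")
  if (any(k > pmin(K, n)))
    stop("inconsistent margins: overlap exceeds min(set size, list size)")
  invisible(TRUE)
}

#' Gene-set over-representation of a DEG table
#'
#' Tests the up- and downregulated DEG lists separately against every gene
#' set (mirroring the separate panels reported for down- and upregulated
#' processes), scoring each term with the EASE score (default) or the Fisher
#' exact upper tail, and flagging terms below the selection threshold. No
#' multiple-testing correction is applied at this stage; selection is on the
#' raw p-value.
#'
#' @param deg a \code{"deg_table"} from \code{\link{deg_test}}.
#' @param sets a \code{\link{gene_set_collection}} or named list of gene id
#'   vectors.
#' @param mode scoring mode, \code{"ease"} (default) or \code{"fisher"}.
#' @param threshold selection threshold on the raw p-value (default 0.1).
#' @param universe gene universe; defaults to the collection's universe if
#'   set, otherwise to all genes in \code{deg} (the tested genes). Gene sets
#'   are intersected with the universe before testing; sets left empty are
#'   dropped with a warning.
#' @param directions \code{"separate"} (default; up and down lists tested
#'   independently) or \code{"combined"} (one list of all DEGs).
#' @return data.frame of class \code{"enrichment_table"} with columns
#'   \code{term}, \code{direction}, \code{overlap}, \code{set_size},
#'   \code{list_size}, \code{universe_size}, \code{p_value},
#'   \code{selected}, sorted by direction, then p, then term.
#' @export
run_enrichment <- function(deg, sets, mode = c("ease", "fisher"),
                           threshold = 0.1, universe = NULL,
                           directions = c("separate", "combined")) {
  mode <- match.arg(mode)
  directions <- match.arg(directions)
  if (threshold <= 0 || threshold > 1) stop("'threshold' must lie in (0, 1]")
  slist <- if (inherits(sets, "gene_set_collection")) sets$sets else sets
  if (is.null(universe) && inherits(sets, "gene_set_collection"))
    universe <- sets$universe
  if (is.null(universe)) universe <- unique(as.character(deg$gene))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  n_univ <- length(universe)

  slist <- lapply(slist, intersect, universe)
  empty <- lengths(slist) == 0L
  if (any(empty)) {
    warning(sprintf("%d gene set(s) disjoint from the universe dropped: %s",
                    sum(empty),
                    paste(names(slist)[empty], collapse = ", ")))
    slist <- slist[!empty]
  }

  deg_genes <- deg$gene[deg$is_deg]
  lists <- if (directions == "separate") {
    list(up = intersect(deg$gene[deg$is_deg & deg$direction == "up"],
                        universe),
         down = intersect(deg$gene[deg$is_deg & deg$direction == "down"],
                          universe))
  } else {
    list(all = intersect(deg_genes, universe))
  }

  score <- if (mode == "ease") ease_p else fisher_tail_p
  rows <- lapply(names(lists), function(dir) {
    gl <- lists[[dir]]
    k <- vapply(slist, function(s) length(intersect(s, gl)), integer(1))
    data.frame(term = names(slist), direction = dir, overlap = k,
               set_size = lengths(slist), list_size = length(gl),
               universe_size = n_univ,
               p_value = score(k, lengths(slist), length(gl), n_univ),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p_value < threshold
  out <- out[order(out$direction, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  out
}
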