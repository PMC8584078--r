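#' Assemble network node/edge tables from a DEG result
#'
#' Labels every node of a user-supplied signed edge list (plus every called
#' DEG) with its regulation direction: "up" or "down" for called DEGs,
#' "nochange" for genes that were not called (or not tested). Edges are
#' passed through unchanged. The node direction is a pure function of the
#' DEG table and its thresholds.
#'
#' @param deg a \code{"deg_table"} from \code{\link{deg_test}}.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{activation}/\code{inhibition}); may be empty or NULL.
#' @return An object of class \code{"network_tables"}: list with \code{nodes}
#'   (gene_id, direction in up/down/nochange) and \code{edges}.
#' @export
assemble_network_tables <- function(deg, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    if (!all(c("source", "target") %in% colnames(edges)))
      stop("edges need columns (source, target[, sign])")
    if (!"sign" %in% colnames(edges)) edges$sign <- "activation"
    bad <- setdiff(unique(edges$sign), c("activation", "inhibition"))
    if (length(bad))
      stop(sprintf("unknown edge sign '%s'", bad[1L]))
  }
  node_ids <- unique(c(edges$source, edges$target,
                       as.character(deg$gene[deg$is_deg])))
  dir_of <- stats::setNames(as.character(deg$direction),
                            as.character(deg$gene))
  node_dir <- dir_of[node_ids]
  node_dir[is.na(node_dir) | node_dir == "none"] <- "nochange"
  nodes <- data.frame(gene_id = node_ids,
                      direction = unname(node_dir),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 edges = edges[, c("source", "target", "sign"),
                               drop = FALSE]),
            class = "network_tables")
}

#' Write network tables (node TSV, edge TSV, SIF)
#'
#' @param net a \code{"network_tables"} object.
#' @param nodes_path,edges_path,sif_path output paths; any may be NULL to
#'   skip that file.
#' @export
write_network_tables <- function(net, nodes_path = NULL, edges_path = NULL,
                                 sif_path = NULL) {
  if (!is.null(nodes_path)) .write_tsv(net$nodes, nodes_path)
  if (!is.null(edges_path)) .write_tsv(net$edges, edges_path)
  if (!is.null(sif_path)) {
    lines <- if (nrow(net$edges) > 0L)
      paste(net$edges$source, net$edges$sign, net$edges$target, sep = "\t")
    else character()
    writeLines(lines, sif_path)
  }
  invisible(net)
}

#' @export
print.network_tables <- function(x, ...) {
  cat(sprintf("network_tables: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$direction)),
                            table(x$nodes$direction)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
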