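#' Pipeline configuration
#'
#' Validated bundle of the tunable thresholds of the analysis.
#'
#' @param fdr_threshold FDR cutoff for DEG calls, in (0, 1) (default 0.05).
#' @param fc_threshold two-sided fold-change cutoff, > 1 (default 1.5).
#' @param enrichment_p_threshold raw-p selection cutoff for gene sets
#'   (default 0.1).
#' @param pseudocount positive constant added before the log2 transform
#'   (default 1).
#' @param seed integer seed recorded in the run log (default 1).
#' @param storey_lambda Storey tuning proportion in [0, 1) (default 0.5).
#' @param ease_mode enrichment scoring, \code{"ease"} (default) or
#'   \code{"fisher"}.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(fdr_threshold = 0.05, fc_threshold = 1.5,
                            enrichment_p_threshold = 0.1, pseudocount = 1,
                            seed = 1, storey_lambda = 0.5,
                            ease_mode = c("ease", "fisher")) {
  ease_mode <- match.arg(ease_mode)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("'fdr_threshold' must lie in (0, 1)")
  if (fc_threshold <= 1) stop("'fc_threshold' must exceed 1")
  if (enrichment_p_threshold <= 0 || enrichment_p_threshold > 1)
    stop("'enrichment_p_threshold' must lie in (0, 1]")
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  if (storey_lambda < 0 || storey_lambda >= 1)
    stop("'storey_lambda' must lie in [0, 1)")
  structure(list(fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold,
                 enrichment_p_threshold = enrichment_p_threshold,
                 pseudocount = pseudocount, seed = as.integer(seed),
                 storey_lambda = storey_lambda, ease_mode = ease_mode),
            class = "pipeline_config")
}

#' Read a plain-text key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and lines starting with
#' \code{#} are ignored. Unknown keys are an error. Values override the
#' \code{\link{pipeline_config}} defaults; arguments passed in \code{...}
#' override the file (so a command-line flag wins over the file).
#'
#' @param path path to the config file.
#' @param ... overrides, as named \code{pipeline_config} arguments.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop(sprintf("bad config line: '%s'", ln))
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    kv[[key]] <- if (key == "ease_mode") val else as.numeric(val)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop(sprintf("unknown config key '%s'", unknown[1L]))
  overrides <- list(...)
  kv[names(overrides)] <- overrides
  do.call(pipeline_config, kv)
}

#' Run the full differential-expression pipeline
#'
#' Orchestrates normalization, permutation-null testing, gene-set
#' over-representation, network table assembly and the volcano table, and
#' (optionally) writes every stage output as TSV plus a run log. Genes with
#' zero counts in every sample carry no information and are dropped before
#' testing; the drop is recorded in the log. With a fixed seed the run is
#' bit-reproducible; on failure any partial outputs are removed.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param gene_sets optional \code{\link{gene_set_collection}} for the
#'   enrichment stage.
#' @param edges optional signed edge list (data.frame source, target, sign)
#'   for the network stage.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory; created if missing. Files:
#'   \code{normalization_factors.tsv}, \code{log_matrix.tsv},
#'   \code{deg_table.tsv}, \code{volcano.tsv}, \code{enrichment.tsv},
#'   \code{network_nodes.tsv}, \code{network_edges.tsv},
#'   \code{network.sif}, \code{run_log.txt}.
#' @param quiet suppress progress messages on stderr.
#' @return list with \code{normalization}, \code{deg_table},
#'   \code{enrichment} (or NULL), \code{network} (or NULL), \code{volcano},
#'   \code{config}, \code{dropped_genes}.
#' @export
run_pipeline <- function(counts, gene_sets = NULL, edges = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  written <- character()
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, file)
      .write_tsv(df, path)
      written <<- c(written, path)
    }
  }

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  res <- tryCatch({
    say("permdeg %s | seed %d | config md5 %s",
        as.character(utils::packageVersion("permdeg")), config$seed,
        .config_hash(config))
    say("thresholds: fdr < %g, fold change > %g, enrichment p < %g (%s)",
        config$fdr_threshold, config$fc_threshold,
        config$enrichment_p_threshold, config$ease_mode)

    keep <- rowSums(counts$counts) > 0
    dropped <- rownames(counts$counts)[!keep]
    if (length(dropped)) {
      counts <- count_matrix(counts$counts[keep, , drop = FALSE],
                             counts$groups)
      say("dropped %d gene(s) with zero counts in all samples",
          length(dropped))
    }
    say("input: %d genes x %d samples", nrow(counts$counts),
        ncol(counts$counts))

    norm <- normalize_counts(counts, pseudocount = config$pseudocount)
    say("normalization: reference sample '%s', factors [%s]",
        norm$reference_sample,
        paste(sprintf("%.4f", norm$factors), collapse = ", "))
    emit(data.frame(sample_id = names(norm$factors),
                    tmm_factor = as.numeric(norm$factors),
                    effective_lib_size = norm$effective_lib_sizes,
                    stringsAsFactors = FALSE),
         "normalization_factors.tsv")
    emit(data.frame(gene_id = rownames(norm$log_matrix), norm$log_matrix,
                    check.names = FALSE), "log_matrix.tsv")

    deg <- deg_test(norm$log_matrix, counts$groups,
                    fdr_threshold = config$fdr_threshold,
                    fc_threshold = config$fc_threshold,
                    storey_lambda = config$storey_lambda)
    say("deg test: %d assignments, pi0_hat = %.3f, %d DEGs (%d up, %d down)",
        attr(deg, "n_assignments"), attr(deg, "pi0_hat"), sum(deg$is_deg),
        sum(deg$direction == "up"), sum(deg$direction == "down"))
    emit(deg, "deg_table.tsv")

    volc <- volcano_table(deg)
    emit(volc, "volcano.tsv")

    enr <- NULL
    if (!is.null(gene_sets)) {
      enr <- run_enrichment(deg, gene_sets, mode = config$ease_mode,
                            threshold = config$enrichment_p_threshold)
      say("enrichment: %d term/direction tests, %d selected",
          nrow(enr), sum(enr$selected))
      emit(enr, "enrichment.tsv")
    }

    net <- NULL
    if (!is.null(edges) || sum(deg$is_deg) > 0) {
      net <- assemble_network_tables(deg, edges)
      say("network: %d nodes, %d edges", nrow(net$nodes), nrow(net$edges))
      if (!is.null(out_dir)) {
        write_network_tables(net,
                             nodes_path = file.path(out_dir,
                                                    "network_nodes.tsv"),
                             edges_path = file.path(out_dir,
                                                    "network_edges.tsv"),
                             sif_path = file.path(out_dir, "network.sif"))
        written <- c(written,
                     file.path(out_dir, c("network_nodes.tsv",
                                          "network_edges.tsv",
                                          "network.sif")))
      }
    }

    if (!is.null(out_dir))
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))

    list(normalization = norm, deg_table = deg, enrichment = enr,
         network = net, volcano = volc, config = config,
         dropped_genes = dropped)
  }, error = function(e) {
    # remove partial outputs so a failed run leaves no half-written results
    unlink(written)
    stop(e)
  })
  res
}

## md5 of the canonical key=value dump of the config (deterministic)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(unclass(config)),
                   vapply(unclass(config), function(v)
                     paste(format(v, digits = 15), collapse = ","),
                     character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
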