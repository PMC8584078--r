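#' Delta-delta-Ct relative quantification
#'
#' Computes relative expression of a target gene from qPCR cycle-threshold
#' (Ct) values, normalized to a reference gene (the GAPDH role) and to the
#' control condition. Per replicate,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} within the same sample;
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}};
#' relative level \eqn{= 2^{-\Delta\Delta Ct}}. Relative levels are then
#' divided by the mean control-replicate level, so the control condition
#' averages exactly 1 (the usual normalize-to-control-mean reporting
#' convention). Replicates are unpaired across conditions: every replicate
#' is referenced to the mean control \eqn{\Delta Ct}.
#'
#' @param ct_table data.frame with columns \code{gene}, \code{sample},
#'   \code{condition} (values \code{control}/\code{test}), \code{ct}.
#' @param target target gene identifier.
#' @param reference reference (housekeeping) gene identifier; default taken
#'   from the table's \code{"reference_gene"} attribute, else "GAPDH".
#' @return An object of class \code{"ddct_result"}: list with \code{target},
#'   \code{reference}, \code{per_replicate} (sample, condition, delta_ct,
#'   delta_delta_ct, relative_level) and \code{summary} (per condition: n,
#'   mean relative level, SEM).
#' @examples
#' ct <- data.frame(
#'   gene = rep(c("GAPDH", "TFEB"), each = 4),
#'   sample = rep(c("c1", "c2", "t1", "t2"), 2),
#'   condition = rep(c("control", "control", "test", "test"), 2),
#'   ct = c(18, 18, 18, 18, 24, 24, 25, 25))
#' delta_delta_ct(ct, "TFEB")$summary   # test mean 0.5 (one cycle later)
#' @export
delta_delta_ct <- function(ct_table, target, reference = NULL) {
  df <- as.data.frame(ct_table)
  needed <- c("gene", "sample", "condition", "ct")
  if (!all(needed %in% colnames(df)))
    stop("ct_table needs columns: ", paste(needed, collapse = ", "))
  if (is.null(reference))
    reference <- attr(ct_table, "reference_gene") %||% "GAPDH"
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop("Ct values must be finite and positive")
  bad_cond <- setdiff(unique(as.character(df$condition)),
                      c("control", "test"))
  if (length(bad_cond))
    stop(sprintf("unknown condition '%s' (use control/test)", bad_cond[1L]))

  tgt <- df[df$gene == target, , drop = FALSE]
  if (nrow(tgt) == 0L) stop(sprintf("target '%s' not in ct_table", target))
  ref <- df[df$gene == reference, , drop = FALSE]
  key <- function(d) paste(d$sample, d$condition, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  miss <- is.na(ref_ct[key(tgt)])
  if (any(miss))
    stop(sprintf("no reference ('%s') measurement for sample '%s'",
                 reference, tgt$sample[miss][1L]))
  if (!any(tgt$condition == "control") || !any(tgt$condition == "test"))
    stop(sprintf("target '%s' must be measured in both conditions", target))

  dct <- tgt$ct - as.numeric(ref_ct[key(tgt)])
  ddct <- dct - mean(dct[tgt$condition == "control"])
  rel <- 2^(-ddct)
  rel <- rel / mean(rel[tgt$condition == "control"])

  per_rep <- data.frame(sample = tgt$sample,
                        condition = as.character(tgt$condition),
                        delta_ct = dct, delta_delta_ct = ddct,
                        relative_level = rel, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("control", "test"), function(cond) {
    x <- rel[per_rep$condition == cond]
    data.frame(condition = cond, n = length(x), mean_relative_level = mean(x),
               sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(target = target, reference = reference,
                 per_replicate = per_rep, summary = summ),
            class = "ddct_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddct_result: %s (reference %s)\n", x$target, x$reference))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
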