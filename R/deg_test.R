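#' Two-sample Student t-statistic
#'
#' Pooled-variance two-sample t: \eqn{t = (\bar x_1 - \bar x_2) /
#' (s_p \sqrt{1/n_1 + 1/n_2})}. Degenerate variances are resolved
#' deterministically: if the pooled variance is zero and the means are equal
#' the statistic is 0; if it is zero with unequal means the statistic is
#' \code{Inf} with the sign of the mean difference, which ranks more extreme
#' than any finite statistic in the permutation null.
#'
#' @param x1,x2 numeric vectors of length >= 2.
#' @param welch use the Welch (unequal-variance) form instead of the pooled
#'   form.
#' @return The t statistic (a single number).
#' @examples
#' t_statistic(c(1, 2, 3), c(4, 5, 6))   # -3.674
#' @export
t_statistic <- function(x1, x2, welch = FALSE) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop("each group needs at least 2 values")
  n1 <- length(x1); n2 <- length(x2)
  d <- mean(x1) - mean(x2)
  if (welch) {
    se <- sqrt(stats::var(x1) / n1 + stats::var(x2) / n2)
  } else {
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    if (d == 0) return(0)
    return(sign(d) * Inf)
  }
  d / se
}

## Row-wise pooled t for every gene at once: idx1/idx2 are column indices.
.row_t_stats <- function(m, idx1, idx2, welch = FALSE) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  ss1 <- rowSums((m[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx2, drop = FALSE] - m2)^2)
  d <- m1 - m2
  if (welch) {
    se <- sqrt(ss1 / (n1 - 1L) / n1 + ss2 / (n2 - 1L) / n2)
  } else {
    se <- sqrt((ss1 + ss2) / (n1 + n2 - 2L) * (1 / n1 + 1 / n2))
  }
  t <- d / se
  zero <- se == 0
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  t
}

#' Enumerate all two-group label assignments
#'
#' All distinct ways to choose which \code{n1} of the \code{n1 + n2} sample
#' positions carry the first label, in deterministic lexicographic order. The
#' observed labelling is always among them.
#'
#' @param n1,n2 group sizes, each >= 2.
#' @return Integer matrix with \code{n1} rows; each of the
#'   \code{choose(n1 + n2, n1)} columns lists the positions assigned to
#'   group 1.
#' @examples
#' ncol(enumerate_label_assignments(3, 3))  # 20
#' @export
enumerate_label_assignments <- function(n1, n2) {
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  utils::combn(n1 + n2, n1)
}

#' Build the permutation null of the t-statistic
#'
#' Computes the gene-wise t-statistic under every distinct relabelling of the
#' samples into the two observed group sizes ("all possible combinations").
#' The statistics are pooled across genes into one empirical null multiset:
#' with only \code{choose(n1 + n2, n1)} assignments (20 for a 3 vs 3 design),
#' a per-gene null cannot resolve p-values below 1/20, so pooling across
#' genes is what makes FDR thresholds such as 0.05 attainable.
#'
#' By default the observed labelling and its label swap (the same partition
#' with the group names exchanged) are excluded from the pooled null: they
#' realize the alternative, not the null, and because each gene would
#' contribute its own |t| to the pool twice, keeping them imposes a hard
#' q-value floor of \eqn{2\hat\pi_0/C} (0.09 for a 3 vs 3 design) that makes
#' an FDR threshold of 0.05 unattainable for any gene, however strong its
#' effect. \code{null_stats} always holds all assignments;
#' \code{exclude_observed} only controls which enter \code{pooled}.
#'
#' @param log_matrix genes-by-samples matrix of log2 expression values.
#' @param groups two-level factor (or named vector) over the columns.
#' @param welch use Welch t statistics.
#' @param exclude_observed drop the observed partition (and, for balanced
#'   designs, its label swap) from the pooled null (default TRUE).
#' @return An object of class \code{"permutation_null"}: list with
#'   \code{assignments} (from \code{\link{enumerate_label_assignments}}),
#'   \code{null_stats} (assignments x genes matrix), \code{pooled} (flattened
#'   multiset), \code{observed_index} (column of the identity assignment) and
#'   \code{null_index} (columns contributing to \code{pooled}).
#' @export
build_null <- function(log_matrix, groups, welch = FALSE,
                       exclude_observed = TRUE) {
  groups <- .align_groups(groups, colnames(log_matrix))
  pos1 <- which(groups == levels(groups)[1L])
  asn <- enumerate_label_assignments(length(pos1),
                                     ncol(log_matrix) - length(pos1))
  all_pos <- seq_len(ncol(log_matrix))
  null_stats <- matrix(NA_real_, nrow = ncol(asn), ncol = nrow(log_matrix),
                       dimnames = list(NULL, rownames(log_matrix)))
  for (a in seq_len(ncol(asn))) {
    i1 <- asn[, a]
    null_stats[a, ] <- .row_t_stats(log_matrix, i1, setdiff(all_pos, i1),
                                    welch = welch)
  }
  obs <- which(colSums(asn == sort(pos1)) == nrow(asn))[1L]
  drop <- obs
  pos2 <- sort(setdiff(all_pos, pos1))
  if (length(pos2) == nrow(asn)) {        # balanced: label swap is a column
    swap <- which(colSums(asn == pos2) == nrow(asn))[1L]
    drop <- c(drop, swap)
  }
  null_index <- if (exclude_observed)
    setdiff(seq_len(ncol(asn)), drop) else seq_len(ncol(asn))
  structure(list(assignments = asn, null_stats = null_stats,
                 pooled = as.numeric(null_stats[null_index, , drop = FALSE]),
                 observed_index = obs,
                 null_index = null_index),
            class = "permutation_null")
}

#' Empirical two-tailed p-values against a pooled null
#'
#' \eqn{p = (1 + \#\{t \in \mathrm{pooled}: |t| \ge |t_{obs}|\}) /
#' (1 + |\mathrm{pooled}|)}, so p always lies in (0, 1]. The add-one
#' smoothing (with the observed labelling already a member of the null)
#' keeps p strictly positive.
#'
#' @param t_obs observed statistic(s); vectorized.
#' @param pooled numeric vector, the pooled null multiset (or a
#'   \code{"permutation_null"} object).
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(t_obs, pooled) {
  if (inherits(pooled, "permutation_null")) pooled <- pooled$pooled
  if (length(pooled) == 0L) stop("empty null multiset")
  s <- sort(abs(pooled))               # ascending, Inf sorts last
  n <- length(s)
  n_less <- findInterval(abs(t_obs), s, left.open = TRUE)  # #{|t| < |t_obs|}
  (1 + (n - n_less)) / (1 + n)
}

#' Per-gene log2 fold changes on the log scale
#'
#' log2 fold change = mean of the second (test) group minus mean of the first
#' (reference) group of the log2 values; fold change = 2^log2fc.
#'
#' @param log_matrix genes-by-samples matrix of log2 values.
#' @param groups two-level factor (or named vector) over the columns; the
#'   first level is the reference.
#' @return data.frame with columns \code{log2fc} and \code{fold_change},
#'   rownames = genes.
#' @export
fold_changes <- function(log_matrix, groups) {
  groups <- .align_groups(groups, colnames(log_matrix))
  i_ref <- which(groups == levels(groups)[1L])
  i_test <- which(groups == levels(groups)[2L])
  lfc <- rowMeans(log_matrix[, i_test, drop = FALSE]) -
    rowMeans(log_matrix[, i_ref, drop = FALSE])
  data.frame(log2fc = lfc, fold_change = 2^lfc,
             row.names = rownames(log_matrix))
}

#' DEG calls from q-values and fold changes
#'
#' A gene is called differentially expressed when its q-value is below the
#' FDR threshold and its fold change exceeds the threshold in either
#' direction (ratio > \code{fc} up or down); direction follows the sign of
#' the log2 fold change.
#'
#' @param q q-values.
#' @param fold_change fold changes (2^log2fc).
#' @param fdr FDR threshold (default 0.05).
#' @param fc fold-change threshold, must exceed 1 (default 1.5).
#' @return data.frame with logical \code{is_deg} and factor \code{direction}
#'   (up/down/none).
#' @export
call_degs <- function(q, fold_change, fdr = 0.05, fc = 1.5) {
  if (fdr <= 0 || fdr >= 1) stop("'fdr' must lie in (0, 1)")
  if (fc <= 1) stop("'fc' must exceed 1")
  is_deg <- q < fdr & pmax(fold_change, 1 / fold_change) > fc
  direction <- ifelse(!is_deg, "none", ifelse(fold_change > 1, "up", "down"))
  data.frame(is_deg = is_deg,
             direction = factor(direction, levels = c("up", "down", "none")))
}

#' Permutation-null differential expression test
#'
#' The full gene-wise testing stage: pooled-variance Student t-statistics
#' (test group minus reference group), an exhaustively enumerated permutation
#' null pooled across genes, empirical two-tailed p-values, Storey q-values,
#' log2 fold changes and DEG calls.
#'
#' @param log_matrix genes-by-samples matrix of log2 expression values (from
#'   \code{\link{normalize_counts}}).
#' @param groups two-level factor or named vector over the columns; first
#'   level = reference/control, second = test.
#' @param fdr_threshold FDR cutoff for DEG calls (default 0.05).
#' @param fc_threshold two-sided fold-change cutoff (default 1.5).
#' @param storey_lambda Storey tuning parameter (default 0.5).
#' @param lambda_grid estimate pi0 on a lambda grid with spline smoothing
#'   instead of a single lambda.
#' @param per_gene_null calibrate each gene against its own assignments only
#'   (limited resolution: p >= 1/(1 + number of null assignments)).
#' @param welch use Welch t statistics.
#' @param exclude_observed see \code{\link{build_null}} (default TRUE).
#' @return A data.frame of class \code{"deg_table"} with one row per gene and
#'   columns \code{gene}, \code{t_stat}, \code{p_emp}, \code{q_value},
#'   \code{log2fc}, \code{fold_change}, \code{is_deg}, \code{direction}.
#'   Attributes: \code{pi0_hat}, \code{storey_lambda}, \code{n_assignments},
#'   \code{fdr_threshold}, \code{fc_threshold}.
#' @export
deg_test <- function(log_matrix, groups, fdr_threshold = 0.05,
                     fc_threshold = 1.5, storey_lambda = 0.5,
                     lambda_grid = FALSE, per_gene_null = FALSE,
                     welch = FALSE, exclude_observed = TRUE) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("'fdr_threshold' must lie in (0, 1)")
  if (fc_threshold <= 1) stop("'fc_threshold' must exceed 1")
  groups <- .align_groups(groups, colnames(log_matrix))

  null <- build_null(log_matrix, groups, welch = welch,
                     exclude_observed = exclude_observed)
  i_test <- which(groups == levels(groups)[2L])
  i_ref <- which(groups == levels(groups)[1L])
  t_obs <- .row_t_stats(log_matrix, i_test, i_ref, welch = welch)

  if (per_gene_null) {
    abs_null <- abs(null$null_stats[null$null_index, , drop = FALSE])
    p <- (1 + colSums(abs_null >= rep(abs(t_obs),
                                      each = nrow(abs_null)))) /
      (1 + nrow(abs_null))
  } else {
    p <- empirical_pvalue(t_obs, null$pooled)
  }

  st <- storey_qvalues(p, lambda = storey_lambda, lambda_grid = lambda_grid)
  fc <- fold_changes(log_matrix, groups)
  calls <- call_degs(st$q_values, fc$fold_change,
                     fdr = fdr_threshold, fc = fc_threshold)

  out <- data.frame(gene = rownames(log_matrix), t_stat = t_obs,
                    p_emp = p, q_value = st$q_values,
                    log2fc = fc$log2fc, fold_change = fc$fold_change,
                    is_deg = calls$is_deg, direction = calls$direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "pi0_hat") <- st$pi0_hat
  attr(out, "storey_lambda") <- st$lambda
  attr(out, "n_assignments") <- ncol(null$assignments)
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "fc_threshold") <- fc_threshold
  out
}

#' Volcano table for a DEG result
#'
#' The (gene, log2 fold change, -log10 p) table behind the standard volcano
#' plot.
#'
#' @param deg a \code{"deg_table"} from \code{\link{deg_test}}.
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{neg_log10_p}, \code{direction}.
#' @export
volcano_table <- function(deg) {
  data.frame(gene = deg$gene, log2fc = deg$log2fc,
             neg_log10_p = -log10(deg$p_emp),
             direction = deg$direction, stringsAsFactors = FALSE)
}
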