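#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization. For each sample k
#' against a reference sample r, gene-wise log ratios
#' \eqn{M_g = \log_2\{(y_{gk}/N_k) / (y_{gr}/N_r)\}} and average abundances
#' \eqn{A_g = \tfrac12 \log_2\{(y_{gk}/N_k)(y_{gr}/N_r)\}} are computed over
#' genes with positive counts in both samples (library sizes \eqn{N} are
#' column totals). The most extreme \code{trim_m} of the M values and
#' \code{trim_a} of the A values are trimmed from each tail, and the scaling
#' factor is \eqn{2^{\bar M_w}} where \eqn{\bar M_w} is the mean of the
#' surviving M values weighted by the inverse of their asymptotic binomial
#' variance \eqn{(N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})}.
#' Factors are rescaled so their geometric mean is 1.
#'
#' Trim ranks are assigned by a stable sort (ties broken by gene order), and
#' genes are kept only when their rank lies strictly inside the trimmed band
#' for both M and A, so the factor is a deterministic function of the input.
#'
#' @param counts a \code{\link{count_matrix}} or genes-by-samples matrix with
#'   at least two samples, each with positive total count.
#' @param trim_m proportion of M values trimmed from each tail (default 0.30,
#'   the method's published default).
#' @param trim_a proportion of A values trimmed from each tail (default 0.05).
#' @param reference reference sample id or column index; by default the
#'   sample whose 75th-percentile count fraction is closest to the mean of
#'   those fractions across samples.
#' @return Named numeric vector of per-sample factors with geometric mean 1;
#'   the chosen reference sample id is attached as attribute
#'   \code{"reference"}.
#' @examples
#' m <- matrix(rpois(400, 100), 100, 4,
#'             dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
#' compute_tmm_factors(m)
#' @export
compute_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                                reference = NULL) {
  y <- .as_count_mat(counts)
  if (ncol(y) < 2L) stop("TMM needs at least 2 samples")
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stop("trim proportions must lie in [0, 0.5)")
  lib <- colSums(y)
  if (any(lib <= 0)) stop("every sample must have positive total count")

  if (is.null(reference)) {
    f75 <- apply(y, 2L, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(y))
    if (is.na(ref)) stop(sprintf("reference sample '%s' not found", reference))
  } else {
    ref <- as.integer(reference)
  }

  f <- vapply(seq_len(ncol(y)), function(k) {
    .tmm_pair(y[, k], y[, ref], lib[k], lib[ref], trim_m, trim_a,
              sample_id = colnames(y)[k])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  attr(f, "reference") <- colnames(y)[ref]
  f
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a,
                      sample_id = "?") {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop(sprintf("sample '%s' shares no positive gene with the reference",
                 sample_id))
  o <- obs[pos]; r <- ref[pos]
  m_val <- log2((o / n_obs) / (r / n_ref))
  # identical proportion profiles (incl. sample vs itself): factor exactly 1
  if (max(abs(m_val)) < 1e-6) return(1)
  a_val <- 0.5 * log2((o / n_obs) * (r / n_ref))
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)

  n <- length(m_val)
  lo_m <- floor(n * trim_m) + 1L; hi_m <- n + 1L - lo_m
  lo_a <- floor(n * trim_a) + 1L; hi_a <- n + 1L - lo_a
  r_m <- .stable_rank(m_val)
  r_a <- .stable_rank(a_val)
  keep <- r_m >= lo_m & r_m <= hi_m & r_a >= lo_a & r_a <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m_val[keep] / v[keep]) / sum(1 / v[keep]))
}

## ranks from a stable sort: ties resolved by original (gene) order
.stable_rank <- function(x) {
  r <- integer(length(x))
  r[order(x)] <- seq_along(x)
  r
}

#' Pseudocount log2 transform of normalized counts
#'
#' Rescales each sample's counts to a common effective sequencing depth (the
#' mean of the TMM-effective library sizes \eqn{N_k f_k}), adds a pseudocount,
#' and takes log2, so a zero count maps to 0 when \code{pseudocount = 1}. With
#' \code{rescale = FALSE} the pseudocount log transform is applied to the raw
#' counts instead.
#'
#' @param counts a \code{\link{count_matrix}} or matrix.
#' @param factors per-sample factors from \code{\link{compute_tmm_factors}}
#'   (ignored when \code{rescale = FALSE}).
#' @param pseudocount positive constant added before the log (default 1).
#' @param rescale rescale counts to the mean effective depth first
#'   (default TRUE).
#' @return Matrix of log2 values, same dimnames as the input.
#' @export
log2_pseudocount <- function(counts, factors, pseudocount = 1,
                             rescale = TRUE) {
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  y <- .as_count_mat(counts)
  if (rescale) {
    if (!is.null(names(factors))) factors <- factors[colnames(y)]
    if (length(factors) != ncol(y) || any(!is.finite(factors) | factors <= 0))
      stop("'factors' must be one positive value per sample")
    eff <- colSums(y) * factors
    y <- sweep(y, 2L, eff, "/") * mean(eff)
  }
  log2(y + pseudocount)
}

#' TMM normalization plus log2 transform
#'
#' Convenience wrapper combining \code{\link{compute_tmm_factors}} and
#' \code{\link{log2_pseudocount}}.
#'
#' @inheritParams compute_tmm_factors
#' @inheritParams log2_pseudocount
#' @return An object of class \code{"normalization_result"}: list with
#'   \code{factors}, \code{effective_lib_sizes}, \code{log_matrix} and
#'   \code{reference_sample}.
#' @export
normalize_counts <- function(counts, trim_m = 0.30, trim_a = 0.05,
                             reference = NULL, pseudocount = 1,
                             rescale = TRUE) {
  y <- .as_count_mat(counts)
  f <- compute_tmm_factors(y, trim_m = trim_m, trim_a = trim_a,
                           reference = reference)
  structure(list(
    factors = f,
    effective_lib_sizes = colSums(y) * as.numeric(f),
    log_matrix = log2_pseudocount(y, f, pseudocount = pseudocount,
                                  rescale = rescale),
    reference_sample = attr(f, "reference")
  ), class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization_result: %d genes x %d samples, reference '%s'\n",
              nrow(x$log_matrix), ncol(x$log_matrix), x$reference_sample))
  print(round(as.numeric(x$factors), 4))
  invisible(x)
}
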