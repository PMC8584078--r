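#' Specification of a synthetic two-group RNA-seq experiment
#'
#' Parameters of the negative-binomial count generator. Defaults emulate the
#' design the pipeline targets: a bulk mRNA-seq comparison of mutant versus
#' normal fibroblasts with three biological replicates per condition, on the
#' order of 15,000 expressed genes, a minority of genes truly differentially
#' expressed in both directions, per-sample library-size variation, and
#' optional composition bias.
#'
#' @param n_genes number of genes (default 15000).
#' @param n_per_group biological replicates per condition (default 3; at
#'   least 2, or the t-test is undefined).
#' @param pi_de proportion of genes truly differentially expressed
#'   (default 0.1).
#' @param log2fc_range range of |log2 fold change| for planted effects
#'   (default c(1, 2)).
#' @param prop_down probability a planted effect is downregulation
#'   (default 0.5, i.e. symmetric in sign; raise it to emulate a
#'   down-dominated response).
#' @param dispersion negative-binomial dispersion phi >= 0 in the
#'   mean/dispersion parameterization (variance = mu + phi mu^2); 0 gives
#'   Poisson counts. Default 0.1, typical of biological replicates.
#' @param lib_size_range range of expected per-sample totals
#'   (default c(1e7, 2e7)).
#' @param composition_bias optional per-sample multiplier (named by sample
#'   id, or one value per sample in column order) applied to the expected
#'   counts of a random subset of genes in that sample; NULL means no bias.
#' @param bias_gene_fraction fraction of genes carrying the composition bias
#'   (default 0.05). A factor applied to all genes alike would be absorbed
#'   into the library size, so bias is planted on a gene subset.
#' @param abundance_sdlog sdlog of the log-normal baseline abundance
#'   distribution (default 2, reproducing the dynamic range of bulk
#'   expression).
#' @param seed integer seed (default 1).
#' @return An object of class \code{"simulation_spec"} (a validated list).
#' @export
simulation_spec <- function(n_genes = 15000, n_per_group = 3, pi_de = 0.1,
                            log2fc_range = c(1, 2), prop_down = 0.5,
                            dispersion = 0.1,
                            lib_size_range = c(1e7, 2e7),
                            composition_bias = NULL,
                            bias_gene_fraction = 0.05,
                            abundance_sdlog = 2, seed = 1) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (n_per_group < 2) stop("'n_per_group' must be >= 2 (t-test undefined)")
  if (pi_de < 0 || pi_de > 1) stop("'pi_de' must lie in [0, 1]")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (any(lib_size_range <= 0)) stop("library sizes must be positive")
  if (length(log2fc_range) != 2L || log2fc_range[1] > log2fc_range[2])
    stop("'log2fc_range' must be an increasing interval")
  if (prop_down < 0 || prop_down > 1) stop("'prop_down' must lie in [0, 1]")
  if (bias_gene_fraction <= 0 || bias_gene_fraction > 1)
    stop("'bias_gene_fraction' must lie in (0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 pi_de = pi_de, log2fc_range = log2fc_range,
                 prop_down = prop_down, dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 composition_bias = composition_bias,
                 bias_gene_fraction = bias_gene_fraction,
                 abundance_sdlog = abundance_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a two-group negative-binomial count matrix with ground truth
#'
#' Counts are drawn from a negative-binomial model: the expected count of
#' gene g in sample j is
#' \eqn{\mu_{gj} = L_j \, q_g \, 2^{\delta_g [j \in \mathrm{test}]} b_{gj}},
#' with per-gene relative abundances \eqn{q_g} drawn log-normal and
#' normalized to sum to 1, expected library sizes \eqn{L_j} uniform on the
#' requested range, planted log2 effects \eqn{\delta_g} on a random
#' \code{pi_de} fraction of genes, and composition-bias multipliers
#' \eqn{b_{gj}} on the biased gene subset. Dispersion 0 degenerates to
#' Poisson. Fully deterministic under a fixed seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{counts} (a \code{\link{count_matrix}}; groups
#'   "control" then "test") and \code{truth}, an object of class
#'   \code{"synthetic_truth"}: \code{de_genes}, \code{log2fc_of} (named,
#'   zero for non-DE genes), \code{pi0_true}, \code{abundance} (the
#'   \eqn{q_g}), \code{bias_genes}, \code{composition_bias},
#'   \code{expected_lib_sizes}.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  s <- 2L * spec$n_per_group
  genes <- sprintf("gene_%05d", seq_len(g))
  samples <- c(sprintf("control_%d", seq_len(spec$n_per_group)),
               sprintf("test_%d", seq_len(spec$n_per_group)))

  q <- stats::rlnorm(g, meanlog = 0, sdlog = spec$abundance_sdlog)
  q <- q / sum(q)

  n_de <- round(spec$pi_de * g)
  lfc <- numeric(g)
  if (n_de > 0) {
    de_idx <- sort(sample.int(g, n_de))
    mag <- stats::runif(n_de, spec$log2fc_range[1], spec$log2fc_range[2])
    sgn <- ifelse(stats::runif(n_de) < spec$prop_down, -1, 1)
    lfc[de_idx] <- mag * sgn
  } else {
    de_idx <- integer(0)
  }

  lib <- stats::runif(s, spec$lib_size_range[1], spec$lib_size_range[2])

  bias <- rep(1, s)
  names(bias) <- samples
  if (!is.null(spec$composition_bias)) {
    cb <- spec$composition_bias
    if (!is.null(names(cb))) {
      unknown <- setdiff(names(cb), samples)
      if (length(unknown))
        stop(sprintf("composition_bias names unknown sample '%s'",
                     unknown[1L]))
      bias[names(cb)] <- cb
    } else {
      if (length(cb) != s)
        stop("'composition_bias' must be named or one value per sample")
      bias[] <- cb
    }
    if (any(bias <= 0)) stop("composition bias factors must be positive")
  }
  bias_genes <- if (any(bias != 1))
    sort(sample.int(g, round(spec$bias_gene_fraction * g))) else integer(0)

  mu <- outer(q, lib)
  test_cols <- (spec$n_per_group + 1L):s
  mu[, test_cols] <- mu[, test_cols] * 2^lfc
  for (j in which(bias != 1))
    mu[bias_genes, j] <- mu[bias_genes, j] * bias[j]

  counts <- if (spec$dispersion > 0) {
    matrix(stats::rnbinom(g * s, mu = mu, size = 1 / spec$dispersion), g, s)
  } else {
    matrix(stats::rpois(g * s, lambda = mu), g, s)
  }
  dimnames(counts) <- list(genes, samples)
  groups <- stats::setNames(
    rep(c("control", "test"), each = spec$n_per_group), samples)

  truth <- structure(list(
    de_genes = genes[de_idx],
    log2fc_of = stats::setNames(lfc, genes),
    pi0_true = mean(lfc == 0),
    abundance = stats::setNames(q, genes),
    bias_genes = genes[bias_genes],
    composition_bias = bias,
    expected_lib_sizes = stats::setNames(lib, samples)
  ), class = "synthetic_truth")

  list(counts = count_matrix(counts, groups), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d genes, %d DE (pi0 = %.3f), %d bias genes\n",
    length(x$log2fc_of), length(x$de_genes), x$pi0_true,
    length(x$bias_genes)))
  invisible(x)
}

#' Simulate gene-set collections with spiked enriched terms
#'
#' Background terms sample genes uniformly from the universe; spiked terms
#' oversample the truly DE genes by \code{enrichment_factor} (sampling
#' weight \code{enrichment_factor} for DE genes, 1 otherwise). Which terms
#' were spiked is recorded in the \code{"spiked_terms"} attribute.
#'
#' @param truth a \code{"synthetic_truth"} from \code{\link{simulate_counts}}
#'   (only \code{de_genes} is used).
#' @param universe character vector of candidate genes.
#' @param n_terms number of gene sets (default 50).
#' @param size_range range of set sizes (default c(20, 200)); must not
#'   exceed the universe size.
#' @param spiked_terms how many terms to spike (default 5; must be
#'   <= n_terms).
#' @param enrichment_factor oversampling weight for DE genes in spiked terms
#'   (default 10; 1 makes spiked terms indistinguishable from background).
#' @param seed integer seed.
#' @return A \code{\link{gene_set_collection}} with the universe set and
#'   attribute \code{"spiked_terms"}.
#' @export
simulate_gene_sets <- function(truth, universe, n_terms = 50,
                               size_range = c(20, 200), spiked_terms = 5,
                               enrichment_factor = 10, seed = 1) {
  if (spiked_terms > n_terms) stop("'spiked_terms' must be <= 'n_terms'")
  if (max(size_range) > length(universe))
    stop("'size_range' exceeds the universe size")
  if (enrichment_factor <= 0) stop("'enrichment_factor' must be positive")
  set.seed(seed)
  if (n_terms == 0L) {
    out <- gene_set_collection(list(), universe = universe)
    attr(out, "spiked_terms") <- character(0)
    return(out)
  }
  w <- ifelse(universe %in% truth$de_genes, enrichment_factor, 1)
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  names <- sprintf("term_%03d", seq_len(n_terms))
  sets <- lapply(seq_len(n_terms), function(i) {
    if (i <= spiked_terms) sample(universe, sizes[i], prob = w)
    else sample(universe, sizes[i])
  })
  names(sets) <- names
  out <- gene_set_collection(sets, universe = universe)
  attr(out, "spiked_terms") <- names[seq_len(spiked_terms)]
  out
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Reference-gene Ct values are constant within each condition; target Ct
#' values are \code{baseline - log2(fold change)} in the test condition plus
#' Gaussian noise. With zero noise the delta-delta-Ct calculator recovers
#' the planted fold changes exactly.
#'
#' @param n_targets number of target genes.
#' @param true_fold_changes positive fold changes, one per target (recycled).
#' @param ct_noise_sd standard deviation of Gaussian Ct noise (default 0.1
#'   cycles).
#' @param n_replicates biological replicates per condition (default 3).
#' @param seed integer seed.
#' @param reference_gene reference gene name (default "GAPDH").
#' @param baseline_ct control-condition target Ct (default 24 cycles).
#' @param reference_ct reference-gene Ct (default 18 cycles).
#' @return data.frame (gene, sample, condition, ct) with attributes
#'   \code{"reference_gene"} and \code{"true_fold_changes"}.
#' @export
simulate_ct_table <- function(n_targets = 3,
                              true_fold_changes = rep(2, n_targets),
                              ct_noise_sd = 0.1, n_replicates = 3, seed = 1,
                              reference_gene = "GAPDH", baseline_ct = 24,
                              reference_ct = 18) {
  if (any(true_fold_changes <= 0)) stop("fold changes must be positive")
  if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0")
  set.seed(seed)
  fc <- rep_len(true_fold_changes, n_targets)
  targets <- sprintf("target_%02d", seq_len(n_targets))
  samples <- list(control = sprintf("control_%d", seq_len(n_replicates)),
                  test = sprintf("test_%d", seq_len(n_replicates)))
  rows <- list()
  for (cond in c("control", "test")) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = reference_gene, sample = samples[[cond]], condition = cond,
      ct = reference_ct, stringsAsFactors = FALSE)
    for (i in seq_len(n_targets)) {
      mu <- baseline_ct - if (cond == "test") log2(fc[i]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = targets[i], sample = samples[[cond]], condition = cond,
        ct = mu + stats::rnorm(n_replicates, sd = ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  attr(out, "true_fold_changes") <- stats::setNames(fc, targets)
  out
}
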