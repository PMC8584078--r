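# small fixtures built in code, shared across test files

# deterministic 3-gene x 6-sample count matrix with named groups
tiny_count_matrix <- function() {
  m <- matrix(c(10, 20, 30, 12, 18, 33, 11, 22, 28,
                40, 5, 60, 38, 6, 55, 42, 4, 65),
              nrow = 3,
              dimnames = list(c("geneA", "geneB", "geneC"),
                              c(paste0("ctl_", 1:3), paste0("mut_", 1:3))))
  count_matrix(m, setNames(rep(c("control", "test"), each = 3),
                           colnames(m)))
}

tiny_groups <- function() {
  setNames(rep(c("control", "test"), each = 3),
           c(paste0("ctl_", 1:3), paste0("mut_", 1:3)))
}

# write a count TSV and sample sheet into a temp dir; returns the paths
write_tiny_tsv <- function(cm = tiny_count_matrix(), dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  counts_path <- file.path(dir, "counts.tsv")
  sheet_path <- file.path(dir, "samples.tsv")
  write_count_matrix(cm, counts_path)
  write_sample_sheet(cm, sheet_path)
  list(counts = counts_path, sheet = sheet_path, dir = dir)
}

# a minimal hand-made deg_table (for enrichment/network tests)
fake_deg_table <- function(genes, deg_genes = character(),
                           up = deg_genes) {
  is_deg <- genes %in% deg_genes
  direction <- ifelse(!is_deg, "none", ifelse(genes %in% up, "up", "down"))
  out <- data.frame(gene = genes, t_stat = 0, p_emp = 1, q_value = 1,
                    log2fc = ifelse(direction == "up", 1,
                                    ifelse(direction == "down", -1, 0)),
                    fold_change = 1, is_deg = is_deg,
                    direction = factor(direction,
                                       levels = c("up", "down", "none")),
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

# independent exhaustive subset generator (bitmask-based), used as the
# oracle for the label-assignment enumeration
bitmask_subsets <- function(n, k) {
  sets <- list()
  for (mask in 0:(2^n - 1)) {
    bits <- which(as.integer(intToBits(mask))[1:n] == 1L)
    if (length(bits) == k) sets[[length(sets) + 1L]] <- bits
  }
  sets
}

# brute-force hypergeometric upper tail via log-binomials (independent of
# stats::phyper)
brute_hyper_tail <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
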