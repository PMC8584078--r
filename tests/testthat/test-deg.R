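test_that("pooled t-statistic matches hand and t.test evaluations", {
  expect_identical(t_statistic(c(5, 5, 5), c(5, 5, 5)), 0)
  # mean diff -3, pooled sd 1, se sqrt(2/3)
  expect_equal(t_statistic(1:3, 4:6), -3 / sqrt(2 / 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5, 1)
    expect_equal(t_statistic(x, y),
                 unname(t.test(x, y, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    expect_equal(t_statistic(x, y, welch = TRUE),
                 unname(t.test(x, y)$statistic), tolerance = 1e-10)
    # antisymmetry
    expect_identical(t_statistic(x, y), -t_statistic(y, x))
  }
  expect_error(t_statistic(1, c(2, 3)), "at least 2")
})

test_that("zero pooled variance with unequal means gives a signed Inf", {
  expect_identical(t_statistic(c(2, 2), c(1, 1)), Inf)
  expect_identical(t_statistic(c(1, 1), c(3, 3)), -Inf)
})

test_that("row-wise t statistics equal the scalar version", {
  set.seed(2)
  m <- matrix(rnorm(60), 10, 6)
  rt <- permdeg:::.row_t_stats(m, 1:3, 4:6)
  for (g in 1:10)
    expect_equal(rt[g], t_statistic(m[g, 1:3], m[g, 4:6]),
                 tolerance = 1e-12)
})

test_that("label assignments are exhaustive, distinct and include identity", {
  expect_identical(ncol(enumerate_label_assignments(3, 3)), 20L)
  expect_identical(ncol(enumerate_label_assignments(2, 2)), 6L)
  for (n1 in 2:4) for (n2 in 2:4) {
    asn <- enumerate_label_assignments(n1, n2)
    cols <- apply(asn, 2, paste, collapse = ",")
    expect_identical(anyDuplicated(cols), 0L)
    oracle <- vapply(bitmask_subsets(n1 + n2, n1), paste, character(1),
                     collapse = ",")
    expect_setequal(cols, oracle)
    expect_true(paste(1:n1, collapse = ",") %in% cols)
  }
  expect_error(enumerate_label_assignments(1, 3), "at least 2")
})

test_that("the pooled null excludes the observed partition by default", {
  set.seed(3)
  m <- matrix(rnorm(6), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  grp <- setNames(rep(c("a", "b"), each = 3), colnames(m))
  nl <- build_null(m, grp)
  expect_identical(dim(nl$null_stats), c(20L, 1L))
  expect_length(nl$pooled, 18L)            # identity + label swap removed
  expect_length(nl$null_index, 18L)

  nl_all <- build_null(m, grp, exclude_observed = FALSE)
  expect_length(nl_all$pooled, 20L)
  t_obs <- t_statistic(m[1, 1:3], m[1, 4:6])
  expect_true(any(abs(nl_all$pooled - (-t_obs)) < 1e-12) ||
                any(abs(nl_all$pooled - t_obs) < 1e-12))

  # unbalanced design: only the identity can be removed
  m2 <- matrix(rnorm(5), 1, 5, dimnames = list("g1", paste0("s", 1:5)))
  grp2 <- setNames(c("a", "a", "b", "b", "b"), colnames(m2))
  nl2 <- build_null(m2, grp2)
  expect_identical(ncol(nl2$assignments), 10L)  # choose(5, 2)
  expect_length(nl2$pooled, 9L)
})

test_that("the pooled null is symmetric on exchangeable data", {
  sim <- simulate_counts(simulation_spec(n_genes = 1000, pi_de = 0,
                                         seed = 21))
  norm <- normalize_counts(sim$counts)
  nl <- build_null(norm$log_matrix, sim$counts$groups)
  pooled <- nl$pooled[is.finite(nl$pooled)]
  expect_lt(abs(mean(pooled)), 3 * sd(pooled) / sqrt(length(pooled)))
})

test_that("empirical p-values count tail mass with add-one smoothing", {
  expect_identical(empirical_pvalue(0, c(-2, -1, 0, 1, 2)), 1)
  expect_identical(empirical_pvalue(1.5, c(-2, -1, 0, 1, 2)), 0.5)
  expect_identical(empirical_pvalue(99, c(-2, -1, 0, 1, 2)), 1 / 6)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")

  # vectorized computation agrees with a naive loop, Inf included
  set.seed(4)
  pooled <- c(rnorm(500), Inf, -Inf)
  t_obs <- c(rnorm(50), Inf, 0)
  naive <- vapply(t_obs, function(t)
    (1 + sum(abs(pooled) >= abs(t))) / (1 + length(pooled)), numeric(1))
  expect_equal(empirical_pvalue(t_obs, pooled), naive, tolerance = 1e-15)
})

test_that("fold changes and DEG calls follow the thresholds", {
  lm <- rbind(g1 = c(1, 1, 1, 2, 2, 2),
              g2 = c(3, 3, 3, 2, 2, 2),
              g3 = c(5, 5, 5, 5, 5, 5))
  colnames(lm) <- paste0("s", 1:6)
  grp <- setNames(rep(c("ctl", "mut"), each = 3), colnames(lm))
  fc <- fold_changes(lm, grp)
  expect_equal(fc["g1", "fold_change"], 2)    # +1 log2 difference
  expect_equal(fc["g2", "fold_change"], 0.5)  # -1 log2 difference
  expect_equal(fc["g3", "fold_change"], 1)

  calls <- call_degs(q = c(0.01, 0.04, 0.20),
                     fold_change = c(2.0, 1.2, 3.0))
  expect_identical(calls$is_deg, c(TRUE, FALSE, FALSE))
  expect_identical(as.character(calls$direction), c("up", "none", "none"))
  # downregulation passes the two-sided fold-change rule
  down <- call_degs(q = 0.01, fold_change = 0.4)
  expect_identical(as.character(down$direction), "down")
  expect_error(call_degs(0.01, 2, fc = 1.0), "exceed 1")
})

test_that("swapping the group labels mirrors the statistics", {
  sim <- simulate_counts(simulation_spec(n_genes = 400, pi_de = 0.2,
                                         seed = 31))
  norm <- normalize_counts(sim$counts)
  grp <- sim$counts$groups
  deg1 <- deg_test(norm$log_matrix, grp)
  flipped <- factor(as.character(grp), levels = rev(levels(grp)))
  names(flipped) <- names(grp)
  deg2 <- deg_test(norm$log_matrix, flipped)
  expect_equal(deg2$t_stat, -deg1$t_stat, tolerance = 1e-12)
  expect_equal(deg2$log2fc, -deg1$log2fc, tolerance = 1e-12)
  expect_equal(deg2$fold_change, 1 / deg1$fold_change, tolerance = 1e-12)
  expect_equal(deg2$p_emp, deg1$p_emp, tolerance = 1e-12)
  expect_equal(deg2$q_value, deg1$q_value, tolerance = 1e-12)
  expect_identical(deg2$is_deg, deg1$is_deg)
})

test_that("per-gene null mode has the expected limited resolution", {
  sim <- simulate_counts(simulation_spec(n_genes = 100, pi_de = 0.3,
                                         seed = 41))
  norm <- normalize_counts(sim$counts)
  deg <- deg_test(norm$log_matrix, sim$counts$groups, per_gene_null = TRUE)
  expect_gte(min(deg$p_emp), 1 / 19)   # 18 null assignments + smoothing
  expect_true(all(abs(deg$p_emp * 19 - round(deg$p_emp * 19)) < 1e-9))
})

test_that("deg_test output satisfies its structural invariants", {
  sim <- simulate_counts(simulation_spec(n_genes = 300, pi_de = 0.1,
                                         seed = 51))
  norm <- normalize_counts(sim$counts)
  deg <- deg_test(norm$log_matrix, sim$counts$groups)
  expect_true(all(deg$p_emp > 0 & deg$p_emp <= 1))
  expect_true(all(deg$q_value > 0 & deg$q_value <= 1))
  expect_equal(deg$fold_change, 2^deg$log2fc, tolerance = 1e-12)
  expect_identical(deg$is_deg,
                   deg$q_value < 0.05 &
                     pmax(deg$fold_change, 1 / deg$fold_change) > 1.5)
  expect_identical(deg$direction == "up", deg$is_deg & deg$log2fc > 0)
  expect_error(deg_test(norm$log_matrix, sim$counts$groups,
                        fc_threshold = 1.0), "exceed 1")
  vt <- volcano_table(deg)
  expect_identical(colnames(vt),
                   c("gene", "log2fc", "neg_log10_p", "direction"))
  expect_equal(vt$neg_log10_p, -log10(deg$p_emp))
})
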