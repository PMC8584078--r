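test_that("simulation spec validates its arguments", {
  expect_error(simulation_spec(n_per_group = 1), "t-test undefined")
  expect_error(simulation_spec(pi_de = 1.2), "pi_de")
  expect_error(simulation_spec(dispersion = -1), "dispersion")
  expect_error(simulation_spec(lib_size_range = c(-1, 10)), "positive")
})

test_that("no planted effects means an empty truth and pi0 = 1", {
  sim <- simulate_counts(simulation_spec(n_genes = 200, pi_de = 0, seed = 3))
  expect_length(sim$truth$de_genes, 0L)
  expect_identical(sim$truth$pi0_true, 1)
  expect_true(all(sim$truth$log2fc_of == 0))
})

test_that("the generator is deterministic under a fixed seed", {
  spec <- simulation_spec(n_genes = 300, pi_de = 0.2, seed = 17)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$log2fc_of, b$truth$log2fc_of)
  c <- simulate_counts(simulation_spec(n_genes = 300, pi_de = 0.2,
                                       seed = 18))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("planted truth matches the requested design", {
  spec <- simulation_spec(n_genes = 1000, pi_de = 0.1,
                          log2fc_range = c(1, 2), prop_down = 0.5, seed = 5)
  sim <- simulate_counts(spec)
  tr <- sim$truth
  expect_length(tr$de_genes, 100L)
  expect_equal(tr$pi0_true, 0.9)
  planted <- tr$log2fc_of[tr$de_genes]
  expect_true(all(abs(planted) >= 1 & abs(planted) <= 2))
  expect_true(any(planted > 0) && any(planted < 0))
  # pi0_true is exactly the fraction of genes with zero planted effect
  expect_identical(tr$pi0_true, mean(tr$log2fc_of == 0))
})

test_that("per-gene sample means follow the stated mean model", {
  # many samples per group, no DE, fixed library size: the mean of
  # count/libsize should sit within 3 standard errors of q_g for >= 99%
  # of genes
  spec <- simulation_spec(n_genes = 2000, n_per_group = 100, pi_de = 0,
                          dispersion = 0.1, lib_size_range = c(1e6, 1e6),
                          seed = 9)
  sim <- simulate_counts(spec)
  y <- sim$counts$counts
  q <- sim$truth$abundance
  n <- ncol(y)
  lib <- 1e6
  mu <- q * lib
  se <- sqrt((mu + 0.1 * mu^2) / n) / lib
  z <- abs(rowMeans(y / lib) - q) / se
  expect_gte(mean(z <= 3), 0.99)
})

test_that("count variance is consistent with the NB parameterization", {
  spec <- simulation_spec(n_genes = 2000, n_per_group = 100, pi_de = 0,
                          dispersion = 0.1, lib_size_range = c(1e6, 1e6),
                          seed = 10)
  sim <- simulate_counts(spec)
  y <- sim$counts$counts
  mu <- sim$truth$abundance * 1e6
  big <- mu > 100
  ratio <- apply(y[big, ], 1, var) / (mu[big] + 0.1 * mu[big]^2)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.2)
})

test_that("dispersion zero gives Poisson-scale variance", {
  spec <- simulation_spec(n_genes = 500, n_per_group = 100, pi_de = 0,
                          dispersion = 0, lib_size_range = c(1e5, 1e5),
                          seed = 11)
  sim <- simulate_counts(spec)
  y <- sim$counts$counts
  mu <- sim$truth$abundance * 1e5
  big <- mu > 50
  ratio <- apply(y[big, ], 1, var) / mu[big]
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.2)
})

test_that("gene-set simulation respects sizes, spiking and determinism", {
  universe <- sprintf("g%04d", 1:500)
  truth <- structure(list(de_genes = universe[1:50]),
                     class = "synthetic_truth")
  gs <- simulate_gene_sets(truth, universe, n_terms = 10,
                           size_range = c(5, 20), spiked_terms = 2,
                           enrichment_factor = 10, seed = 2)
  expect_length(gs$sets, 10L)
  expect_true(all(lengths(gs$sets) >= 5 & lengths(gs$sets) <= 20))
  expect_identical(attr(gs, "spiked_terms"), c("term_001", "term_002"))
  gs2 <- simulate_gene_sets(truth, universe, n_terms = 10,
                            size_range = c(5, 20), spiked_terms = 2,
                            enrichment_factor = 10, seed = 2)
  expect_identical(gs$sets, gs2$sets)

  expect_length(simulate_gene_sets(truth, universe, n_terms = 0,
                                   spiked_terms = 0)$sets, 0L)
  expect_error(simulate_gene_sets(truth, universe, n_terms = 5,
                                  size_range = c(5, 1000)),
               "universe")
  expect_error(simulate_gene_sets(truth, universe, n_terms = 2,
                                  spiked_terms = 5), "spiked_terms")
})

test_that("spiked terms oversample the DE genes", {
  universe <- sprintf("g%04d", 1:1000)
  truth <- structure(list(de_genes = universe[1:100]),
                     class = "synthetic_truth")
  gs <- simulate_gene_sets(truth, universe, n_terms = 20,
                           size_range = c(100, 100), spiked_terms = 5,
                           enrichment_factor = 10, seed = 4)
  frac_de <- vapply(gs$sets, function(s)
    mean(s %in% truth$de_genes), numeric(1))
  spiked <- names(gs$sets) %in% attr(gs, "spiked_terms")
  expect_gt(min(frac_de[spiked]), max(0.25, mean(frac_de[!spiked])))
})

test_that("zero-noise Ct tables encode the planted fold changes exactly", {
  ct <- simulate_ct_table(n_targets = 3, true_fold_changes = c(1, 2, 0.25),
                          ct_noise_sd = 0, seed = 1)
  r1 <- delta_delta_ct(ct, "target_01")
  expect_equal(r1$per_replicate$delta_delta_ct, rep(0, 6))
  expect_equal(r1$summary$mean_relative_level, c(1, 1))
  r2 <- delta_delta_ct(ct, "target_02")
  expect_equal(r2$summary$mean_relative_level[2], 2)
  r3 <- delta_delta_ct(ct, "target_03")
  expect_equal(r3$summary$mean_relative_level[2], 0.25)
})

test_that("noisy Ct tables recover fold changes within 15%", {
  ct <- simulate_ct_table(n_targets = 4,
                          true_fold_changes = c(2, 0.5, 1, 3),
                          ct_noise_sd = 0.1, n_replicates = 3, seed = 3)
  fc <- attr(ct, "true_fold_changes")
  for (g in names(fc)) {
    est <- delta_delta_ct(ct, g)$summary$mean_relative_level[2]
    expect_lt(abs(est / fc[[g]] - 1), 0.15)
  }
})
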