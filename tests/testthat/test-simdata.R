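test_that("architectures set the effect pattern they promise", {
  sc_null <- sim_scenario(architecture = "null", seed = 3)
  expect_true(all(poolburden:::architecture_betas(sc_null) == 0))
  sc_uni <- sim_scenario(architecture = "unidirectional", seed = 3)
  expect_true(all(poolburden:::architecture_betas(sc_uni) == log(3)))
  sc_bi <- sim_scenario(
    architecture = "bidirectional", variants_per_gene = 10, seed = 3
  )
  b <- poolburden:::architecture_betas(sc_bi)
  expect_equal(sum(b > 0), 5)
  expect_equal(sum(b < 0), 5)
  expect_equal(unique(abs(b)), log(3))
  sc_mix <- sim_scenario(
    architecture = "neutral_mix", variants_per_gene = 10, seed = 3
  )
  expect_equal(sum(poolburden:::architecture_betas(sc_mix) == 0), 5)
})

test_that("unidirectional sampling enriches carriers in cases", {
  sc <- sim_scenario(
    architecture = "unidirectional", variants_per_gene = 10,
    maf_shape1 = 2, maf_shape2 = 98, seed = 19
  )
  tr <- simulate_genotypes(sc)
  case <- tr$phenotype == "case"
  carrier_case <- mean(rowSums(tr$genotypes[case, ]) > 0)
  carrier_ctrl <- mean(rowSums(tr$genotypes[!case, ]) > 0)
  expect_gt(carrier_case, carrier_ctrl * 1.5)
  # intercept tuned near the rare-disease approximation
  expect_lt(tr$beta0, qlogis(sc$prevalence))
})

test_that("generation is deterministic in the seed", {
  sc <- sim_scenario(n_genes = 2, variants_per_gene = 4, seed = 55,
    n_cases = 24, n_controls = 24)
  t1 <- simulate_genotypes(sc)
  t2 <- simulate_genotypes(sc)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(t1$maf, t2$maf)
  s1 <- pool_and_sequence(t1)
  s2 <- pool_and_sequence(t2)
  expect_identical(
    as.data.frame(s1$variants), as.data.frame(s2$variants)
  )
  # and the written table is byte-identical across runs
  p1 <- withr::local_tempdir()
  p2 <- withr::local_tempdir()
  pool_and_sequence(t1, path = p1)
  pool_and_sequence(t2, path = p2)
  expect_identical(
    readLines(file.path(p1, "variants.tsv")),
    readLines(file.path(p2, "variants.tsv"))
  )
})

test_that("pooling conserves genotypes exactly", {
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 3, variants_per_gene = 5, architecture = "unidirectional",
    seed = 91, n_cases = 60, n_controls = 36
  ))
  expect_equal(
    colSums(sim$truth$true_counts),
    colSums(sim$truth$genotypes)
  )
  expect_equal(nrow(sim$design), 60 / 12 + 36 / 12)
  # per-pool counts respect the chromosome bound
  expect_true(all(sim$truth$true_counts <= 24))
})

test_that("pool size not dividing an arm truncates the last pool, warning", {
  expect_warning(
    sim <- simulate_pooled_study(sim_scenario(
      n_genes = 1, variants_per_gene = 3, seed = 5,
      n_cases = 30, n_controls = 24
    )),
    "truncated"
  )
  expect_equal(sim$design$n_individuals[sim$design$phenotype == "case"],
    c(12L, 12L, 6L))
})

test_that("MLAC recovers the true pool counts as depth grows and error
           vanishes", {
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 1, variants_per_gene = 10, architecture = "null",
    maf_shape1 = 5, maf_shape2 = 95, seed = 13,
    mean_depth = 1e5, depth_dispersion = Inf, error_rate = 0
  ))
  X <- mlac_matrix(sim$variants, sim$design)
  expect_identical(
    matrix(as.integer(X), nrow(X)),
    matrix(as.integer(sim$truth$true_counts), nrow(X))
  )
})

test_that("zero depth produces missing calls everywhere", {
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 1, variants_per_gene = 3, seed = 2, n_cases = 24,
    n_controls = 24, mean_depth = 0, depth_dispersion = Inf
  ))
  dp_cols <- grep("\\.dp$", names(sim$variants), value = TRUE)
  expect_true(all(is.na(as.matrix(sim$variants[dp_cols]))))
  mr <- missingness_report(sim$variants, sim$design)
  expect_true(all(mr$frac_missing == 1))
})

test_that("annotation classes realize their target mix", {
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 500, variants_per_gene = 20, architecture = "null",
    seed = 37, n_cases = 24, n_controls = 24, mean_depth = 30
  ))
  realized <- table(sim$variants$func_class) / nrow(sim$variants)
  expect_equal(unname(realized[["intergenic"]]), 0.325, tolerance = 0.02 / 0.325)
  expect_equal(unname(realized[["intronic"]]), 0.443, tolerance = 0.02 / 0.443)
  expect_lt(abs(realized[["missense"]] - 0.055), 0.02)
})

test_that("realized cohort MAF converges to the generating MAF", {
  # noise-free sequencing at high depth, MAFs well inside (0, 0.5)
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 40, variants_per_gene = 10, architecture = "null",
    maf_shape1 = 4, maf_shape2 = 96, seed = 53,
    mean_depth = 5000, depth_dispersion = Inf, error_rate = 0
  ))
  realized <- cohort_maf(sim$variants, sim$design)
  n_ind <- sum(sim$design$n_individuals)
  err <- abs(realized - sim$truth$maf)
  bound <- 3 * sqrt(sim$truth$maf / (2 * n_ind))
  expect_lte(mean(err), mean(bound))
  expect_lt(mean(err) / mean(sim$truth$maf), 0.25)
})

test_that("the tiny fixture spans exactly twenty label assignments", {
  fx <- make_fixture("tiny_enumerable")
  expect_equal(nrow(fx$design), 6L)
  expect_equal(choose(6, sum(fx$design$phenotype == "case")), 20)
  pt <- permutation_pvalue(
    mlac_matrix(fx$variants, fx$design), fx$design, "wss", B = 1000, seed = 1
  )
  expect_true(pt$exhaustive)
  expect_equal(pt$B, 20L)
})
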