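test_that("the WSS statistic matches its hand-evaluated definition", {
  # pools of size 1: 2 cases with counts (1, 0), 2 controls with (0, 0);
  # q = 1/6, w = sqrt(4 * (1/6) * (5/6)), scores (1.342, 0, 0, 0);
  # zeros tie at average rank 2, the carrier ranks 4: case rank sum 6
  d <- design_of(2, 2, 1)
  expect_equal(wss_statistic(matrix(c(1, 0, 0, 0), 4, 1), d), 6)

  # full tie: every score zero, case rank sum = n_case * (P + 1) / 2
  d2 <- design_of(3, 5, 12)
  expect_equal(wss_statistic(matrix(0, 8, 4), d2), 3 * 9 / 2)

  # rank invariance: scaling a single variant's counts rescales every pool
  # score by the same positive factor, so the rank statistic is unchanged
  # (with several variants the weights are re-estimated from the scaled
  # counts, so exact invariance holds column-wise)
  set.seed(5)
  x1 <- matrix(rbinom(8, 24, 0.1), 8, 1)
  expect_equal(wss_statistic(x1, d2), wss_statistic(2L * x1, d2))
  expect_equal(wss_statistic(x1, d2), wss_statistic(5L * x1, d2))
})

test_that("WSS reduces exactly to individual-level Madsen-Browning", {
  # pools of size 1 with genotype counts are the classical setting
  set.seed(1203)
  for (rep in 1:5) {
    n_case <- sample(40:120, 1)
    n_ctrl <- sample(40:120, 1)
    d <- design_of(n_case, n_ctrl, 1)
    geno <- matrix(
      rbinom((n_case + n_ctrl) * 8, 2, runif(8, 0.005, 0.05)),
      n_case + n_ctrl, 8, byrow = TRUE
    )
    expect_equal(
      wss_statistic(geno, d),
      reference_wss_individual(geno, d$phenotype == "case")
    )
  }
})

test_that("the C-alpha statistic matches its defining sum", {
  d <- design_of(2, 2, 1) # balanced, p0 = 0.5
  expect_equal(calpha_statistic(matrix(c(2, 0, 0, 0), 4, 1), d), 0.5)
  expect_equal(calpha_statistic(matrix(c(1, 0, 1, 0), 4, 1), d), -0.5)
  expect_equal(calpha_statistic(matrix(0, 4, 3), d), 0)

  # unseen variants contribute nothing
  X <- matrix(c(2, 0, 0, 0), 4, 1)
  expect_equal(
    calpha_statistic(cbind(X, 0), d), calpha_statistic(X, d)
  )

  # unequal pool sizes against the independent loop implementation
  set.seed(88)
  d3 <- as_pool_design(tibble::tibble(
    pool_id = paste0("p", 1:6),
    phenotype = c("case", "case", "control", "control", "control", "case"),
    n_individuals = c(12L, 8L, 12L, 5L, 12L, 12L)
  ))
  X3 <- matrix(rbinom(6 * 7, 10, 0.1), 6, 7)
  expect_equal(
    calpha_statistic(X3, d3),
    reference_calpha(X3, d3$phenotype == "case", d3$n_individuals)
  )

  # balanced-design label symmetry: swapping all labels leaves T unchanged
  d_bal <- design_of(4, 4, 12)
  X_bal <- matrix(rbinom(8 * 5, 24, 0.08), 8, 5)
  d_swap <- d_bal
  d_swap$phenotype <- ifelse(d_bal$phenotype == "case", "control", "case")
  expect_equal(calpha_statistic(X_bal, d_bal),
    calpha_statistic(X_bal, d_swap))
})

test_that("permutation p-values switch to exhaustive enumeration and floor
           at 1/(B+1)", {
  fx <- make_fixture("tiny_enumerable")
  X <- mlac_matrix(fx$variants, fx$design)

  pt <- permutation_pvalue(X, fx$design, "wss", B = 2000, seed = 1)
  expect_true(pt$exhaustive)
  expect_equal(pt$B, 20L) # choose(6, 3)
  expect_equal(pt$p * 20, round(pt$p * 20)) # multiple of 1/20

  # sampled mode on an exhausted space warns
  expect_warning(
    permutation_pvalue(X, fx$design, "wss", B = 100, seed = 1,
      exhaustive = "never"),
    "exhausted"
  )

  # constant statistic: every permutation ties the observed value, p = 1
  const <- function(X, case, n_ind) 1
  pt_const <- suppressWarnings(permutation_pvalue(
    X, fx$design, const, B = 50, seed = 2, exhaustive = "never"
  ))
  expect_equal(pt_const$p, 1)

  # add-one convention: p is never 0 and never below 1/(B+1)
  d <- design_of(10, 10, 12)
  set.seed(12)
  X2 <- matrix(rbinom(20 * 4, 24, 0.05), 20, 4)
  for (stat in c("wss", "calpha")) {
    pt2 <- permutation_pvalue(X2, d, stat, B = 99, seed = 3,
      exhaustive = "never")
    expect_gte(pt2$p, 1 / 100)
    expect_lte(pt2$p, 1)
  }
})

test_that("the hybrid test combines the shared null coherently", {
  fx <- make_fixture("tiny_enumerable")
  X <- mlac_matrix(fx$variants, fx$design)
  ht <- hybrid_test(X, fx$design, B = 2000, seed = 4)
  # F = -ln(p_WSS) - ln(p_CALPHA) on the shared permutation set
  expect_equal(ht$stat_hybrid, -log(ht$p_wss) - log(ht$p_calpha))
  expect_equal(ht$p_wss,
    permutation_pvalue(X, fx$design, "wss", B = 2000, seed = 4)$p)
  expect_equal(ht$p_calpha,
    permutation_pvalue(X, fx$design, "calpha", B = 2000, seed = 4)$p)
  expect_false(ht$degenerate)
  expect_warning(
    expect_warning(
      hybrid_test(X, fx$design, B = 50, seed = 1, exhaustive = "never"),
      "B < 100"
    ),
    "exhausted"
  )
  # an all-zero gene is flagged degenerate with well-defined p-values
  ht0 <- hybrid_test(matrix(0, 6, 2), fx$design, B = 200, seed = 1)
  expect_true(ht0$degenerate)
  expect_equal(ht0$p_wss, 1)
})

test_that("gene test orchestration is deterministic and order-independent", {
  sim <- simulate_pooled_study(sim_scenario(
    n_genes = 6, variants_per_gene = 10, architecture = "null", seed = 77,
    n_cases = 60, n_controls = 48, annotation_mix = c(missense = 1)
  ))
  qc <- run_qc(sim$variants, sim$design, analysis_config())
  cfg <- analysis_config(n_permutations = 300, rng_seed = 11)
  res1 <- run_gene_tests(qc$variants, sim$design, cfg,
    filters = "MisDisr_05")
  res2 <- run_gene_tests(qc$variants, sim$design, cfg,
    filters = "MisDisr_05")
  expect_identical(res1, res2) # bitwise reproducibility

  # shuffling the variant rows must not change any gene's p-values
  shuffled <- qc$variants[rev(seq_len(nrow(qc$variants))), ]
  res3 <- run_gene_tests(shuffled, sim$design, cfg, filters = "MisDisr_05")
  res3 <- res3[match(res1$gene, res3$gene), ]
  expect_equal(res1$p_hybrid, res3$p_hybrid)
  expect_equal(res1$p_wss, res3$p_wss)

  expect_true(all(res1$n_snvs >= 2))
  expect_identical(res1$significant, res1$p_hybrid < 0.05)
})
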