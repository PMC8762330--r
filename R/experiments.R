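# Simulation experiments: calibration scans over many genes of one synthetic
# cohort, and power estimation over independent replicate cohorts.

#' Hybrid-test scan over every gene of a variant table
#'
#' Runs [hybrid_test()] on each gene's full pools-by-variants MLAC matrix,
#' bypassing the qualifying-variant filters. This is the workhorse for
#' calibration studies on synthetic cohorts, where the question is whether the
#' permutation p-values of the three tests are uniform under the null, not
#' which variants qualify. Per-gene seeds derive deterministically from
#' `seed` and the gene label.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble.
#' @param B Permutations per gene.
#' @param seed Base seed.
#' @return Tibble with one row per gene (columns as in [hybrid_test()]).
#' @export
gene_hybrid_scan <- function(variants, design, B = 1000, seed = 1) {
  idx <- split(seq_len(nrow(variants)), variants$gene)
  idx <- idx[unique(variants$gene)] # keep table order
  purrr::map_dfr(names(idx), function(gn) {
    X <- mlac_matrix(variants[idx[[gn]], , drop = FALSE], design)
    hybrid_test(X, design,
      B = B, seed = gene_seed(seed, gn), gene = gn, filter = "all"
    )
  })
}

#' Replicate a single-gene scenario and collect test p-values
#'
#' Simulates `n_replicates` independent case/control cohorts from a
#' single-gene scenario (genotypes, pooling, sequencing, MLAC calling) and
#' runs [hybrid_test()] on each. Empirical power at level `alpha` is the
#' rejection fraction of each p-value column. Replicate seeds derive
#' deterministically from `seed`.
#'
#' @param scenario A [sim_scenario()] with `n_genes = 1`.
#' @param n_replicates Number of independent cohorts.
#' @param B Permutations per replicate.
#' @param seed Base seed.
#' @return Tibble: `replicate`, `p_wss`, `p_calpha`, `p_hybrid`.
#' @export
replicate_gene_study <- function(scenario, n_replicates = 500, B = 1000,
                                 seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"), scenario$n_genes == 1L)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    sc <- scenario
    sc$seed <- as.integer((as.double(seed) + 104729 * r) %% 2147483647)
    sim <- simulate_pooled_study(sc)
    X <- mlac_matrix(sim$variants, sim$design)
    ht <- hybrid_test(X, sim$design,
      B = B, seed = as.integer((sc$seed + 1L) %% 2147483647)
    )
    tibble(
      replicate = r, p_wss = ht$p_wss, p_calpha = ht$p_calpha,
      p_hybrid = ht$p_hybrid
    )
  })
}

#' Rejection rates of the three tests
#'
#' @param pvals Tibble with `p_wss`, `p_calpha`, `p_hybrid` (one row per gene
#'   or replicate).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `alpha`, `n`, `power_wss`, `power_calpha`,
#'   `power_hybrid`.
#' @export
rejection_rates <- function(pvals, alpha = 0.05) {
  tibble(
    alpha = alpha, n = nrow(pvals),
    power_wss = mean(pvals$p_wss < alpha),
    power_calpha = mean(pvals$p_calpha < alpha),
    power_hybrid = mean(pvals$p_hybrid < alpha)
  )
}
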