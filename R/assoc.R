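# Pool-adapted gene-based association tests.
#
# The pool is the statistical unit: the data for one gene are an integer
# matrix X [pools x variants] of per-pool maximum-likelihood ALT counts
# (MLAC), and inference permutes case/control labels across pools, preserving
# the number of case and control pools.
#
#   WSS (burden): variant j is weighted by w_j = sqrt(n * q_j * (1 - q_j))
#   with q_j = (m_j^U + 1) / (2 * n^U + 2), where m_j^U is the summed MLAC in
#   control ("unaffected") pools, n^U the control individuals and n the total
#   individuals. Pool p scores gamma_p = sum_j X[p, j] / w_j; the statistic is
#   the sum of the case pools' ranks among all pool scores (average ranks on
#   ties). Weights are recomputed inside every permutation, since relabelling
#   changes the control set.
#
#   C-alpha (variance component): with p0 = case chromosomes / total
#   chromosomes, n_j total copies of variant j and y_j the copies in case
#   pools, T = sum_j [ (y_j - n_j p0)^2 - n_j p0 (1 - p0) ]. Overdispersion of
#   the case/control split (risk and protective variants alike) inflates T.
#
# Both tests are one-sided upper. Monte-Carlo p-values use the add-one
# estimator p = (1 + #{T_b >= T_obs}) / (B + 1); when the number of distinct
# label assignments is <= B the engine switches to exhaustive enumeration and
# p = #{T_b >= T_obs} / n_assignments (the observed labelling is one of them).

case_vector <- function(design) design$phenotype == "case"

check_count_matrix <- function(X, design) {
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(design))
  if (nrow(X) != nrow(design)) {
    abort("count matrix must have one row per pool in the design")
  }
  if (!any(case_vector(design)) || all(case_vector(design))) {
    abort("design must contain at least one case and one control pool")
  }
  storage.mode(X) <- "double"
  X
}

# Vectorised statistics over a set of label assignments.
# S: [B x pools] logical case-indicator matrix. Returns numeric length B.
wss_stats_engine <- function(X, S, n_ind) {
  n_total <- sum(n_ind)
  m_u <- (!S) %*% X # control minor-allele totals per assignment
  n_u <- as.vector((!S) %*% n_ind) # control individuals per assignment
  q <- (m_u + 1) / (2 * n_u + 2)
  w <- sqrt(n_total * q * (1 - q))
  gamma <- (1 / w) %*% t(X) # [B x pools] pool scores
  vapply(
    seq_len(nrow(S)),
    function(b) sum(rank(gamma[b, ])[S[b, ]]),
    numeric(1)
  )
}

calpha_stats_engine <- function(X, S, n_ind) {
  n_j <- colSums(X)
  chrom <- 2 * n_ind
  p0 <- as.vector(S %*% chrom) / sum(chrom)
  y <- S %*% X # [B x variants] case copies
  mu <- outer(p0, n_j)
  v <- outer(p0 * (1 - p0), n_j)
  rowSums((y - mu)^2 - v)
}

one_row_S <- function(case) matrix(case, nrow = 1)

#' Pool-adapted weighted-sum (WSS) burden statistic
#'
#' The case-pool rank sum of Madsen–Browning-weighted pool scores; see the
#' package vignette for the pool adaptation. Larger values indicate an excess
#' burden of minor alleles in case pools.
#'
#' @param X Integer matrix `[pools x variants]` of per-pool MLACs, rows in
#'   design order (see [mlac_matrix()]).
#' @param design A `pool_design` tibble.
#' @return The observed statistic (numeric scalar).
#' @export
wss_statistic <- function(X, design) {
  X <- check_count_matrix(X, design)
  as.numeric(
    wss_stats_engine(X, one_row_S(case_vector(design)), design$n_individuals)
  )
}

#' C-alpha variance-component statistic
#'
#' Tests overdispersion of per-variant case/control allele splits around the
#' binomial expectation at `p0` = case chromosomes / total chromosomes.
#' Variants with zero observed copies contribute 0.
#'
#' @inheritParams wss_statistic
#' @return The observed statistic `T` (numeric scalar).
#' @export
calpha_statistic <- function(X, design) {
  X <- check_count_matrix(X, design)
  as.numeric(
    calpha_stats_engine(
      X, one_row_S(case_vector(design)), design$n_individuals
    )
  )
}

# Build the permutation set: either all distinct case-pool assignments
# (exhaustive) or B sampled assignments. Returns list(S, exhaustive).
permutation_set <- function(design, B, seed,
                            exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  P <- nrow(design)
  n_case <- sum(case_vector(design))
  n_assign <- choose(P, n_case)
  use_exhaustive <- switch(exhaustive,
    auto = n_assign <= B,
    always = TRUE,
    never = FALSE
  )
  if (use_exhaustive) {
    if (n_assign > 5e5) {
      abort("exhaustive enumeration requested for > 5e5 assignments")
    }
    idx <- combn(P, n_case)
    S <- matrix(FALSE, ncol(idx), P)
    for (b in seq_len(ncol(idx))) S[b, idx[, b]] <- TRUE
  } else {
    if (n_assign <= B) {
      warn(paste0(
        "permutation space has only ", n_assign,
        " distinct assignments (< B); the sampled null is exhausted"
      ))
    }
    set.seed(seed)
    S <- t(vapply(
      seq_len(B),
      function(b) {
        v <- logical(P)
        v[sample.int(P, n_case)] <- TRUE
        v
      },
      logical(P)
    ))
  }
  list(S = S, exhaustive = use_exhaustive)
}

null_statistics <- function(X, design, statistic, S) {
  n_ind <- design$n_individuals
  if (is.function(statistic)) {
    vapply(
      seq_len(nrow(S)),
      function(b) statistic(X, S[b, ], n_ind),
      numeric(1)
    )
  } else {
    switch(statistic,
      wss = wss_stats_engine(X, S, n_ind),
      calpha = calpha_stats_engine(X, S, n_ind),
      abort(paste0("unknown statistic ", sQuote(statistic)))
    )
  }
}

perm_p <- function(observed, null, exhaustive) {
  if (exhaustive) {
    mean(null >= observed)
  } else {
    (1 + sum(null >= observed)) / (length(null) + 1)
  }
}

# Self-inclusive upper-tail p for each null draw, ranked within the null
# (add-one convention under sampling; plain proportion under enumeration).
null_p_within <- function(null, exhaustive) {
  B <- length(null)
  cnt_ge <- B - rank(null, ties.method = "min") + 1
  if (exhaustive) cnt_ge / B else (1 + cnt_ge) / (B + 1)
}

#' Permutation p-value by pool-label swapping
#'
#' Permutes the assignment of case/control labels to pools (preserving the
#' numbers of case and control pools), recomputes the statistic for each
#' assignment — WSS weights included — and returns the one-sided upper
#' add-one Monte-Carlo p-value `(1 + #{T_b >= T_obs}) / (B + 1)`. When the
#' number of distinct assignments is at most `B` (and `exhaustive = "auto"`),
#' all assignments are enumerated instead and the p-value is the exact
#' proportion `#{T_b >= T_obs} / n_assignments`.
#'
#' @inheritParams wss_statistic
#' @param statistic `"wss"`, `"calpha"`, or a function
#'   `f(X, case_logical, n_individuals)` returning a scalar.
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed for the label permutations.
#' @param exhaustive `"auto"` (default: enumerate when feasible), `"never"`,
#'   or `"always"`.
#' @return List with class `perm_test`: `p`, `observed`, `null` (vector of
#'   permuted statistics), `exhaustive`, `B` (null size), `statistic`.
#' @export
permutation_pvalue <- function(X, design, statistic = c("wss", "calpha"),
                               B = 10000, seed = 1,
                               exhaustive = c("auto", "never", "always")) {
  if (!is.function(statistic)) statistic <- match.arg(statistic)
  X <- check_count_matrix(X, design)
  if (B < 1) abort("B must be >= 1")
  ps <- permutation_set(design, B, seed, exhaustive)
  obs <- as.numeric(null_statistics(
    X, design, statistic, one_row_S(case_vector(design))
  ))
  null <- null_statistics(X, design, statistic, ps$S)
  structure(
    list(
      p = perm_p(obs, null, ps$exhaustive),
      observed = obs, null = null, exhaustive = ps$exhaustive,
      B = length(null),
      statistic = if (is.function(statistic)) "custom" else statistic
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(
    "<perm_test> statistic:", x$statistic,
    if (x$exhaustive) "(exhaustive)" else "(sampled)", "\n",
    "observed =", format(x$observed), " p =", format(x$p),
    " B =", x$B, "\n"
  )
  invisible(x)
}

#' Fisher-combined hybrid burden / variance-component test
#'
#' Runs the WSS and C-alpha tests on one shared set of pool-label
#' permutations and combines them with Fisher's statistic
#' `F = -ln(p_WSS) - ln(p_CALPHA)`. Because the two tests are correlated, `F`
#' has no convenient asymptotic null; instead each permutation `b` is assigned
#' component p-values by ranking its statistics within the same shared null
#' (self-inclusive, add-one convention), giving a null sample `F_b` whose
#' dependence structure matches the observed `F`. The hybrid p-value is
#' `(1 + #{F_b >= F_obs}) / (B + 1)` (exact proportion under enumeration).
#'
#' @inheritParams permutation_pvalue
#' @param gene,filter Optional labels copied into the result.
#' @return One-row tibble: `gene`, `filter`, `n_snvs`, `stat_wss`, `p_wss`,
#'   `stat_calpha`, `p_calpha`, `stat_hybrid`, `p_hybrid`, `n_permutations`,
#'   `seed`, `degenerate` (all pool counts zero).
#' @export
hybrid_test <- function(X, design, B = 10000, seed = 1,
                        exhaustive = c("auto", "never", "always"),
                        gene = NA_character_, filter = NA_character_) {
  X <- check_count_matrix(X, design)
  ps <- permutation_set(design, B, seed, exhaustive)
  if (!ps$exhaustive && B < 100) {
    warn("B < 100 gives unstable within-null ranks for the hybrid test")
  }
  n_ind <- design$n_individuals
  S_obs <- one_row_S(case_vector(design))

  obs_w <- as.numeric(wss_stats_engine(X, S_obs, n_ind))
  obs_c <- as.numeric(calpha_stats_engine(X, S_obs, n_ind))
  null_w <- wss_stats_engine(X, ps$S, n_ind)
  null_c <- calpha_stats_engine(X, ps$S, n_ind)

  p_w <- perm_p(obs_w, null_w, ps$exhaustive)
  p_c <- perm_p(obs_c, null_c, ps$exhaustive)
  f_obs <- -log(p_w) - log(p_c)
  f_null <- -log(null_p_within(null_w, ps$exhaustive)) -
    log(null_p_within(null_c, ps$exhaustive))
  p_f <- perm_p(f_obs, f_null, ps$exhaustive)

  tibble(
    gene = gene, filter = filter, n_snvs = ncol(X),
    stat_wss = obs_w, p_wss = p_w,
    stat_calpha = obs_c, p_calpha = p_c,
    stat_hybrid = f_obs, p_hybrid = p_f,
    n_permutations = length(null_w), seed = as.integer(seed),
    degenerate = all(X == 0)
  )
}

# Deterministic per-gene seed stream: results do not depend on the order in
# which genes are processed. Kept below 2^31 - 1.
hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

gene_seed <- function(seed, key) {
  as.integer((as.double(seed) + 1000003 * hash_string(key)) %% 2147483647)
}

#' Run the gene-based tests across filters
#'
#' The full testing stage: applies each qualifying-variant filter, groups the
#' surviving SNVs into genes with at least `config$min_snvs_per_gene` of them,
#' builds each gene's pool-by-variant MLAC matrix, and runs [hybrid_test()]
#' with `config$n_permutations` pool-label permutations. Every gene draws a
#' deterministic seed from `config$rng_seed` and its `(filter, gene)` key, so
#' results are reproducible and independent of processing order. Genes with
#' `p_hybrid < 0.05` are flagged `significant` (nominal level; no
#' multiple-testing correction is applied).
#'
#' @param variants Post-QC variant tibble with a `maf` column (see
#'   [run_qc()]).
#' @param design A `pool_design` tibble.
#' @param config An [analysis_config()].
#' @param filters Filter names to run (default: all seven).
#' @return Tibble with one row per (gene, filter), columns as in
#'   [hybrid_test()] plus `significant`.
#' @export
run_gene_tests <- function(variants, design, config = analysis_config(),
                           filters = qv_filters()$name) {
  results <- purrr::map_dfr(filters, function(f) {
    sub <- apply_variant_filter(
      variants, f,
      min_tools = config$damaging_min_tools
    )
    sets <- build_qualifying_sets(sub, f, min_snvs = config$min_snvs_per_gene)
    purrr::map_dfr(seq_len(nrow(sets)), function(i) {
      X <- mlac_matrix(sets$data[[i]], design)
      hybrid_test(
        X, design,
        B = config$n_permutations,
        seed = gene_seed(config$rng_seed, paste0(f, "|", sets$gene[i])),
        gene = sets$gene[i], filter = f
      )
    })
  })
  if (nrow(results) == 0) {
    results <- tibble(
      gene = character(), filter = character(), n_snvs = integer(),
      stat_wss = double(), p_wss = double(), stat_calpha = double(),
      p_calpha = double(), stat_hybrid = double(), p_hybrid = double(),
      n_permutations = integer(), seed = integer(), degenerate = logical()
    )
  }
  results$significant <- results$p_hybrid < 0.05
  results
}
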