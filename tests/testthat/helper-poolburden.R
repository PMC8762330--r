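# Shared builders and independent reference implementations (deliberately
# plain loops, written from the original individual-level definitions, so
# they cannot share bugs with the vectorised pool engines they check).

design_of <- function(n_case_pools, n_ctrl_pools, n = 12L) {
  as_pool_design(tibble::tibble(
    pool_id = c(
      sprintf("case%02d", seq_len(n_case_pools)),
      sprintf("ctrl%02d", seq_len(n_ctrl_pools))
    ),
    phenotype = rep(c("case", "control"), c(n_case_pools, n_ctrl_pools)),
    n_individuals = as.integer(n)
  ))
}

# Canonical variant tibble wrapping a pools x variants count matrix.
variants_from_counts <- function(counts, design, gene = "G1",
                                 func_class = "missense", qual = 500,
                                 maf_true = NULL, chrom = "1") {
  J <- ncol(counts)
  v <- tibble::tibble(
    chrom = chrom, pos = as.integer(100L + 10L * seq_len(J)),
    ref = "A", alt = "G", qual = qual,
    gene = rep_len(gene, J), func_class = rep_len(func_class, J),
    sift = NA_character_, polyphen2 = NA_character_,
    mutationtaster = NA_character_, mutationassessor = NA_character_,
    lrt = NA_character_, fathmm = NA_character_, reg_flags = "-"
  )
  for (p in seq_len(nrow(design))) {
    pid <- design$pool_id[p]
    v[[paste0(pid, ".af")]] <- counts[p, ] / (2 * design$n_individuals[p])
    v[[paste0(pid, ".dp")]] <- 300L
    v[[paste0(pid, ".mlac")]] <- as.integer(counts[p, ])
  }
  validate_variant_table(v, design)
}

# Classical individual-level Madsen-Browning weighted-sum rank statistic.
reference_wss_individual <- function(geno, case) {
  n <- nrow(geno)
  n_u <- sum(!case)
  scores <- numeric(n)
  for (j in seq_len(ncol(geno))) {
    m_u <- sum(geno[!case, j])
    q <- (m_u + 1) / (2 * n_u + 2)
    w <- sqrt(n * q * (1 - q))
    scores <- scores + geno[, j] / w
  }
  sum(rank(scores)[case])
}

# Direct C-alpha evaluation from the defining sum.
reference_calpha <- function(X, case, n_ind) {
  p0 <- sum(2 * n_ind[case]) / sum(2 * n_ind)
  t_sum <- 0
  for (j in seq_len(ncol(X))) {
    n_j <- sum(X[, j])
    y_j <- sum(X[case, j])
    t_sum <- t_sum + (y_j - n_j * p0)^2 - n_j * p0 * (1 - p0)
  }
  t_sum
}

# Exhaustive-enumeration oracle: loops over every distinct case-pool
# assignment, recomputing statistics through the public single-assignment
# functions, and derives all three p-values independently of the package's
# permutation engine.
reference_exhaustive <- function(X, design) {
  P <- nrow(design)
  n_case <- sum(design$phenotype == "case")
  combos <- utils::combn(P, n_case)
  n_assign <- ncol(combos)
  t_w <- t_c <- numeric(n_assign)
  for (b in seq_len(n_assign)) {
    d2 <- design
    d2$phenotype <- "control"
    d2$phenotype[combos[, b]] <- "case"
    t_w[b] <- wss_statistic(X, d2)
    t_c[b] <- calpha_statistic(X, d2)
  }
  obs_w <- wss_statistic(X, design)
  obs_c <- calpha_statistic(X, design)
  p_w <- mean(t_w >= obs_w)
  p_c <- mean(t_c >= obs_c)
  p_within <- function(v) vapply(v, function(x) mean(v >= x), numeric(1))
  f_null <- -log(p_within(t_w)) - log(p_within(t_c))
  f_obs <- -log(p_w) - log(p_c)
  list(
    p_wss = p_w, p_calpha = p_c,
    p_hybrid = mean(f_null >= f_obs), n_assign = n_assign
  )
}

# Brute-force MLAC oracle: scan every k, first maximum wins.
reference_mlac <- function(alt, depth, n_ind, e) {
  k <- 0:(2 * n_ind)
  p <- e + (k / (2 * n_ind)) * (1 - 2 * e)
  k[which.max(dbinom(alt, depth, p))]
}
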