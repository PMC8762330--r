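# Synthetic pooled-cohort generator.
#
# Emulates the statistical structure the analysis assumes, end to end:
# per-variant MAFs skewed toward rare, Hardy-Weinberg genotypes, case/control
# status from a logistic liability model, phenotype-homogeneous pools,
# per-(pool, variant) sequencing depth and read-level error, and MLAC calling
# via the same binomial maximum-likelihood rule the QC module uses. The ground
# truth (true MAFs, effects, genotypes, per-pool true counts) is returned for
# calibration and recovery tests.

#' Simulation scenario
#'
#' Defaults encode the pooled case/control study design the package targets:
#' 588 cases and 408 controls in phenotype-homogeneous pools of 12 (49 case +
#' 34 control pools), mean sequencing depth 360x, 20 variants per gene with
#' MAFs drawn from a rare-skewed Beta distribution (mean 0.005), disease
#' prevalence 0.001, symmetric per-read error 0.5%, and the 2.6% single-pool
#' noise threshold. The default architecture is `"null"` (no genetic effects);
#' when an effect architecture is selected, the per-variant log odds ratio
#' magnitude defaults to `log(3)`.
#'
#' @param n_genes Number of genes.
#' @param variants_per_gene Variants simulated per gene.
#' @param maf_shape1,maf_shape2 Beta parameters of the true-MAF distribution
#'   (clamped to `[1e-4, 0.5]`).
#' @param architecture `"null"` (no effects), `"unidirectional"` (all risk),
#'   `"bidirectional"` (alternating risk/protective), or `"neutral_mix"`
#'   (half neutral, half risk).
#' @param effect_size Per-variant log odds ratio magnitude (sign pattern set
#'   by `architecture`).
#' @param prevalence Disease prevalence the logistic intercept is tuned to.
#' @param n_cases,n_controls Individuals per arm.
#' @param pool_size Individuals per pool; must divide each arm or the last
#'   pool is truncated with a warning.
#' @param mean_depth Mean per-(pool, variant) sequencing depth.
#' @param depth_dispersion Negative-binomial size parameter for depth
#'   (`Inf` = fixed depth).
#' @param error_rate Symmetric per-read sequencing error rate.
#' @param noise_threshold Single-pool ALT-fraction noise threshold carried in
#'   the scenario metadata (applied by QC, not by the generator).
#' @param annotation_mix Named probabilities over [func_classes()] used to
#'   label variants.
#' @param damaging_fraction Fraction of missense variants given a
#'   two-predictor damaging consensus.
#' @param regulatory_fraction Fraction of intronic/UTR/up/downstream variants
#'   given a regulatory-overlap flag.
#' @param seed Integer seed; every stage derives its stream from it.
#' @return A list with class `sim_scenario`.
#' @export
sim_scenario <- function(n_genes = 1L,
                         variants_per_gene = 20L,
                         maf_shape1 = 0.5,
                         maf_shape2 = 99.5,
                         architecture = c(
                           "null", "unidirectional", "bidirectional",
                           "neutral_mix"
                         ),
                         effect_size = log(3),
                         prevalence = 0.001,
                         n_cases = 588L,
                         n_controls = 408L,
                         pool_size = 12L,
                         mean_depth = 360,
                         depth_dispersion = 8,
                         error_rate = 0.005,
                         noise_threshold = 0.026,
                         annotation_mix = default_annotation_mix(),
                         damaging_fraction = 0.5,
                         regulatory_fraction = 0.2,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(
    n_genes >= 1, variants_per_gene >= 1, prevalence > 0, prevalence < 1,
    n_cases >= 1, n_controls >= 1, pool_size >= 1, mean_depth >= 0,
    error_rate >= 0, error_rate < 0.5, all(annotation_mix >= 0)
  )
  if (!all(names(annotation_mix) %in% func_classes())) {
    abort("annotation_mix names must be valid func_class tokens")
  }
  sc <- list(
    n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
    architecture = architecture, effect_size = effect_size,
    prevalence = prevalence,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    pool_size = as.integer(pool_size),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    error_rate = error_rate, noise_threshold = noise_threshold,
    annotation_mix = annotation_mix / sum(annotation_mix),
    damaging_fraction = damaging_fraction,
    regulatory_fraction = regulatory_fraction,
    seed = as.integer(seed)
  )
  class(sc) <- "sim_scenario"
  sc
}

#' Default annotation class proportions
#'
#' Approximate class proportions of rare and low-frequency SNVs in a targeted
#' panel that sequences introns and flanks for part of its genes: roughly a
#' third intergenic, 44% intronic, ~8% exonic, ~10% UTR, ~3% within 1 kb of
#' the transcript, with a sliver of ncRNA and disruptive calls.
#'
#' @return Named numeric vector over [func_classes()], summing to 1.
#' @export
default_annotation_mix <- function() {
  c(
    intergenic = 0.325, intronic = 0.443, ncRNA = 0.012,
    missense = 0.055, synonymous = 0.023, UTR3 = 0.090, UTR5 = 0.009,
    upstream = 0.015, downstream = 0.015,
    `stop-gain` = 0.008, `stop-loss` = 0.001, `splice-site` = 0.004
  )
}

architecture_betas <- function(scenario) {
  J <- scenario$n_genes * scenario$variants_per_gene
  within <- seq_len(scenario$variants_per_gene)
  pattern <- switch(scenario$architecture,
    null = rep(0, scenario$variants_per_gene),
    unidirectional = rep(scenario$effect_size, scenario$variants_per_gene),
    bidirectional = scenario$effect_size * ifelse(within %% 2 == 1, 1, -1),
    neutral_mix = scenario$effect_size * as.numeric(within %% 2 == 1)
  )
  rep(pattern, scenario$n_genes)[seq_len(J)]
}

# Genotypes {0,1,2} for n individuals from per-variant genotype probabilities
# (3 x J column-stochastic matrix).
draw_genotypes <- function(n, probs) {
  J <- ncol(probs)
  u <- matrix(runif(n * J), n, J)
  c1 <- matrix(probs[1, ], n, J, byrow = TRUE)
  c2 <- matrix(probs[1, ] + probs[2, ], n, J, byrow = TRUE)
  matrix(as.integer((u > c1) + (u > c2)), n, J)
}

hwe_probs <- function(maf) {
  rbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Simulate genotypes under a case/control architecture
#'
#' Draws true MAFs from the scenario's Beta distribution, builds
#' Hardy–Weinberg genotype frequencies, tunes the logistic intercept `beta0`
#' so that `E[P(case | g)]` equals the scenario prevalence, and samples exact
#' case and control genotype vectors from the conditional distributions
#' `P(g | case)` and `P(g | control)` implied by the logistic model
#' `logit P(case) = beta0 + sum_j beta_j g_j` (an exponentially tilted
#' proposal with an exact accept step; distributionally identical to
#' prospective sampling until the quotas are reached, but usable at low
#' prevalence).
#'
#' @param scenario A [sim_scenario()].
#' @return A list with class `synthetic_truth`: `maf`, `beta`, `beta0`,
#'   `gene` (per-variant gene label), `genotypes`
#'   (`[individuals x variants]`, cases first), `phenotype`, `scenario`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  J <- scenario$n_genes * scenario$variants_per_gene
  maf <- pmin(pmax(rbeta(J, scenario$maf_shape1, scenario$maf_shape2), 1e-4),
    0.5)
  beta <- architecture_betas(scenario)
  gene <- rep(sprintf("G%04d", seq_len(scenario$n_genes)),
    each = scenario$variants_per_gene
  )
  p_hwe <- hwe_probs(maf)

  if (all(beta == 0)) {
    beta0 <- qlogis(scenario$prevalence)
    genotypes <- draw_genotypes(
      scenario$n_cases + scenario$n_controls, p_hwe
    )
  } else {
    # tune beta0 to the target prevalence on a Monte-Carlo population sample
    s_pop <- as.vector(draw_genotypes(20000L, p_hwe) %*% beta)
    lo <- qlogis(scenario$prevalence) - 2 * sum(pmax(beta, 0)) - 10
    hi <- qlogis(scenario$prevalence) + 2 * sum(pmax(-beta, 0)) + 10
    beta0 <- uniroot(
      function(b0) mean(plogis(b0 + s_pop)) - scenario$prevalence,
      lower = lo, upper = hi, extendInt = "yes", tol = 1e-10
    )$root

    tilt <- p_hwe * rbind(rep(1, J), exp(beta), exp(2 * beta))
    tilt <- sweep(tilt, 2, colSums(tilt), "/")
    sample_arm <- function(n_target, probs) {
      got <- matrix(0L, 0L, J)
      guard <- 0L
      while (nrow(got) < n_target) {
        guard <- guard + 1L
        if (guard > 1000L) {
          abort(paste0(
            "could not reach the requested arm size at prevalence ",
            scenario$prevalence, "; raise prevalence or weaken effects"
          ))
        }
        nb <- max(200L, ceiling(1.1 * (n_target - nrow(got))))
        g <- draw_genotypes(nb, probs)
        x <- beta0 + as.vector(g %*% beta)
        keep <- runif(nb) < plogis(-x) # exact accept step for both arms
        got <- rbind(got, g[keep, , drop = FALSE])
      }
      got[seq_len(n_target), , drop = FALSE]
    }
    genotypes <- rbind(
      sample_arm(scenario$n_cases, tilt),
      sample_arm(scenario$n_controls, p_hwe)
    )
  }

  structure(
    list(
      maf = maf, beta = beta, beta0 = beta0, gene = gene,
      genotypes = genotypes,
      phenotype = rep(c("case", "control"),
        c(scenario$n_cases, scenario$n_controls)
      ),
      scenario = scenario
    ),
    class = "synthetic_truth"
  )
}

make_sim_design <- function(scenario) {
  arm_pools <- function(n, prefix, phenotype) {
    n_full <- n %/% scenario$pool_size
    rem <- n %% scenario$pool_size
    sizes <- rep(scenario$pool_size, n_full)
    if (rem > 0) {
      warn(paste0(
        "pool size ", scenario$pool_size, " does not divide ", n, " ",
        phenotype, " individuals; last pool truncated to ", rem
      ))
      sizes <- c(sizes, rem)
    }
    tibble(
      pool_id = sprintf("%s%02d", prefix, seq_along(sizes)),
      phenotype = phenotype, n_individuals = sizes
    )
  }
  as_pool_design(bind_rows(
    arm_pools(scenario$n_cases, "case", "case"),
    arm_pools(scenario$n_controls, "ctrl", "control")
  ))
}

#' Pool and sequence simulated genotypes
#'
#' Partitions individuals into phenotype-homogeneous pools, draws a
#' per-(pool, variant) depth from a negative binomial with the scenario's
#' mean and dispersion, draws ALT reads as
#' `Binomial(depth, f (1 - e) + (1 - f) e)` with `f` the true pool allele
#' fraction, and calls per-pool MLACs with [estimate_mlac()] at the same
#' error rate. Variants receive functional-class, predictor and regulatory
#' annotations per the scenario's annotation mix. Pools with zero depth carry
#' missing calls.
#'
#' @param truth A `synthetic_truth` from [simulate_genotypes()].
#' @param path Optional directory; if given, writes `variants.tsv`,
#'   `design.tsv`, `truth.tsv` (per-pool true counts) and the resolved
#'   `scenario.yaml` there.
#' @return List: `variants` (canonical variant tibble), `design`
#'   (`pool_design`), `truth` (input truth augmented with `pool_id` per
#'   individual and `true_counts` `[pools x variants]`).
#' @export
pool_and_sequence <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  scenario <- truth$scenario
  set.seed((scenario$seed + 1L) %% 2147483647L)
  design <- make_sim_design(scenario)
  pool_of <- rep(design$pool_id, design$n_individuals)
  true_counts <- rowsum(truth$genotypes, pool_of, reorder = FALSE)
  true_counts <- true_counts[design$pool_id, , drop = FALSE]

  P <- nrow(design)
  J <- ncol(truth$genotypes)
  f <- true_counts / (2 * design$n_individuals)
  depth <- if (is.infinite(scenario$depth_dispersion)) {
    matrix(as.integer(round(scenario$mean_depth)), P, J)
  } else {
    matrix(
      rnbinom(P * J, mu = scenario$mean_depth,
        size = scenario$depth_dispersion),
      P, J
    )
  }
  e <- scenario$error_rate
  p_read <- f * (1 - e) + (1 - f) * e
  alt <- matrix(rbinom(P * J, as.vector(depth), as.vector(p_read)), P, J)
  af <- ifelse(depth > 0, alt / depth, NA_real_)
  depth_na <- ifelse(depth > 0, depth, NA_integer_)

  variants <- annotate_sim_variants(truth, scenario)
  for (p in seq_len(P)) {
    pid <- design$pool_id[p]
    variants[[paste0(pid, ".af")]] <- af[p, ]
    variants[[paste0(pid, ".dp")]] <- as.integer(depth_na[p, ])
    variants[[paste0(pid, ".mlac")]] <- estimate_mlac(
      alt[p, ], depth[p, ], design$n_individuals[p], e
    )
  }
  variants <- validate_variant_table(variants, design)

  truth$pool_id <- pool_of
  truth$true_counts <- true_counts
  out <- list(variants = variants, design = design, truth = truth)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write_variant_table(variants, design, file.path(path, "variants.tsv"))
    write_pool_design(design, file.path(path, "design.tsv"))
    readr::write_tsv(
      as_tibble(as.data.frame(true_counts), rownames = "pool_id"),
      file.path(path, "truth.tsv"),
      progress = FALSE
    )
    yaml::write_yaml(
      unclass(scenario)[names(unclass(scenario)) != "annotation_mix"],
      file.path(path, "scenario.yaml")
    )
  }
  out
}

annotate_sim_variants <- function(truth, scenario) {
  J <- length(truth$maf)
  mix <- scenario$annotation_mix
  func_class <- sample(names(mix), J, replace = TRUE, prob = mix)
  gene_index <- as.integer(factor(truth$gene, levels = unique(truth$gene)))
  within <- stats::ave(seq_len(J), truth$gene, FUN = seq_along)

  preds <- matrix(NA_character_, J, 6,
    dimnames = list(NULL, predictor_columns())
  )
  mis <- which(func_class == "missense")
  if (length(mis) > 0) {
    dam <- runif(length(mis)) < scenario$damaging_fraction
    n_tools <- ifelse(dam, 2L + rbinom(length(mis), 4L, 0.3), 0L)
    benign <- c(
      sift = "T", polyphen2 = "B", mutationtaster = "N",
      mutationassessor = "L", lrt = "N", fathmm = "T"
    )
    damaging <- c(
      sift = "D", polyphen2 = "D", mutationtaster = "D",
      mutationassessor = "M", lrt = "D", fathmm = "D"
    )
    for (i in seq_along(mis)) {
      calls <- benign
      if (n_tools[i] > 0) {
        hit <- sample.int(6L, n_tools[i])
        calls[hit] <- damaging[hit]
      }
      preds[mis[i], ] <- calls
    }
  }
  reg_flags <- rep("-", J)
  nc <- which(func_class %in% noncoding_classes())
  if (length(nc) > 0) {
    flagged <- nc[runif(length(nc)) < scenario$regulatory_fraction]
    reg_flags[flagged] <- sample(reg_flag_tokens(), length(flagged),
      replace = TRUE
    )
  }
  tibble(
    chrom = "1",
    pos = as.integer(1e6 * gene_index + 50L * within),
    ref = "A", alt = "G",
    qual = round(runif(J, 150, 3000), 1),
    gene = truth$gene, func_class = func_class,
    sift = preds[, "sift"], polyphen2 = preds[, "polyphen2"],
    mutationtaster = preds[, "mutationtaster"],
    mutationassessor = preds[, "mutationassessor"],
    lrt = preds[, "lrt"], fathmm = preds[, "fathmm"],
    reg_flags = reg_flags
  )
}

#' Simulate a full pooled study
#'
#' [simulate_genotypes()] followed by [pool_and_sequence()].
#'
#' @inheritParams simulate_genotypes
#' @inheritParams pool_and_sequence
#' @return See [pool_and_sequence()].
#' @export
simulate_pooled_study <- function(scenario, path = NULL) {
  pool_and_sequence(simulate_genotypes(scenario), path = path)
}

#' Built-in regression fixtures
#'
#' Three deterministic synthetic datasets used throughout the test suite:
#'
#' * `"discovery_disr_structure"`: a 49 case + 34 control pool design (pools
#'   of 12, 996 individuals) whose annotated table carries exactly 17
#'   disruptive SNVs — 8 in one gene and 9 in singleton genes — among
#'   missense, synonymous, non-coding and intergenic filler, so the
#'   disruptive filter yields 17 SNVs and exactly one testable gene. The most
#'   common disruptive variant is simulated near MAF 0.0856.
#' * `"tiny_enumerable"`: 3 case + 3 control pools of one individual each
#'   (permutation space of exactly `choose(6, 3) = 20` assignments).
#' * `"null_calibration"`: 1,000 genes of 8 variants each simulated under the
#'   null architecture on the 49 + 34 pool design.
#'
#' @param name Fixture name.
#' @param seed Integer seed (fixed default: fixtures are reproducible).
#' @return List with `variants` and `design` (plus `truth` where simulated).
#' @export
make_fixture <- function(name = c(
                           "discovery_disr_structure", "tiny_enumerable",
                           "null_calibration"
                         ),
                         seed = 20260901L) {
  name <- match.arg(name)
  switch(name,
    discovery_disr_structure = fixture_discovery_disr(seed),
    tiny_enumerable = fixture_tiny_enumerable(),
    null_calibration = simulate_pooled_study(sim_scenario(
      n_genes = 1000L, variants_per_gene = 8L, architecture = "null",
      seed = seed
    ))
  )
}

fixture_discovery_disr <- function(seed) {
  set.seed(seed)
  design <- as_pool_design(tibble(
    pool_id = c(sprintf("case%02d", 1:49), sprintf("ctrl%02d", 1:34)),
    phenotype = rep(c("case", "control"), c(49L, 34L)),
    n_individuals = 12L
  ))
  genes <- sprintf("GENE%02d", 1:10)
  rows <- list()
  add <- function(gene, func_class, maf, n = 1L, damaging = FALSE,
                  reg = "-") {
    tibble(
      gene = gene, func_class = func_class, maf_true = rep(maf, n),
      damaging = damaging, reg_flags = reg
    )
  }
  # 17 disruptive SNVs: 8 in GENE01, one in each of GENE02..GENE10.
  spec <- bind_rows(
    add("GENE01", "stop-gain", 0.0856), # most common disruptive
    add("GENE01", "stop-gain", 0.004, n = 3L),
    add("GENE01", "splice-site", 0.002, n = 3L),
    add("GENE01", "stop-loss", 0.001),
    purrr::map_dfr(genes[2:10], function(g) add(g, "stop-gain", 0.003)),
    # filler: non-disruptive annotation in every gene plus intergenic noise
    purrr::map_dfr(genes, function(g) bind_rows(
      add(g, "missense", 0.008, n = 2L, damaging = TRUE),
      add(g, "synonymous", 0.02),
      add(g, "intronic", 0.01, reg = "Strong_Enhancer"),
      add(g, "intergenic", 0.03)
    ))
  )
  J <- nrow(spec)
  gene_index <- match(spec$gene, genes)
  variants <- tibble(
    chrom = "17",
    pos = as.integer(1e6 * gene_index +
      stats::ave(seq_len(J), spec$gene, FUN = seq_along) * 100L),
    ref = "C", alt = "T",
    qual = round(runif(J, 150, 2500), 1),
    gene = spec$gene, func_class = spec$func_class,
    sift = ifelse(spec$damaging, "D", NA_character_),
    polyphen2 = ifelse(spec$damaging, "D", NA_character_),
    mutationtaster = NA_character_, mutationassessor = NA_character_,
    lrt = NA_character_, fathmm = NA_character_,
    reg_flags = spec$reg_flags
  )
  for (p in seq_len(nrow(design))) {
    pid <- design$pool_id[p]
    mlac <- rbinom(J, 2L * design$n_individuals[p], spec$maf_true)
    variants[[paste0(pid, ".af")]] <- round(mlac / 24 +
      pmin(abs(stats::rnorm(J, 0, 0.002)), 0.02), 5)
    variants[[paste0(pid, ".dp")]] <- as.integer(
      rnbinom(J, mu = 360, size = 8) + 30L
    )
    variants[[paste0(pid, ".mlac")]] <- mlac
  }
  list(variants = validate_variant_table(variants, design), design = design)
}

fixture_tiny_enumerable <- function() {
  design <- as_pool_design(tibble(
    pool_id = c("case1", "case2", "case3", "ctrl1", "ctrl2", "ctrl3"),
    phenotype = rep(c("case", "control"), each = 3L),
    n_individuals = 1L
  ))
  # fixed counts, unbalanced toward cases but with one shared variant
  counts <- rbind(
    case1 = c(2L, 1L, 0L, 1L),
    case2 = c(1L, 0L, 1L, 0L),
    case3 = c(0L, 1L, 0L, 0L),
    ctrl1 = c(0L, 0L, 1L, 0L),
    ctrl2 = c(1L, 0L, 0L, 0L),
    ctrl3 = c(0L, 0L, 0L, 0L)
  )
  J <- ncol(counts)
  variants <- tibble(
    chrom = "1", pos = as.integer(1000L + 10L * seq_len(J)),
    ref = "A", alt = "G", qual = 500,
    gene = "G1", func_class = "missense",
    sift = "D", polyphen2 = "D", mutationtaster = NA_character_,
    mutationassessor = NA_character_, lrt = NA_character_,
    fathmm = NA_character_, reg_flags = "-"
  )
  for (p in seq_len(nrow(design))) {
    pid <- design$pool_id[p]
    variants[[paste0(pid, ".af")]] <- counts[pid, ] / 2
    variants[[paste0(pid, ".dp")]] <- 100L
    variants[[paste0(pid, ".mlac")]] <- counts[pid, ]
  }
  list(variants = validate_variant_table(variants, design), design = design)
}
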