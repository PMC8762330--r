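# Call-level quality control for pooled variant calls.
#
# Three rules reproduce the upstream contract of a CRISP-style pooled caller:
#   * QUAL filter: keep calls with phred quality strictly above the threshold.
#   * Noise zeroing: single-pool ALT allele fractions strictly below an
#     empirically determined threshold are treated as sequencing noise and the
#     pool's call (fraction + MLAC) is set to 0. The thresholds this targets
#     (2.6% / 2.4%) sit below one heterozygote's expected fraction in a
#     12-individual pool (1/24 ~ 4.2%), so true singletons survive.
#   * MLAC: the per-pool alternative-allele count is the maximum-likelihood
#     integer k in [0, 2n] under a binomial read model with symmetric
#     sequencing error.

#' Filter variants by call quality
#'
#' Retains records with phred-scaled `qual` strictly greater than `qual_min`;
#' row order is preserved.
#'
#' @param variants Variant tibble.
#' @param qual_min Quality threshold (default 100, strict `>`).
#' @return Filtered variant tibble.
#' @export
filter_by_qual <- function(variants, qual_min = 100) {
  if (any(is.na(variants$qual))) {
    abort("qual must be present on every record")
  }
  variants[variants$qual > qual_min, , drop = FALSE]
}

#' Zero single-pool calls below the noise threshold
#'
#' For every (variant, pool) cell whose raw ALT allele fraction is strictly
#' below `threshold`, both the fraction and the MLAC are set to 0. Calls at
#' exactly the threshold are kept. Missing calls (`NA`) are left missing.
#' The operation is idempotent.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble.
#' @param threshold Noise threshold in `[0, 1)` (e.g. 0.026 or 0.024).
#' @return The variant tibble with noisy cells zeroed; the number of zeroed
#'   (previously non-zero) cells is attached as attribute `n_zeroed`.
#' @export
zero_noise_calls <- function(variants, design, threshold = 0.026) {
  if (threshold < 0 || threshold >= 1) abort("threshold must be in [0, 1)")
  n_zeroed <- 0L
  for (pid in design$pool_id) {
    af_col <- paste0(pid, ".af")
    mlac_col <- paste0(pid, ".mlac")
    af <- variants[[af_col]]
    noisy <- !is.na(af) & af < threshold
    changed <- noisy & (af > 0 |
      (!is.na(variants[[mlac_col]]) & variants[[mlac_col]] > 0L))
    n_zeroed <- n_zeroed + sum(changed)
    variants[[af_col]][noisy] <- 0
    variants[[mlac_col]][noisy] <- 0L
  }
  attr(variants, "n_zeroed") <- n_zeroed
  variants
}

#' Maximum-likelihood alternative-allele count for one pool
#'
#' Returns the integer `k` in `0..2n` maximising the binomial likelihood of
#' observing `alt_reads` successes in `depth` trials with success probability
#' `(k/2n) * (1 - e) + (1 - k/2n) * e`, i.e. the pool allele fraction
#' contaminated by a symmetric per-read error rate `e`. Likelihood ties break
#' toward the smaller `k` (conservative against false positives). Vectorised
#' over `alt_reads`/`depth`.
#'
#' @param alt_reads Non-negative integer vector, `alt_reads <= depth`.
#' @param depth Positive integer vector of read depths; `0`/`NA` gives `NA`
#'   (missing call).
#' @param n_individuals Individuals in the pool (so `2n` chromosomes).
#' @param error_rate Per-read error rate in `[0, 1)`.
#' @return Integer vector of MLAC values in `[0, 2n]`, `NA` where depth is
#'   missing or zero.
#' @examples
#' estimate_mlac(10, 240, n_individuals = 12, error_rate = 0) # one copy
#' @export
estimate_mlac <- function(alt_reads, depth, n_individuals, error_rate = 0) {
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  n2 <- 2L * as.integer(n_individuals)
  alt_reads <- as.integer(alt_reads)
  depth <- as.integer(depth)
  ok <- !is.na(depth) & depth > 0L & !is.na(alt_reads)
  if (any(alt_reads[ok] < 0L | alt_reads[ok] > depth[ok])) {
    abort("alt_reads must satisfy 0 <= alt_reads <= depth")
  }
  out <- rep(NA_integer_, length(alt_reads))
  if (!any(ok)) return(out)
  k <- 0:n2
  p_k <- error_rate + (k / n2) * (1 - 2 * error_rate)
  ll <- vapply(
    p_k,
    function(p) dbinom(alt_reads[ok], depth[ok], p, log = TRUE),
    numeric(sum(ok))
  )
  if (sum(ok) == 1L) ll <- matrix(ll, nrow = 1L)
  # max.col with ties.method = "first" implements the smaller-k tie-break
  out[ok] <- k[max.col(ll, ties.method = "first")]
  out
}

#' Cohort minor-allele frequency from pool MLACs
#'
#' Estimates the per-variant alternative-allele frequency as the sum of MLACs
#' over the selected pools divided by the total chromosomes in those pools,
#' then (by default) folds to the minor allele, `min(f, 1 - f)`. Missing
#' MLACs count as 0 copies.
#'
#' @param variants Variant tibble (post-QC).
#' @param design A `pool_design` tibble.
#' @param subset Pools to use: `"all"` (default), `"cases"`, `"controls"`.
#' @param fold Fold to the minor allele (default `TRUE`).
#' @return Numeric vector, one frequency per variant (in `[0, 0.5]` when
#'   folded).
#' @export
cohort_maf <- function(variants, design,
                       subset = c("all", "cases", "controls"), fold = TRUE) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    all = rep(TRUE, nrow(design)),
    cases = design$phenotype == "case",
    controls = design$phenotype == "control"
  )
  if (!any(keep)) abort("empty pool subset")
  X <- mlac_matrix(variants, design[keep, , drop = FALSE])
  f <- unname(colSums(X)) / n_chromosomes(design[keep, , drop = FALSE])
  if (fold) pmin(f, 1 - f) else f
}

#' Per-variant missingness report
#'
#' Pools with missing depth (or depth 0) carry no call for the variant; tests
#' treat them as 0 copies, so this report is the place to see how much data
#' that convention hides.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble.
#' @return Tibble with `chrom, pos, ref, alt, n_missing_pools, frac_missing`.
#' @export
missingness_report <- function(variants, design) {
  miss <- vapply(
    design$pool_id,
    function(pid) {
      dp <- variants[[paste0(pid, ".dp")]]
      is.na(dp) | dp == 0L
    },
    logical(nrow(variants))
  )
  if (nrow(variants) == 1L) miss <- matrix(miss, nrow = 1L)
  tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    n_missing_pools = as.integer(rowSums(miss)),
    frac_missing = rowSums(miss) / nrow(design)
  )
}

#' Run call-level QC
#'
#' Applies the QUAL filter and noise zeroing from an [analysis_config()],
#' annotates the surviving variants with the cohort MAF column `maf` used by
#' the qualifying-variant filters, and returns a QC report.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble.
#' @param config An [analysis_config()].
#' @return List with elements `variants` (filtered, MAF-annotated tibble) and
#'   `report` (one-row tibble: `n_input`, `n_pass_qual`, `n_pools_zeroed`).
#' @export
run_qc <- function(variants, design, config = analysis_config()) {
  n_input <- nrow(variants)
  variants <- filter_by_qual(variants, config$qual_min)
  n_pass_qual <- nrow(variants)
  variants <- zero_noise_calls(variants, design, config$noise_threshold)
  n_zeroed <- attr(variants, "n_zeroed")
  variants$maf <- cohort_maf(
    variants, design,
    subset = if (config$maf_subset == "controls") "controls" else "all"
  )
  list(
    variants = variants,
    report = tibble(
      n_input = n_input,
      n_pass_qual = n_pass_qual,
      n_pools_zeroed = n_zeroed
    )
  )
}
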