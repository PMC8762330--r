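# Analysis configuration: a flat key-value record mirrored 1:1 in a YAML file,
# so every run can log the resolved configuration and seed.

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' pooled-sequencing design the package targets: calls are kept at phred QUAL
#' strictly above 100; single-pool ALT allele fractions strictly below the
#' empirically determined noise threshold (2.6% discovery / 2.4% replication;
#' the default is the discovery value) are zeroed; qualifying-variant filters
#' use MAF cutoffs 1% and 5%; genes need at least 2 qualifying SNVs to be
#' tested; permutation p-values use 10,000 pool-label swaps; a missense call
#' is damaging by consensus when at least 2 of 6 predictors agree.
#'
#' @param qual_min Phred-scaled call quality threshold (strict `>`).
#' @param noise_threshold Single-pool ALT-fraction noise threshold in `[0, 1)`
#'   (strict `<` zeroing).
#' @param maf_cutoffs Numeric vector of MAF cutoffs used by the filters.
#' @param n_permutations Number of pool-label permutations `B` (>= 1).
#' @param rng_seed Integer seed for the permutation engine.
#' @param min_snvs_per_gene Minimum qualifying SNVs for a gene to be testable.
#' @param damaging_min_tools Predictors that must agree for damaging consensus.
#' @param maf_subset Pools used to estimate the MAF the filters compare
#'   against: `"all"` (cases + controls, the default) or `"controls"`.
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(qual_min = 100,
                            noise_threshold = 0.026,
                            maf_cutoffs = c(0.01, 0.05),
                            n_permutations = 10000L,
                            rng_seed = 1L,
                            min_snvs_per_gene = 2L,
                            damaging_min_tools = 2L,
                            maf_subset = c("all", "controls")) {
  maf_subset <- match.arg(maf_subset)
  if (noise_threshold < 0 || noise_threshold >= 1) {
    abort("noise_threshold must be in [0, 1)")
  }
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (min_snvs_per_gene < 1) abort("min_snvs_per_gene must be >= 1")
  cfg <- list(
    qual_min = as.double(qual_min),
    noise_threshold = as.double(noise_threshold),
    maf_cutoffs = as.double(maf_cutoffs),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    min_snvs_per_gene = as.integer(min_snvs_per_gene),
    damaging_min_tools = as.integer(damaging_min_tools),
    maf_subset = maf_subset
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a flat YAML file
#'
#' Unknown keys are rejected; missing keys take the [analysis_config()]
#' defaults.
#'
#' @param path Path to the YAML file.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown config key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param config An `analysis_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
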