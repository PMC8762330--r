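# Pool design: the case/control pool layout, the statistical unit of
# permutation. One row per pool; 2 * n_individuals chromosomes per pool.

#' Construct and validate a pool design
#'
#' A pool design describes the layout of a pooled-sequencing study: one row per
#' DNA pool with its identifier, phenotype label (`"case"` or `"control"`) and
#' the number of individuals mixed into the pool. Each pool contributes
#' `2 * n_individuals` chromosomes; these totals are the single source of truth
#' for every downstream frequency and test computation.
#'
#' @param df Data frame with columns `pool_id`, `phenotype`, `n_individuals`.
#' @param require_both If `TRUE` (default), require at least one case and one
#'   control pool, as needed for association testing.
#' @return A validated tibble with class `pool_design`, row order preserved.
#' @examples
#' as_pool_design(data.frame(
#'   pool_id = c("MS1", "HC1"), phenotype = c("case", "control"),
#'   n_individuals = 12
#' ))
#' @export
as_pool_design <- function(df, require_both = TRUE) {
  needed <- c("pool_id", "phenotype", "n_individuals")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "pool design is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- as_tibble(df)[needed]
  if (nrow(df) == 0) abort("no pools: the pool design is empty")
  df$pool_id <- as.character(df$pool_id)
  df$phenotype <- as.character(df$phenotype)
  df$n_individuals <- as.integer(df$n_individuals)

  bad_pheno <- which(!df$phenotype %in% c("case", "control"))
  if (length(bad_pheno) > 0) {
    abort(paste0(
      "unknown phenotype token ", sQuote(df$phenotype[bad_pheno[1]]),
      " in pool design row ", bad_pheno[1], " (expected 'case' or 'control')"
    ))
  }
  bad_n <- which(is.na(df$n_individuals) | df$n_individuals < 1)
  if (length(bad_n) > 0) {
    abort(paste0(
      "non-positive pool size in pool design row ", bad_n[1],
      " (pool ", sQuote(df$pool_id[bad_n[1]]), ")"
    ))
  }
  dup <- df$pool_id[duplicated(df$pool_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate pool_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (require_both) {
    if (!any(df$phenotype == "case") || !any(df$phenotype == "control")) {
      abort("pool design needs at least one case and one control pool")
    }
  }
  class(df) <- c("pool_design", class(df))
  df
}

#' Read a pool design from TSV
#'
#' Reads the canonical pool-design dialect: a tab-separated file with header
#' `pool_id`, `phenotype`, `n_individuals`.
#'
#' @param path Path to the TSV file.
#' @inheritParams as_pool_design
#' @return A `pool_design` tibble (see [as_pool_design()]); file order
#'   preserved.
#' @export
read_pool_design <- function(path, require_both = TRUE) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      pool_id = readr::col_character(),
      phenotype = readr::col_character(),
      n_individuals = readr::col_integer()
    ),
    progress = FALSE
  )
  as_pool_design(df, require_both = require_both)
}

#' Write a pool design to TSV
#'
#' @param design A `pool_design` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_design <- function(design, path) {
  design <- as_pool_design(design, require_both = FALSE)
  readr::write_tsv(as_tibble(as.data.frame(design)), path, progress = FALSE)
  invisible(path)
}

#' Chromosome totals implied by a pool design
#'
#' @param design A `pool_design` tibble.
#' @param subset One of `"all"`, `"cases"`, `"controls"`.
#' @return Integer: total chromosomes (`2 * sum(n_individuals)`) in the subset.
#' @export
n_chromosomes <- function(design, subset = c("all", "cases", "controls")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    all = rep(TRUE, nrow(design)),
    cases = design$phenotype == "case",
    controls = design$phenotype == "control"
  )
  as.integer(2L * sum(design$n_individuals[keep]))
}

is_case_pool <- function(design) design$phenotype == "case"
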