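# Gene-level test results: deterministic column order, TSV round-trip safe to
# at least 12 significant digits.

gene_result_columns <- function() {
  c(
    "gene", "filter", "n_snvs", "stat_wss", "p_wss", "stat_calpha",
    "p_calpha", "stat_hybrid", "p_hybrid", "n_permutations", "seed"
  )
}

#' Write gene-based test results to TSV
#'
#' Columns are written in the fixed order `gene, filter, n_snvs, stat_wss,
#' p_wss, stat_calpha, p_calpha, stat_hybrid, p_hybrid, n_permutations, seed`;
#' numeric values keep full double precision so that a write/read round trip
#' is exact to at least 12 significant digits. An empty result set yields a
#' header-only file.
#'
#' @param results Tibble of gene test results (as from [run_gene_tests()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(results, path) {
  cols <- gene_result_columns()
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "results are missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  readr::write_tsv(as_tibble(results)[cols], path, progress = FALSE)
  invisible(path)
}

#' Read gene-based test results from TSV
#'
#' @param path Path written by [write_gene_results()].
#' @return Tibble in the canonical column order.
#' @export
read_gene_results <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      filter = readr::col_character(),
      n_snvs = readr::col_integer(),
      n_permutations = readr::col_integer(),
      seed = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
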