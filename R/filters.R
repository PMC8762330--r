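# Qualifying-variant filters: seven combinations of functional class,
# in-silico damaging consensus, regulatory overlap and MAF cutoff that define
# the (gene, filter) sets entering the gene-based tests.
#
#   Disr          disruptive (stop-gain/stop-loss/splice-site), no MAF cutoff
#   MisDisr_01    missense or disruptive, MAF < 1%
#   MisDisr_05    missense or disruptive, MAF < 5%
#   DamDisr_01    damaging-consensus missense or disruptive, MAF < 1%
#   DamDisr_05    damaging-consensus missense or disruptive, MAF < 5%
#   SynMisDisr_01 synonymous, missense or disruptive, MAF < 1%
#   Reg_01        non-coding with regulatory overlap, MAF < 1%
#
# MAF comparisons are strict (< 0.01, < 0.05). Within the MAF-capped filters,
# disruptive variants must meet the cutoff too; only Disr is frequency-free.

disruptive_classes <- function() c("stop-gain", "stop-loss", "splice-site")
noncoding_classes <- function() {
  c("intronic", "UTR3", "UTR5", "upstream", "downstream")
}

#' The seven qualifying-variant filter definitions
#'
#' @return Tibble with one row per filter: `name`, `classes` (list of allowed
#'   functional classes), `maf_max` (`NA` for no cutoff), `requires_damaging`,
#'   `requires_regulatory`.
#' @export
qv_filters <- function() {
  disr <- disruptive_classes()
  tibble(
    name = c(
      "Disr", "MisDisr_01", "MisDisr_05", "DamDisr_01", "DamDisr_05",
      "SynMisDisr_01", "Reg_01"
    ),
    classes = list(
      disr,
      c("missense", disr),
      c("missense", disr),
      c("missense", disr),
      c("missense", disr),
      c("synonymous", "missense", disr),
      noncoding_classes()
    ),
    maf_max = c(NA, 0.01, 0.05, 0.01, 0.05, 0.01, 0.01),
    requires_damaging = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    requires_regulatory = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Is a variant disruptive?
#'
#' Stop-gain, stop-loss and splice-site SNVs are disruptive; no frequency
#' condition applies.
#'
#' @param variants Variant tibble.
#' @return Logical vector.
#' @export
is_disruptive <- function(variants) {
  variants$func_class %in% disruptive_classes()
}

#' Damaging consensus for missense variants
#'
#' A missense SNV is rated damaging when at least `min_tools` of the six
#' predictors call it so, using each tool's damaging categories: SIFT `D`;
#' PolyPhen2 `D` or `P`; MutationTaster `D` or `A`; MutationAssessor `M` or
#' `H`; LRT `D`; FATHMM `D`. Missing predictor calls count as non-damaging.
#' Calling this on non-missense records is an error: disruptive variants
#' bypass the consensus test.
#'
#' @param variants Variant tibble (missense rows only).
#' @param min_tools Minimum agreeing predictors (default 2).
#' @return Logical vector.
#' @export
is_damaging <- function(variants, min_tools = 2) {
  if (any(variants$func_class != "missense")) {
    abort("is_damaging() applies to missense variants only")
  }
  damaging_calls(variants) >= min_tools
}

damaging_categories <- function() {
  list(
    sift = "D", polyphen2 = c("D", "P"), mutationtaster = c("D", "A"),
    mutationassessor = c("M", "H"), lrt = "D", fathmm = "D"
  )
}

damaging_calls <- function(variants) {
  cats <- damaging_categories()
  hits <- vapply(
    names(cats),
    function(tool) {
      call <- variants[[tool]]
      !is.na(call) & call %in% cats[[tool]]
    },
    logical(nrow(variants))
  )
  if (nrow(variants) == 1L) hits <- matrix(hits, nrow = 1L)
  rowSums(hits)
}

#' Does a non-coding variant overlap a regulatory element?
#'
#' True when a variant in a non-coding class (intronic, 3'/5' UTR, 1 kb
#' upstream/downstream) carries at least one regulatory-overlap flag
#' ([reg_flag_tokens()]). Coding and intergenic variants return `FALSE`.
#'
#' @param variants Variant tibble.
#' @return Logical vector.
#' @export
is_regulatory <- function(variants) {
  flags <- parse_reg_flags(variants$reg_flags)
  has_flag <- vapply(
    flags, function(f) length(intersect(f, reg_flag_tokens())) > 0, logical(1)
  )
  variants$func_class %in% noncoding_classes() & has_flag
}

#' Apply one qualifying-variant filter
#'
#' Selects the subset of `variants` satisfying a filter's functional-class,
#' damaging-consensus and regulatory predicates, and the strict MAF cutoff
#' where the filter has one. The MAF is the post-QC cohort estimate: pass it
#' explicitly or leave `maf = NULL` to use the `maf` column added by
#' [run_qc()].
#'
#' @param variants Variant tibble.
#' @param filter Filter name (see [qv_filters()]).
#' @param maf Per-variant MAF vector; default uses `variants$maf`.
#' @param min_tools Damaging-consensus threshold (default 2).
#' @return The qualifying subset of `variants`, order preserved.
#' @export
apply_variant_filter <- function(variants, filter, maf = NULL, min_tools = 2) {
  spec <- qv_filters()
  row <- which(spec$name == filter)
  if (length(row) != 1L) abort(paste0("unknown filter name ", sQuote(filter)))
  if (nrow(variants) == 0) return(variants)
  if (is.null(maf)) maf <- variants[["maf"]]
  if (!is.na(spec$maf_max[row]) &&
    (is.null(maf) || any(is.na(maf)) || length(maf) != nrow(variants))) {
    abort("per-variant MAF is required for MAF-capped filters")
  }

  keep <- variants$func_class %in% spec$classes[[row]]
  if (spec$requires_damaging[row]) {
    mis <- variants$func_class == "missense"
    keep[mis] <- keep[mis] & (damaging_calls(variants)[mis] >= min_tools)
  }
  if (spec$requires_regulatory[row]) {
    keep <- keep & is_regulatory(variants)
  }
  if (!is.na(spec$maf_max[row])) {
    keep <- keep & maf < spec$maf_max[row]
  }
  variants[keep, , drop = FALSE]
}

#' Group filtered variants into testable gene sets
#'
#' Groups an already-filtered variant table by gene, de-duplicates variants by
#' `(chrom, pos, ref, alt)`, and keeps genes harbouring at least
#' `min_snvs` qualifying SNVs. Genes are returned in genomic order (smallest
#' position per chromosome).
#'
#' @param variants Filtered variant tibble.
#' @param filter Filter name recorded on the output.
#' @param min_snvs Minimum qualifying SNVs per gene (default 2).
#' @return Nested tibble: `filter`, `gene`, `n_snvs`, `data` (list column of
#'   variant tibbles).
#' @export
build_qualifying_sets <- function(variants, filter, min_snvs = 2) {
  variants <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
  if (nrow(variants) == 0) {
    return(tibble(
      filter = character(), gene = character(), n_snvs = integer(),
      data = list()
    ))
  }
  variants %>%
    group_by(.data$gene) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(
      n_snvs = vapply(.data$data, nrow, integer(1)),
      .chrom = vapply(.data$data, function(d) d$chrom[1], character(1)),
      .pos = vapply(.data$data, function(d) min(d$pos), double(1))
    ) %>%
    filter(.data$n_snvs >= min_snvs) %>%
    arrange(.data$.chrom, .data$.pos) %>%
    mutate(filter = .env$filter) %>%
    select("filter", "gene", "n_snvs", "data")
}

#' Per-filter SNV and testable-gene summary
#'
#' Applies every requested filter and reports, per filter, the number of
#' qualifying SNVs and the number of genes with at least `min_snvs` of them —
#' both before and after gene-eligibility pruning of the SNV count.
#'
#' @param variants Post-QC variant tibble (with `maf` column or `maf` given).
#' @param filters Filter names (default: all seven).
#' @param maf Optional per-variant MAF vector.
#' @param min_snvs Gene-eligibility threshold (default 2).
#' @param min_tools Damaging-consensus threshold (default 2).
#' @return Tibble: `filter`, `n_snvs`, `n_eligible_genes`,
#'   `n_snvs_in_eligible_genes`.
#' @export
filter_summary <- function(variants, filters = qv_filters()$name, maf = NULL,
                           min_snvs = 2, min_tools = 2) {
  purrr::map_dfr(filters, function(f) {
    sub <- apply_variant_filter(variants, f, maf = maf, min_tools = min_tools)
    sub <- sub[!duplicated(variant_key(sub)), , drop = FALSE]
    sets <- build_qualifying_sets(sub, f, min_snvs = min_snvs)
    tibble(
      filter = f,
      n_snvs = nrow(sub),
      n_eligible_genes = nrow(sets),
      n_snvs_in_eligible_genes = sum(sets$n_snvs)
    )
  })
}
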