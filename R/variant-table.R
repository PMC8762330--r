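# Variant tables: one row per annotated biallelic SNV with per-pool
# alternative-allele data (raw allele fraction, depth, MLAC).
#
# Canonical on-disk dialect (TSV, UTF-8, '#'-prefixed header):
#   chrom  pos  ref  alt  qual  gene  func_class
#   sift  polyphen2  mutationtaster  mutationassessor  lrt  fathmm
#   reg_flags (comma-joined, '-' for none)
#   then, for every pool in the design: <pool_id>.af  <pool_id>.dp
#   <pool_id>.mlac
# Coordinates are 1-based inclusive. Missing per-pool calls are '.' on disk
# and NA in memory, distinguished from an observed 0.

variant_fixed_columns <- function() {
  c(
    "chrom", "pos", "ref", "alt", "qual", "gene", "func_class",
    predictor_columns(), "reg_flags"
  )
}

pool_columns <- function(design) {
  as.vector(t(outer(design$pool_id, c(".af", ".dp", ".mlac"), paste0)))
}

#' Validate a variant table against a pool design
#'
#' Checks the in-memory contract of a variant table: fixed annotation columns
#' present, biallelic single-base alleles, valid `func_class` tokens, valid
#' `reg_flags` tokens, per-pool column triplets (`<pool_id>.af`, `.dp`,
#' `.mlac`) matching the design exactly, and MLAC within `[0, 2 * pool size]`.
#' Violations raise row-numbered errors.
#'
#' @param variants Variant table (tibble).
#' @param design A `pool_design` tibble.
#' @return `variants` as a tibble, invisibly valid (columns reordered to the
#'   canonical order).
#' @export
validate_variant_table <- function(variants, design) {
  variants <- as_tibble(variants)
  fixed <- variant_fixed_columns()
  missing_cols <- setdiff(fixed, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "variant table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  pcols <- pool_columns(design)
  missing_pools <- setdiff(pcols, names(variants))
  if (length(missing_pools) > 0) {
    abort(paste0(
      "variant table pool columns do not match the design; missing: ",
      paste(missing_pools, collapse = ", ")
    ))
  }
  extra_pools <- setdiff(
    grep("\\.(af|dp|mlac)$", names(variants), value = TRUE), pcols
  )
  if (length(extra_pools) > 0) {
    abort(paste0(
      "variant table has pool columns absent from the design: ",
      paste(extra_pools, collapse = ", ")
    ))
  }

  variants <- variants[c(fixed, pcols)]
  if (nrow(variants) == 0) return(variants)

  variants$pos <- as.integer(variants$pos)
  variants$qual <- as.double(variants$qual)

  fail_row <- function(i, what) {
    abort(paste0("variant table row ", i, ": ", what))
  }
  bases <- c("A", "C", "G", "T")
  bad <- which(!(variants$ref %in% bases) | !(variants$alt %in% bases) |
    variants$ref == variants$alt)
  if (length(bad) > 0) {
    fail_row(bad[1], paste0(
      "alleles must be distinct single bases (biallelic SNVs only); got ref=",
      sQuote(variants$ref[bad[1]]), " alt=", sQuote(variants$alt[bad[1]])
    ))
  }
  bad <- which(!variants$func_class %in% func_classes())
  if (length(bad) > 0) {
    fail_row(bad[1], paste0(
      "malformed func_class token ", sQuote(variants$func_class[bad[1]])
    ))
  }
  flags <- parse_reg_flags(variants$reg_flags)
  bad_flag <- which(vapply(
    flags, function(f) length(setdiff(f, reg_flag_tokens())) > 0, logical(1)
  ))
  if (length(bad_flag) > 0) {
    fail_row(bad_flag[1], paste0(
      "unknown reg_flags token(s): ",
      paste(setdiff(flags[[bad_flag[1]]], reg_flag_tokens()), collapse = ", ")
    ))
  }
  for (p in seq_len(nrow(design))) {
    pid <- design$pool_id[p]
    mlac <- variants[[paste0(pid, ".mlac")]]
    max_ac <- 2L * design$n_individuals[p]
    bad <- which(!is.na(mlac) & (mlac < 0L | mlac > max_ac))
    if (length(bad) > 0) {
      fail_row(bad[1], paste0(
        "mlac=", mlac[bad[1]], " out of range for pool ", sQuote(pid),
        " (max ", max_ac, ")"
      ))
    }
    af <- variants[[paste0(pid, ".af")]]
    bad <- which(!is.na(af) & (af < 0 | af > 1))
    if (length(bad) > 0) {
      fail_row(bad[1], paste0(
        "raw allele fraction ", af[bad[1]], " outside [0, 1] for pool ",
        sQuote(pid)
      ))
    }
  }
  variants
}

parse_reg_flags <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "-" | x == ""] <- NA_character_
  strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
}

#' Read a variant table from TSV
#'
#' Reads the canonical variant-table dialect (see the package vignette):
#' tab-separated, UTF-8, with a `#`-prefixed header naming the fixed
#' annotation columns followed by `<pool_id>.af`, `<pool_id>.dp`,
#' `<pool_id>.mlac` triplets for every pool in `design`. `'.'` and `'-'`
#' denote missing per-pool calls and empty regulatory flags respectively.
#'
#' @param path Path to the TSV file.
#' @param design A `pool_design` tibble the table must match.
#' @return Validated variant tibble (see [validate_variant_table()]).
#' @export
read_variant_table <- function(path, design) {
  header <- readLines(path, n = 1L)
  header <- sub("^#", "", header)
  col_names <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- readr::read_tsv(
    path,
    skip = 1L, col_names = col_names, na = c("", "NA", "."),
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), gene = readr::col_character(),
      func_class = readr::col_character(),
      reg_flags = readr::col_character(),
      pos = readr::col_integer(), qual = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  for (pc in grep("\\.(dp|mlac)$", names(df), value = TRUE)) {
    df[[pc]] <- as.integer(df[[pc]])
  }
  for (pc in grep("\\.af$", names(df), value = TRUE)) {
    df[[pc]] <- as.double(df[[pc]])
  }
  for (pc in intersect(predictor_columns(), names(df))) {
    df[[pc]] <- as.character(df[[pc]])
  }
  df$reg_flags[is.na(df$reg_flags)] <- "-"
  validate_variant_table(df, design)
}

#' Write a variant table to TSV
#'
#' Writes the canonical dialect read back by [read_variant_table()]:
#' `#`-prefixed header, `'.'` for missing per-pool values and missing
#' predictor calls, `'-'` for empty `reg_flags`.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble (fixes the pool column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, design, path) {
  variants <- validate_variant_table(variants, design)
  variants$reg_flags[is.na(variants$reg_flags) | variants$reg_flags == ""] <-
    "-"
  out <- vapply(variants, function(col) {
    s <- as.character(col)
    s[is.na(s)] <- "."
    s
  }, character(nrow(variants)))
  if (nrow(variants) == 1L) out <- matrix(out, nrow = 1L)
  lines <- c(
    paste0("#", paste(names(variants), collapse = "\t")),
    if (nrow(variants) > 0) apply(out, 1L, paste, collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Extract the pools-by-variants MLAC count matrix
#'
#' Builds the integer matrix `X` with one row per pool (design order) and one
#' column per variant (table order) holding the per-pool maximum-likelihood
#' alternative-allele counts. Missing calls are treated as 0 copies for
#' testing; use [missingness_report()] to quantify them.
#'
#' @param variants Variant tibble.
#' @param design A `pool_design` tibble.
#' @return Integer matrix `[pools x variants]`, dimnames
#'   `(pool_id, chrom:pos:ref:alt)`.
#' @export
mlac_matrix <- function(variants, design) {
  X <- vapply(
    design$pool_id,
    function(pid) {
      m <- variants[[paste0(pid, ".mlac")]]
      if (is.null(m)) abort(paste0("no mlac column for pool ", sQuote(pid)))
      m[is.na(m)] <- 0L
      as.integer(m)
    },
    integer(nrow(variants))
  )
  X <- if (nrow(variants) == 1L) matrix(X, nrow = 1L) else X
  X <- t(X)
  dimnames(X) <- list(
    design$pool_id,
    paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  )
  X
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
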