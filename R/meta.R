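# Cross-cohort meta-analysis.
#
# Two flavours, matching how single-variant follow-up is usually done:
#   * fixed-effect inverse-variance pooling of per-cohort log odds ratios from
#     2x2 allele-count tables, with the Haldane-Anscombe 0.5 continuity
#     correction applied to all four cells when any cell is zero (rare
#     variants produce zero cells routinely);
#   * random-effect pooling of standardized mean differences (Hedges' g with
#     the small-sample correction) using the DerSimonian-Laird tau^2, for
#     expression-level case/control comparisons.

#' Log odds ratio from a 2x2 allele-count table
#'
#' Cells are `a` (case minor), `b` (case major), `c` (control minor),
#' `d` (control major). If any cell is zero, `correction` (default 0.5,
#' Haldane–Anscombe) is added to all four cells before computing
#' `log(ad / bc)` and its standard error `sqrt(1/a + 1/b + 1/c + 1/d)`.
#' Vectorised over the cells.
#'
#' @param a,b,c,d Non-negative integer allele counts.
#' @param correction Continuity correction added when a zero cell exists.
#' @return Tibble with columns `log_or`, `se`.
#' @examples
#' log_or(10, 90, 5, 95) # OR = (10 * 95) / (90 * 5)
#' @export
log_or <- function(a, b, c, d, correction = 0.5) {
  if (any(c(a, b, c, d) < 0)) abort("allele counts must be non-negative")
  bad <- (a + b == 0) | (c + d == 0) | (a + c == 0) | (b + d == 0)
  if (any((a + b == 0) | (c + d == 0))) {
    abort("a 2x2 table with an empty case or control margin is undefined")
  }
  if (any(bad)) {
    abort("a 2x2 table with an empty allele margin is undefined")
  }
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  a <- a + correction * zero
  b <- b + correction * zero
  c <- c + correction * zero
  d <- d + correction * zero
  tibble(
    log_or = log((a * d) / (b * c)),
    se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  )
}

meta_result <- function(studies, pooled, model) {
  structure(list(studies = studies, pooled = pooled, model = model),
    class = c(paste0(model, "_meta"), "poolburden_meta")
  )
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study log odds ratios (or any estimates on a common scale) with
#' weights `1 / se^2`. Reports the pooled estimate, its standard error, the
#' normal z and two-sided p, Cochran's Q and `I^2 = max(0, (Q - df) / Q)`.
#'
#' @param estimates Tibble with columns `log_or` and `se` (one row per study);
#'   an optional `label` column is carried through.
#' @return A `fixed_meta` object; see [tidy.poolburden_meta()] and
#'   [glance.poolburden_meta()].
#' @export
fixed_effect_meta <- function(estimates) {
  estimates <- as_tibble(estimates)
  if (nrow(estimates) < 1) abort("at least one study is required")
  if (any(estimates$se <= 0)) abort("all standard errors must be positive")
  if (is.null(estimates[["label"]])) {
    estimates$label <- paste0("study_", seq_len(nrow(estimates)))
  }
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  q <- sum(w * (estimates$log_or - pooled)^2)
  df <- nrow(estimates) - 1
  i2 <- if (df > 0 && q > 0) max(0, (q - df) / q) else 0
  meta_result(
    studies = estimates %>%
      mutate(weight = w / sum(w)) %>%
      select("label", "log_or", "se", "weight"),
    pooled = tibble(
      estimate = pooled, se = se,
      ci_low = pooled - qnorm(0.975) * se,
      ci_high = pooled + qnorm(0.975) * se,
      z = z, p = 2 * pnorm(-abs(z)), Q = q, df = df, I2 = i2
    ),
    model = "fixed"
  )
}

#' Fixed-effect meta-analysis of 2x2 allele-count tables
#'
#' Convenience wrapper: computes per-cohort Haldane-corrected log odds ratios
#' with [log_or()] and pools them with [fixed_effect_meta()].
#'
#' @param tables Tibble with columns `label`, `a`, `b`, `c`, `d` (see
#'   [log_or()]).
#' @param correction Continuity correction (default 0.5).
#' @return A `fixed_meta` object.
#' @export
meta_2x2 <- function(tables, correction = 0.5) {
  est <- log_or(tables$a, tables$b, tables$c, tables$d,
    correction = correction
  )
  est$label <- if (!is.null(tables[["label"]])) {
    as.character(tables$label)
  } else {
    paste0("cohort_", seq_len(nrow(tables)))
  }
  fixed_effect_meta(est)
}

#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected SMD between two groups and its standard variance:
#' `g = J * (m1 - m2) / s_pooled` with `J = 1 - 3 / (4 df - 1)`,
#' `df = n1 + n2 - 2`, and
#' `var(g) = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`.
#'
#' @param mean1,sd1,n1 First group (e.g. cases).
#' @param mean2,sd2,n2 Second group (e.g. controls).
#' @return Tibble with columns `g`, `var_g`.
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) <= 0)) abort("standard deviations must be positive")
  if (any(c(n1, n2) < 2)) abort("each group needs n >= 2")
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (mean1 - mean2) / s_pooled
  tibble(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

#' Random-effect meta-analysis of standardized mean differences
#'
#' Computes Hedges' g per study, the DerSimonian–Laird between-study variance
#' `tau^2`, and the inverse-variance pooled SMD with weights
#' `1 / (v_k + tau^2)`, with 95% CI and two-sided normal p. With a single
#' study, falls back to fixed-effect pooling with a warning.
#'
#' @param studies Tibble with columns `label`, `mean_case`, `sd_case`,
#'   `n_case`, `mean_control`, `sd_control`, `n_control`.
#' @param tau2 Optional: force the between-study variance (e.g. `0` to
#'   reproduce fixed-effect pooling); default `NULL` estimates it.
#' @return A `random_meta` object; see [tidy.poolburden_meta()] and
#'   [glance.poolburden_meta()].
#' @export
random_effect_smd_meta <- function(studies, tau2 = NULL) {
  studies <- as_tibble(studies)
  if (nrow(studies) < 1) abort("at least one study is required")
  if (is.null(studies[["label"]])) {
    studies$label <- paste0("study_", seq_len(nrow(studies)))
  }
  eff <- hedges_g(
    studies$mean_case, studies$sd_case, studies$n_case,
    studies$mean_control, studies$sd_control, studies$n_control
  )
  if (nrow(studies) == 1 && is.null(tau2)) {
    warn("single study: falling back to fixed-effect pooling (tau^2 = 0)")
    tau2 <- 0
  }
  w_fe <- 1 / eff$var_g
  pooled_fe <- sum(w_fe * eff$g) / sum(w_fe)
  q <- sum(w_fe * (eff$g - pooled_fe)^2)
  df <- nrow(studies) - 1
  if (is.null(tau2)) {
    denom <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    tau2 <- max(0, (q - df) / denom)
  }
  w <- 1 / (eff$var_g + tau2)
  pooled <- sum(w * eff$g) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  i2 <- if (df > 0 && q > 0) max(0, (q - df) / q) else 0
  meta_result(
    studies = tibble(
      label = studies$label, g = eff$g, se = sqrt(eff$var_g),
      weight = w / sum(w)
    ),
    pooled = tibble(
      estimate = pooled, se = se,
      ci_low = pooled - qnorm(0.975) * se,
      ci_high = pooled + qnorm(0.975) * se,
      z = z, p = 2 * pnorm(-abs(z)), Q = q, df = df, I2 = i2, tau2 = tau2
    ),
    model = "random"
  )
}

#' @export
print.poolburden_meta <- function(x, ...) {
  cat(
    "<", x$model, "-effect meta-analysis of ", nrow(x$studies),
    " studies>\n",
    sep = ""
  )
  print(x$pooled)
  invisible(x)
}

#' Tidy a meta-analysis object
#'
#' One row per study: the study label, its estimate (`log_or` or Hedges' `g`),
#' standard error and normalised pooling weight.
#'
#' @param x A `fixed_meta` or `random_meta` object.
#' @param ... Unused.
#' @return A tibble, one row per study.
#' @export
tidy.poolburden_meta <- function(x, ...) x$studies

#' Glance at a meta-analysis object
#'
#' One-row summary: pooled estimate, standard error, 95% CI, z, two-sided p,
#' Cochran's Q, I^2 (and tau^2 for the random-effect model).
#'
#' @inheritParams tidy.poolburden_meta
#' @return A one-row tibble.
#' @export
glance.poolburden_meta <- function(x, ...) x$pooled
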