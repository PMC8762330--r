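# Diagnostics: forest plots for meta-analyses, QQ plots for gene-level
# p-values, and the permutation null behind a single test.

#' Forest plot of a meta-analysis
#'
#' Per-study estimates with 95% intervals and the pooled estimate (diamond
#' row at the bottom).
#'
#' @param object A `fixed_meta` or `random_meta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poolburden_meta <- function(object, ...) {
  st <- object$studies
  est_col <- if ("log_or" %in% names(st)) "log_or" else "g"
  df <- tibble(
    label = c(st$label, "Pooled"),
    estimate = c(st[[est_col]], object$pooled$estimate),
    low = c(
      st[[est_col]] - qnorm(0.975) * st$se, object$pooled$ci_low
    ),
    high = c(
      st[[est_col]] + qnorm(0.975) * st$se, object$pooled$ci_high
    ),
    pooled = c(rep(FALSE, nrow(st)), TRUE)
  )
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate, y = .data$label, colour = .data$pooled
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c("black", "firebrick")) +
    ggplot2::labs(
      x = if (est_col == "log_or") "log odds ratio" else "Hedges' g",
      y = NULL,
      title = paste0(object$model, "-effect meta-analysis")
    ) +
    ggplot2::theme_minimal()
}

#' QQ plot of gene-level permutation p-values
#'
#' Observed versus expected -log10 p under the uniform null, faceted by
#' filter. With `B` permutations the attainable floor is `1 / (B + 1)`.
#'
#' @param results Gene test results (as from [run_gene_tests()]).
#' @param which One of `"p_hybrid"` (default), `"p_wss"`, `"p_calpha"`.
#' @return A ggplot object.
#' @export
plot_pvalue_qq <- function(results,
                           which = c("p_hybrid", "p_wss", "p_calpha")) {
  which <- match.arg(which)
  df <- results %>%
    group_by(.data$filter) %>%
    arrange(.data[[which]], .by_group = TRUE) %>%
    mutate(expected = -log10(row_number() / (n() + 1))) %>%
    ungroup() %>%
    mutate(observed = -log10(.data[[which]]))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~filter) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = paste("QQ plot of", which)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a permutation null
#'
#' The permuted statistics with the observed value marked; the upper tail at
#' or beyond the line is the (pre-add-one) p-value mass.
#'
#' @param object A `perm_test` from [permutation_pvalue()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(
    tibble(stat = object$null), ggplot2::aes(.data$stat)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = paste(object$statistic, "statistic"), y = "permutations",
      title = sprintf(
        "%s null (%s), p = %.4g", object$statistic,
        if (object$exhaustive) "exhaustive" else "sampled", object$p
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
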