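# ggplot2 figures for harmonized instruments and analysis results.

#' Scatter plot of per-allele outcome vs exposure effects
#'
#' Each variant is a point at (per-allele 25(OH)D effect, per-allele log
#' odds ratio) with 95% confidence bars in both directions, overlaid by the
#' fitted causal slope (solid) and its 95% confidence band (dotted) — the
#' standard instrument scatter for a two-sample MR analysis.
#'
#' @param object An `mr_instrument`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_instrument <- function(object, ...) {
  dat <- export_scatter_data(object)
  unit <- attr(object, "exposure_unit") %||% "nmol/L"
  xmax <- max(dat$exposure_beta + dat$exposure_ci)
  abline_df <- tibble::tibble(
    slope = c(dat$slope[1], dat$slope_low[1], dat$slope_high[1]),
    band = c("estimate", "lower", "upper")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$exposure_beta,
                                    y = .data$outcome_beta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$outcome_beta - .data$outcome_ci,
                   ymax = .data$outcome_beta + .data$outcome_ci),
      width = 0) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$exposure_beta - .data$exposure_ci,
                   xmax = .data$exposure_beta + .data$exposure_ci),
      height = 0) +
    ggplot2::geom_abline(
      data = abline_df,
      ggplot2::aes(intercept = 0, slope = .data$slope,
                   linetype = .data$band),
      show.legend = FALSE) +
    ggplot2::scale_linetype_manual(
      values = c(estimate = "solid", lower = "dotted", upper = "dotted")) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = paste0("Per-allele effect on 25(OH)D (", unit, ")"),
      y = "Per-allele log odds ratio of outcome"
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of estimates across methods and outcomes
#'
#' @param analysis An `mr_analysis` from [run_mr_analysis()].
#' @return A ggplot object: odds ratios with 95% CIs by method, faceted by
#'   outcome, on a log scale.
#' @export
plot_mr_estimates <- function(analysis) {
  stopifnot(inherits(analysis, "mr_analysis"))
  dat <- analysis$estimates
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$fit_label)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(
      x = sprintf("Odds ratio per %g nmol/L %s (95%% CI)",
                  analysis$config$scale_increment,
                  analysis$config$direction),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
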