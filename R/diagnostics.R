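# Instrument-validity diagnostics: heterogeneity of the per-variant causal
# estimates (Cochran's Q against the pooled IVW value), the
# over-identification test built on it, and a cross-method consistency
# report.

new_diagnostic <- function(statistic_name, statistic, df, pvalue) {
  tibble::tibble(
    statistic_name = statistic_name,
    statistic = statistic,
    df = as.integer(df),
    pvalue = pvalue
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' Goodness-of-fit of the single-slope model: with Wald ratios `theta_j`
#' and IVW weights `w_j = gamma_j^2 / sigma_yj^2`,
#' \deqn{Q = \sum_j w_j (\theta_j - \hat\theta_{IVW})^2,}
#' referred to a chi-square with `J - 1` degrees of freedom. Q equals the
#' weighted sum of squared residuals of the IVW fit, so a large value means
#' the variants do not share a common causal slope — evidence of horizontal
#' pleiotropy or instrument invalidity. Q is invariant to rescaling the
#' exposure units.
#'
#' @inheritParams wald_ratio
#' @param pooled Optional `mr_estimate`; defaults to [mr_ivw()] on the same
#'   instrument (supplying anything else changes the null being tested).
#' @return A one-row diagnostic tibble: `statistic_name = "cochran_q"`,
#'   `statistic`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(instrument, pooled = NULL) {
  check_instrument(instrument, 2, "mr_cochran_q()")
  pooled <- pooled %||% mr_ivw(instrument)
  if (!inherits(pooled, "mr_estimate")) abort("pooled must be an mr_estimate")
  wr <- wald_ratio(instrument)
  w <- 1 / wr$se^2
  q <- sum(w * (wr$beta - pooled$beta)^2)
  df <- nrow(instrument) - 1L
  new_diagnostic("cochran_q", q, df, pchisq(q, df, lower.tail = FALSE))
}

#' Over-identification test
#'
#' Tests whether the variant-specific causal estimates are mutually
#' consistent — with more instruments than parameters the model is
#' over-identified and the per-variant Wald ratios should agree up to
#' sampling error. In the fixed-effect summary-data setting this is
#' Cochran's Q on the ratios against the IVW pooled estimate (a Sargan-type
#' statistic up to parameterization); the implementation is shared with
#' [mr_cochran_q()] so the two labels can never diverge.
#'
#' @inheritParams mr_cochran_q
#' @return A one-row diagnostic tibble with
#'   `statistic_name = "overid"`.
#' @export
mr_overid <- function(instrument, pooled = NULL) {
  out <- mr_cochran_q(instrument, pooled)
  out$statistic_name <- "overid"
  out
}

#' Egger-intercept pleiotropy diagnostic as a tidy row
#'
#' @param egger An `mr_egger` fit.
#' @return A one-row diagnostic tibble with
#'   `statistic_name = "egger_intercept"`, the intercept z (or t)
#'   statistic, `df = J - 2`, and the intercept p-value.
#' @export
mr_egger_intercept <- function(egger) {
  if (!inherits(egger, "mr_egger")) abort("egger must be an mr_egger fit")
  new_diagnostic("egger_intercept", egger$intercept / egger$intercept_se,
                 egger$n_variants - 2L, egger$intercept_pvalue)
}

#' Cross-method consistency report
#'
#' Lays estimates from different methods side by side on the odds-ratio
#' scale and flags pairs whose ORs differ by more than a display tolerance
#' — the check behind "the results were consistent across analytical
#' approaches" summaries.
#'
#' @param estimates A list of `mr_estimate` objects on the same instrument
#'   and outcome; they must share a reporting scale.
#' @param tolerance Maximum absolute OR difference not flagged
#'   (default 0.01, i.e. agreement at 2-decimal display rounding).
#' @return A tibble with one row per method (`method`, `or`, `ci_low`,
#'   `ci_high`, `p.value`, `display`) plus attributes `flagged` (tibble of
#'   discordant pairs) and `max_abs_diff`.
#' @export
consistency_report <- function(estimates, tolerance = 0.01) {
  if (!is.list(estimates) || length(estimates) < 1 ||
      !all(purrr::map_lgl(estimates, inherits, "mr_estimate"))) {
    abort("estimates must be a list of mr_estimate objects")
  }
  scales <- purrr::map_dbl(estimates, ~ .x$scale %||% 1)
  dirs <- purrr::map_chr(estimates, ~ .x$direction %||% "increase")
  if (length(unique(scales)) > 1 || length(unique(dirs)) > 1) {
    abort("estimates are on mixed reporting scales; rescale first")
  }
  rows <- purrr::map_dfr(estimates, function(e) {
    orv <- odds_ratio(e)
    tibble::tibble(
      method = if (!is.null(e$score)) paste0(e$method, ":", e$score) else e$method,
      or = orv[["or"]], ci_low = orv[["ci_low"]], ci_high = orv[["ci_high"]],
      p.value = e$pvalue, display = format_mr_estimate(e)
    )
  })
  flagged <- tibble::tibble(method_a = character(), method_b = character(),
                            abs_diff = numeric())
  if (nrow(rows) >= 2) {
    pairs <- utils::combn(nrow(rows), 2)
    diffs <- abs(rows$or[pairs[1, ]] - rows$or[pairs[2, ]])
    hit <- diffs > tolerance + 1e-12
    flagged <- tibble::tibble(
      method_a = rows$method[pairs[1, hit]],
      method_b = rows$method[pairs[2, hit]],
      abs_diff = diffs[hit]
    )
    attr(rows, "max_abs_diff") <- max(diffs)
  } else {
    attr(rows, "max_abs_diff") <- 0
  }
  attr(rows, "flagged") <- flagged
  rows
}
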