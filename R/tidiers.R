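# broom-style tidiers and display helpers for fitted MR objects.

#' Tidy a causal-effect estimate
#'
#' @param x An `mr_estimate`.
#' @param exponentiate If `TRUE`, report the odds ratio and its CI on the
#'   estimate's reporting scale instead of the log odds ratio.
#' @param ... Unused.
#' @return A one-row tibble with columns `method`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`, `n_variants`,
#'   `scale`, `direction`.
#' @export
tidy.mr_estimate <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    method = x$method,
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$pvalue,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    n_variants = x$n_variants,
    scale = x$scale,
    direction = x$direction
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @rdname tidy.mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_variants = x$n_variants,
    scale = x$scale,
    direction = x$direction,
    ci_level = x$ci_level %||% 0.95
  )
}

#' Tidy an MR-Egger fit
#'
#' @param x An `mr_egger` object.
#' @param ... Passed to [tidy.mr_estimate()] for the slope row.
#' @return A two-row tibble (`term = "slope"`, `"intercept"`) with
#'   `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.mr_egger <- function(x, ...) {
  z <- qnorm(0.975)
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope$beta, x$intercept),
    std.error = c(x$slope$se, x$intercept_se),
    statistic = c(x$slope$beta / x$slope$se, x$intercept / x$intercept_se),
    p.value = c(x$slope$pvalue, x$intercept_pvalue),
    conf.low = c(x$slope$ci_low, x$intercept - z * x$intercept_se),
    conf.high = c(x$slope$ci_high, x$intercept + z * x$intercept_se)
  )
}

#' @rdname tidy.mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  tibble::tibble(
    n_variants = x$n_variants,
    residual_se = x$residual_se,
    intercept_test = x$intercept_test
  )
}

scale_label <- function(x) {
  unit <- x$exposure_unit %||% "nmol/L"
  sprintf("per %g %s %s", x$scale %||% 1, unit, x$direction %||% "increase")
}

#' Format an estimate the way result tables print it
#'
#' `"OR (ci_low to ci_high); P"` with odds ratios and confidence bounds
#' rounded to 2 decimals and the p-value to 2 decimals.
#'
#' @param est An `mr_estimate`.
#' @param digits Decimal places (default 2).
#' @return A character scalar.
#' @export
format_mr_estimate <- function(est, digits = 2) {
  or <- odds_ratio(est)
  sprintf("%.*f (%.*f to %.*f); %.*f",
          digits, or[["or"]], digits, or[["ci_low"]],
          digits, or[["ci_high"]], digits, est$pvalue)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]%s\n", x$method,
              if (!is.null(x$score)) paste0(" (", x$score, " score)") else ""))
  cat("  log OR ", scale_label(x), ": ", signif(x$beta, 4),
      " (SE ", signif(x$se, 4), ")\n", sep = "")
  cat("  OR (95% CI); P: ", format_mr_estimate(x), "\n", sep = "")
  cat("  variants: ", x$n_variants, "\n", sep = "")
  invisible(x)
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression (", x$n_variants, " variants)\n", sep = "")
  cat("  slope (causal):   ", signif(x$slope$beta, 4), " (SE ",
      signif(x$slope$se, 4), "), P = ", signif(x$slope$pvalue, 3), "\n",
      sep = "")
  cat("  intercept (pleiotropy): ", signif(x$intercept, 4), " (SE ",
      signif(x$intercept_se, 4), "), P = ", signif(x$intercept_pvalue, 3),
      " [", x$intercept_test, " test]\n", sep = "")
  invisible(x)
}
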