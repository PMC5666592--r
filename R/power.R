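# Statistical power and minimum detectable odds ratios for binary-outcome
# Mendelian randomisation with a case-control outcome sample.
#
# The approximation treats the two-stage estimator's z statistic as normal
# with non-centrality sqrt(N * R2 * K * (1 - K)) * |log OR|, where N is the
# total outcome sample, K the case fraction, and R2 the fraction of
# exposure variance explained by the instrument.

#' Specify a binary-outcome MR design
#'
#' @param n_cases,n_controls Outcome-sample case and control counts (> 0).
#' @param r2 Fraction of exposure variance explained by the instrument,
#'   in (0, 1).
#' @param alpha Two-sided test size (default 0.05).
#' @param target_power Power at which minimum detectable effects are
#'   defined (default 0.80).
#' @return A `power_spec` (one-row tibble) with the derived totals `n` and
#'   case fraction `k`.
#' @export
power_spec <- function(n_cases, n_controls, r2, alpha = 0.05,
                       target_power = 0.80) {
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    abort("n_cases and n_controls must be > 0")
  }
  if (any(r2 <= 0 | r2 >= 1)) abort("r2 must lie in (0, 1)")
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  if (any(target_power <= 0 | target_power >= 1)) {
    abort("target_power must lie in (0, 1)")
  }
  n <- n_cases + n_controls
  k <- n_cases / n
  if (any(k <= 0 | k >= 1)) abort("case fraction must lie strictly in (0, 1)")
  structure(
    tibble::tibble(n_cases = n_cases, n_controls = n_controls, n = n, k = k,
                   r2 = r2, alpha = alpha, target_power = target_power),
    class = c("power_spec", class(tibble::tibble()))
  )
}

noncentrality_scale <- function(spec) {
  sqrt(spec$n * spec$r2 * spec$k * (1 - spec$k))
}

#' Power to detect an odds ratio per SD of exposure
#'
#' \deqn{\mathrm{power} = \Phi\big(\sqrt{N R^2 K (1-K)}\,|\log OR| -
#'   z_{1-\alpha/2}\big)}
#' (upper-tail approximation of the two-sided test; at `or_alt = 1` it
#' returns `alpha / 2`, the one tail of the null rejection rate). Power is
#' monotone increasing in `|log or_alt|`, `N`, and `R^2`.
#'
#' @param spec A [power_spec()].
#' @param or_alt Odds ratio(s) per 1 SD increase in the exposure (> 0).
#' @return Power value(s) in (0, 1).
#' @examples
#' mr_power(power_spec(22898, 23054, r2 = 0.03), or_alt = 0.86) # ~0.80
#' @export
mr_power <- function(spec, or_alt) {
  stopifnot(inherits(spec, "power_spec"))
  if (any(or_alt <= 0)) abort("or_alt must be > 0")
  z_alpha <- qnorm(1 - spec$alpha / 2)
  pnorm(noncentrality_scale(spec) * abs(log(or_alt)) - z_alpha)
}

#' Minimum detectable odds ratios of a design
#'
#' Inverts [mr_power()] at the design's target power:
#' \deqn{|\log OR| = \frac{z_{1-\alpha/2} + z_{\mathrm{power}}}
#'   {\sqrt{N R^2 K (1-K)}},}
#' returning the protective bound `exp(-|log OR|)` and the risk-direction
#' bound `exp(+|log OR|)`. Pre-rounding the two bounds are exact
#' reciprocals; effects at least this far from the null are detectable with
#' the target power.
#'
#' @param spec A [power_spec()]; vectorized over its rows.
#' @return A tibble with the design columns plus `log_or_detectable`,
#'   `min_or_protective` (< 1) and `min_or_risk` (> 1), unrounded.
#' @examples
#' minimum_detectable_or(power_spec(22898, 23054, r2 = 0.03)) # 0.86 / 1.16
#' @export
minimum_detectable_or <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  z_alpha <- qnorm(1 - spec$alpha / 2)
  z_power <- qnorm(spec$target_power)
  log_or <- (z_alpha + z_power) / noncentrality_scale(spec)
  dplyr::mutate(tibble::as_tibble(spec),
                log_or_detectable = log_or,
                min_or_protective = exp(-log_or),
                min_or_risk = exp(log_or))
}

#' Minimum-detectable-OR table for a set of labeled designs
#'
#' Batch layout for study tables: one row per cancer/study design, with the
#' minimum detectable ORs printed as `"protective/risk"` at each requested
#' instrument strength, rounded to 2 decimals.
#'
#' @param designs A data frame with columns `label` (or `cancer`/`study`),
#'   `n_cases`, `n_controls`.
#' @param r2 Instrument strengths to tabulate (default `c(0.03, 0.05)`).
#' @param alpha,target_power Passed to [power_spec()].
#' @param digits Display rounding (default 2).
#' @return A tibble with the label columns, counts, and one
#'   `min_or_r2_<value>` character column per `r2` entry.
#' @export
mr_power_table <- function(designs, r2 = c(0.03, 0.05), alpha = 0.05,
                           target_power = 0.80, digits = 2) {
  if (nrow(designs) == 0) abort("designs must have at least one row")
  if (!all(c("n_cases", "n_controls") %in% names(designs))) {
    abort("designs needs n_cases and n_controls columns")
  }
  label_cols <- intersect(c("label", "cancer", "study"), names(designs))
  out <- tibble::as_tibble(designs[, c(label_cols, "n_cases", "n_controls")])
  for (r in r2) {
    spec <- power_spec(designs$n_cases, designs$n_controls, r2 = r,
                       alpha = alpha, target_power = target_power)
    mdor <- minimum_detectable_or(spec)
    out[[sprintf("min_or_r2_%g", r)]] <- sprintf(
      "%.*f/%.*f", digits, round(mdor$min_or_protective, digits),
      digits, round(mdor$min_or_risk, digits))
  }
  out
}
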