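# Causal-effect estimators for summary-data Mendelian randomisation.
#
# All estimators operate on a harmonized instrument (see harmonize()) whose
# rows hold matched per-allele effects: gamma_hat on the exposure (nmol/L of
# 25(OH)D) and Gamma_hat on the outcome (log odds ratio), each with a
# standard error. The causal parameter theta is the log odds ratio per
# 1 nmol/L increase in the exposure.

#' rsids of the vitamin D synthesis and metabolism allele scores
#'
#' Pathway subsets of the four-variant 25(OH)D instrument used as a
#' pleiotropy sensitivity analysis: synthesis-pathway variants (CYP2R1,
#' DHCR7/NADSYN1) versus metabolism/transport variants (GC, CYP24A1).
#'
#' @format A named list of two character vectors.
#' @export
allele_scores <- list(
  synthesis = c("rs10741657", "rs12785878"),
  metabolism = c("rs2282679", "rs6013897")
)

new_mr_estimate <- function(method, beta, se, n_variants,
                            scale = 1, direction = "increase",
                            ci_level = 0.95, extra = list()) {
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(
    c(list(
      method = method,
      beta = beta,
      se = se,
      ci_low = beta - z * se,
      ci_high = beta + z * se,
      pvalue = pvalue_from_se(beta, se),
      n_variants = n_variants,
      scale = scale,
      direction = direction,
      ci_level = ci_level
    ), extra),
    class = "mr_estimate"
  )
}

check_instrument <- function(instrument, min_variants = 1, caller = "estimator") {
  if (!is.data.frame(instrument) ||
      !all(c("exposure_beta", "exposure_se", "outcome_beta", "outcome_se")
           %in% names(instrument))) {
    abort(paste0(caller, " expects a harmonized instrument (see harmonize())"))
  }
  if (nrow(instrument) < min_variants) {
    abort(sprintf("%s needs at least %d variant(s), got %d",
                  caller, min_variants, nrow(instrument)))
  }
  invisible(instrument)
}

#' Per-variant Wald ratio estimates
#'
#' The single-variant causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, `theta_j = Gamma_hat_j / gamma_hat_j`, with the
#' first-order delta-method standard error `se_j = outcome_se_j /
#' |gamma_hat_j|` (exposure-side uncertainty is ignored here, matching the
#' inverse-variance weighting convention; [mr_likelihood()] is the route
#' that honours it).
#'
#' @param instrument A harmonized instrument (see [harmonize()]); every
#'   `exposure_beta` must be non-zero.
#' @return A tibble with one row per variant: `rsid`, `beta` (log OR per
#'   exposure unit), `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
wald_ratio <- function(instrument) {
  check_instrument(instrument, 1, "wald_ratio()")
  if (any(instrument$exposure_beta == 0)) {
    abort("wald_ratio() is undefined where exposure_beta = 0")
  }
  beta <- instrument$outcome_beta / instrument$exposure_beta
  se <- instrument$outcome_se / abs(instrument$exposure_beta)
  tibble::tibble(
    rsid = instrument$rsid %||% paste0("variant_", seq_along(beta)),
    beta = beta,
    se = se,
    ci_low = beta - qnorm(0.975) * se,
    ci_high = beta + qnorm(0.975) * se,
    pvalue = pvalue_from_se(beta, se)
  )
}

ivw_weights <- function(instrument) {
  instrument$exposure_beta^2 / instrument$outcome_se^2
}

#' Inverse-variance weighted causal estimate
#'
#' Fixed-effect inverse-variance weighted average of the per-variant Wald
#' ratios; algebraically the weighted least-squares slope of the outcome
#' effects on the exposure effects through the origin with weights
#' `1 / outcome_se^2`:
#' \deqn{\hat\theta = \frac{\sum_j \gamma_j \Gamma_j \sigma_{yj}^{-2}}
#'                         {\sum_j \gamma_j^2 \sigma_{yj}^{-2}},\qquad
#'       \mathrm{se} = \Big(\sum_j \gamma_j^2 \sigma_{yj}^{-2}\Big)^{-1/2}.}
#' No residual-variance inflation is applied (fixed-effect model); the
#' p-value is two-sided normal.
#'
#' @inheritParams wald_ratio
#' @return An `mr_estimate` (log OR per exposure unit); see
#'   [tidy.mr_estimate()] and [rescale_estimate()].
#' @export
mr_ivw <- function(instrument) {
  check_instrument(instrument, 1, "mr_ivw()")
  g <- instrument$exposure_beta
  o <- instrument$outcome_beta
  wy <- 1 / instrument$outcome_se^2
  denom <- sum(g^2 * wy)
  new_mr_estimate("ivw", sum(g * o * wy) / denom, 1 / sqrt(denom),
                  nrow(instrument))
}

profile_gamma <- function(theta, g, o, sx2, sy2) {
  (g / sx2 + theta * o / sy2) / (1 / sx2 + theta^2 / sy2)
}

profile_nll <- function(theta, g, o, sx2, sy2) {
  gs <- profile_gamma(theta, g, o, sx2, sy2)
  sum((g - gs)^2 / (2 * sx2) + (o - theta * gs)^2 / (2 * sy2))
}

#' Profile-likelihood causal estimate
#'
#' Maximum-likelihood estimate under the bivariate normal measurement model
#' `gamma_hat_j ~ N(gamma_j, sigma_xj^2)`, `Gamma_hat_j ~ N(theta * gamma_j,
#' sigma_yj^2)` with the exposure and outcome samples independent. The
#' nuisance `gamma_j` are profiled out in closed form, leaving a
#' one-dimensional optimisation in `theta`; unlike IVW this honours the
#' uncertainty in the SNP-exposure estimates. As all `sigma_x -> 0` (the
#' no-measurement-error limit) the estimate coincides with [mr_ivw()].
#'
#' The standard error comes from the curvature of the profile
#' log-likelihood at the maximum; `ci = "profile"` instead inverts the
#' likelihood-ratio test for the interval.
#'
#' @inheritParams wald_ratio
#' @param ci `"wald"` (default, curvature-based) or `"profile"`.
#' @param tol Convergence tolerance for the one-dimensional optimiser.
#' @return An `mr_estimate` with method `"likelihood"`.
#' @export
mr_likelihood <- function(instrument, ci = c("wald", "profile"), tol = 1e-10) {
  ci <- match.arg(ci)
  check_instrument(instrument, 1, "mr_likelihood()")
  if (any(instrument$exposure_se <= 0)) abort("all exposure_se must be > 0")
  g <- instrument$exposure_beta
  o <- instrument$outcome_beta
  sx2 <- instrument$exposure_se^2
  sy2 <- instrument$outcome_se^2

  ivw <- mr_ivw(instrument)
  half <- max(abs(ivw$beta), 1e-3) + 100 * ivw$se
  lo <- ivw$beta - half
  hi <- ivw$beta + half
  for (attempt in 1:6) {
    opt <- optimize(profile_nll, c(lo, hi), g = g, o = o, sx2 = sx2,
                    sy2 = sy2, tol = tol)
    width <- hi - lo
    at_edge <- min(opt$minimum - lo, hi - opt$minimum) < 1e-4 * width
    if (!at_edge) break
    lo <- lo - width
    hi <- hi + width
  }
  if (at_edge) {
    abort(sprintf(
      "Profile-likelihood optimisation did not converge in [%g, %g] (min at %g)",
      lo, hi, opt$minimum))
  }
  theta_hat <- opt$minimum

  h <- max(1e-5, 1e-4 * abs(theta_hat))
  curv <- (profile_nll(theta_hat + h, g, o, sx2, sy2) -
             2 * opt$objective +
             profile_nll(theta_hat - h, g, o, sx2, sy2)) / h^2
  if (!is.finite(curv) || curv <= 0) {
    abort("Profile-likelihood curvature is not positive at the optimum")
  }
  se <- 1 / sqrt(curv)

  est <- new_mr_estimate("likelihood", theta_hat, se, nrow(instrument),
                         extra = list(ci_method = ci))
  if (ci == "profile") {
    cut <- opt$objective + qchisq_95_half
    lrt <- function(x) profile_nll(x, g, o, sx2, sy2) - cut
    lo_ci <- stats::uniroot(lrt, c(theta_hat - 50 * se, theta_hat),
                            tol = tol)$root
    hi_ci <- stats::uniroot(lrt, c(theta_hat, theta_hat + 50 * se),
                            tol = tol)$root
    est$ci_low <- lo_ci
    est$ci_high <- hi_ci
  }
  est
}

qchisq_95_half <- stats::qchisq(0.95, df = 1) / 2

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, weights `1 / outcome_se^2`, fitted on the
#' exposure-increasing orientation that [harmonize()] enforces (the
#' intercept is not identifiable otherwise). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional (horizontal) pleiotropic effect per variant, and its test is
#' the pleiotropy diagnostic.
#'
#' Standard errors are fixed-effect, i.e. from `(X'WX)^{-1}` without
#' residual-variance inflation, matching the fixed-effect IVW convention;
#' `dispersion = "residual"` multiplies by the residual standard error as
#' in a conventional weighted regression. The intercept test is normal by
#' default; `intercept_test = "t"` uses a t reference with `J - 2` degrees
#' of freedom, which is materially different at J = 4.
#'
#' @inheritParams wald_ratio
#' @param intercept_test `"normal"` (default) or `"t"`.
#' @param dispersion `"fixed"` (default) or `"residual"`.
#' @return An `mr_egger` object: fields `slope` (an `mr_estimate` with
#'   method `"egger_slope"`), `intercept`, `intercept_se`,
#'   `intercept_pvalue`, `residual_se`, `n_variants`.
#' @export
mr_egger <- function(instrument, intercept_test = c("normal", "t"),
                     dispersion = c("fixed", "residual")) {
  intercept_test <- match.arg(intercept_test)
  dispersion <- match.arg(dispersion)
  check_instrument(instrument, 3, "mr_egger()")
  g <- instrument$exposure_beta
  o <- instrument$outcome_beta
  w <- 1 / instrument$outcome_se^2
  if (length(unique(g)) < 2) {
    abort("mr_egger() needs spread in the exposure effects (slope unidentifiable)")
  }
  X <- cbind(intercept = 1, slope = g)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * o)))
  resid <- o - drop(X %*% coefs)
  df <- length(g) - 2L
  sigma2 <- sum(w * resid^2) / df
  vc <- solve(xtwx)
  if (dispersion == "residual") vc <- vc * sigma2
  ses <- sqrt(diag(vc))

  intercept_p <- if (intercept_test == "t") {
    2 * stats::pt(-abs(coefs[1] / ses[1]), df = df)
  } else {
    pvalue_from_se(coefs[1], ses[1])
  }
  slope <- new_mr_estimate("egger_slope", unname(coefs[2]), unname(ses[2]),
                           length(g))
  structure(
    list(
      slope = slope,
      intercept = unname(coefs[1]),
      intercept_se = unname(ses[1]),
      intercept_pvalue = unname(intercept_p),
      intercept_test = intercept_test,
      residual_se = sqrt(sigma2),
      n_variants = length(g)
    ),
    class = "mr_egger"
  )
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  J <- length(theta)
  if (0.5 >= s[J]) return(theta[J])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median causal estimate
#'
#' Orders the per-variant Wald ratios and returns the value at which the
#' cumulative inverse-variance weight crosses 50%, linearly interpolating
#' between breakpoints placed at each variant's cumulative weight minus
#' half its own weight. Consistent when variants carrying at least half of
#' the weight are valid instruments, so it tolerates pleiotropy in a
#' minority of variants. The standard error comes from a parametric
#' bootstrap: the summary estimates are resampled at their standard errors
#' and the weighted median recomputed.
#'
#' @inheritParams wald_ratio
#' @param bootstrap_reps Number of parametric bootstrap resamples
#'   (default 2000; fewer than 100 draws a warning).
#' @param seed Integer seed for the bootstrap (required).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(instrument, bootstrap_reps = 2000, seed) {
  check_instrument(instrument, 3, "mr_weighted_median()")
  if (missing(seed)) abort("mr_weighted_median() requires an explicit seed")
  if (bootstrap_reps < 100) {
    warn("bootstrap_reps < 100: the bootstrap SE will be unstable")
  }
  wr <- wald_ratio(instrument)
  if (any(!is.finite(wr$beta))) abort("non-finite Wald ratio in instrument")
  w <- 1 / wr$se^2
  point <- weighted_median_point(wr$beta, w)

  g <- instrument$exposure_beta
  o <- instrument$outcome_beta
  sx <- instrument$exposure_se
  sy <- instrument$outcome_se
  J <- length(g)
  boots <- with_seed(seed, {
    vapply(seq_len(bootstrap_reps), function(i) {
      gb <- rnorm(J, g, sx)
      ob <- rnorm(J, o, sy)
      tb <- ob / gb
      weighted_median_point(tb, gb^2 / sy^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", point, sd(boots), J,
                  extra = list(bootstrap_reps = bootstrap_reps, seed = seed))
}

#' Allele-score subset estimate
#'
#' Inverse-variance weighted estimate restricted to a named pathway subset
#' of the instrument — the vitamin D synthesis score (rs10741657,
#' rs12785878) or the metabolism score (rs2282679, rs6013897) — used as a
#' sensitivity analysis: materially different subset estimates point to
#' pathway-specific pleiotropy.
#'
#' @inheritParams wald_ratio
#' @param subset `"synthesis"`, `"metabolism"`, or a character vector of
#'   rsids.
#' @return An `mr_estimate` with method `"score_subset"` and a
#'   `score` field naming the subset.
#' @export
mr_score_subset <- function(instrument, subset = c("synthesis", "metabolism")) {
  if (is.character(subset) && length(subset) == 1 &&
      subset %in% names(allele_scores)) {
    score_name <- subset
    rsids <- allele_scores[[subset]]
  } else if (is.character(subset) && length(subset) > 1) {
    score_name <- "custom"
    rsids <- subset
  } else {
    subset <- match.arg(subset)
    score_name <- subset
    rsids <- allele_scores[[subset]]
  }
  check_instrument(instrument, 1, "mr_score_subset()")
  missing_rs <- setdiff(rsids, instrument$rsid)
  if (length(missing_rs) > 0) {
    abort(paste0("Subset '", score_name, "' members absent from instrument: ",
                 paste(missing_rs, collapse = ", ")))
  }
  sub <- instrument[instrument$rsid %in% rsids, ]
  est <- mr_ivw(sub)
  est$method <- "score_subset"
  est$score <- score_name
  est
}

#' Rescale a causal estimate to a reporting increment
#'
#' Converts a log-OR-per-unit estimate to the odds ratio per
#' `target_increment` exposure units, in either direction: a protective
#' effect of OR 0.988 per 1 nmol/L increase in 25(OH)D is the same effect
#' as OR 1.27 per 20 nmol/L decrease. On the log scale the transform is
#' linear (`beta -> s * target_increment * beta`, `s = -1` for
#' `"decrease"`), so confidence bounds map monotonically, with their order
#' swapped under negation.
#'
#' @param est An `mr_estimate` (per 1 exposure unit).
#' @param target_increment Exposure units per reported increment (> 0);
#'   default 25 nmol/L.
#' @param direction `"increase"` (default) or `"decrease"`.
#' @return An `mr_estimate` on the target scale (its `beta`, `se`,
#'   `ci_low`, `ci_high` are per `target_increment` units in the stated
#'   direction; the p-value is unchanged).
#' @examples
#' est <- new_mr_estimate_from_or(0.988, c(0.979, 0.997))
#' rescale_estimate(est, 20, "decrease") |> odds_ratio()  # ~1.27
#' @export
rescale_estimate <- function(est, target_increment = 25,
                             direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!inherits(est, "mr_estimate")) abort("est must be an mr_estimate")
  if (!is.numeric(target_increment) || target_increment <= 0) {
    abort("target_increment must be > 0")
  }
  s <- if (direction == "decrease") -1 else 1
  out <- est
  out$beta <- s * target_increment * est$beta
  out$se <- target_increment * est$se
  bounds <- sort(s * target_increment * c(est$ci_low, est$ci_high))
  out$ci_low <- bounds[1]
  out$ci_high <- bounds[2]
  out$scale <- target_increment * (est$scale %||% 1)
  out$direction <- direction
  out
}

#' Build an estimate from a published odds ratio and confidence interval
#'
#' Convenience constructor for cross-checking published results: takes an
#' odds ratio with its 95% CI (per 1 exposure unit) and recovers the
#' log-scale estimate with `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`.
#'
#' @param or Odds ratio per 1 exposure unit.
#' @param ci Length-2 vector, 95% confidence bounds of `or`.
#' @param method Method tag (default `"external"`).
#' @return An `mr_estimate`.
#' @export
new_mr_estimate_from_or <- function(or, ci, method = "external") {
  if (or <= 0 || any(ci <= 0)) abort("odds ratios must be positive")
  se <- (log(max(ci)) - log(min(ci))) / (2 * qnorm(0.975))
  est <- new_mr_estimate(method, log(or), se, n_variants = NA_integer_)
  est$ci_low <- log(min(ci))
  est$ci_high <- log(max(ci))
  est
}

#' Reported odds ratio of an estimate
#'
#' @param est An `mr_estimate`.
#' @return Named numeric: `or`, `ci_low`, `ci_high` on the estimate's
#'   reporting scale.
#' @export
odds_ratio <- function(est) {
  if (!inherits(est, "mr_estimate")) abort("est must be an mr_estimate")
  c(or = exp(est$beta), ci_low = exp(est$ci_low), ci_high = exp(est$ci_high))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
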