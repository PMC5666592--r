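# Shared test fixtures and independent oracles.

# Minimal association table in the exchange schema.
assoc_table <- function(rsid, effect_allele, beta, se = NULL, pvalue = NULL,
                        other_allele = NA_character_, eaf = NA_real_) {
  tibble::tibble(
    rsid = rsid,
    chr = NA_character_, locus = NA_character_,
    effect_allele = effect_allele,
    other_allele = other_allele,
    eaf = eaf,
    beta = beta,
    se = se %||% NA_real_,
    pvalue = pvalue %||% NA_real_,
    n_cases = NA_real_, n_controls = NA_real_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Bare harmonized instrument (the estimators only need these columns);
# bypasses allele bookkeeping for speed in simulation loops.
bare_instrument <- function(exposure_beta, exposure_se,
                            outcome_beta, outcome_se,
                            rsid = sprintf("rs%03d", seq_along(exposure_beta))) {
  tibble::tibble(
    rsid = rsid,
    exposure_beta = exposure_beta,
    exposure_se = exposure_se,
    outcome_beta = outcome_beta,
    outcome_se = outcome_se
  )
}

# Published instrument strengths used across simulation tests.
fixture_gammas <- abs(vitdmr::vitd_variants$beta)
fixture_exposure_ses <- vitdmr::se_from_pvalue(vitdmr::vitd_variants$beta,
                                               vitdmr::vitd_variants$pvalue)
fixture_outcome_ses <- c(0.016, 0.018, 0.018, 0.022)

# Independent oracle: upper-tail normal quantile by bisection on the
# log survival function (never calls qnorm).
bisect_z <- function(p_half, lo = 0, hi = 45, iters = 200) {
  target <- log(p_half)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (pnorm(mid, lower.tail = FALSE, log.p = TRUE) > target) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Independent oracle: weighted median by brute-force scan over the
# piecewise-linear cumulative weight function.
scan_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  for (k in seq_len(length(theta) - 1)) {
    if (s[k] < 0.5 && 0.5 <= s[k + 1]) {
      # scan the linear segment, zooming on the best cell until converged
      lo <- theta[k]; hi <- theta[k + 1]
      cw_at <- function(x) {
        s[k] + (x - theta[k]) / (theta[k + 1] - theta[k]) * (s[k + 1] - s[k])
      }
      repeat {
        xs <- seq(lo, hi, length.out = 2001)
        j <- which.min(abs(cw_at(xs) - 0.5))
        if (xs[2] - xs[1] < 1e-13) return(xs[j])
        lo <- xs[max(1, j - 1)]
        hi <- xs[min(length(xs), j + 1)]
      }
    }
  }
  stop("no crossing found")
}

# Independent oracle: dense grid search over theta with the profiled
# per-variant exposure effects plugged in, refined by zooming on the
# minimising cell until the grid step is below 1e-12.
grid_search_theta <- function(instrument, lo, hi, n = 4001) {
  g <- instrument$exposure_beta
  o <- instrument$outcome_beta
  sx2 <- instrument$exposure_se^2
  sy2 <- instrument$outcome_se^2
  nll_at <- function(th) {
    gs <- (g / sx2 + th * o / sy2) / (1 / sx2 + th^2 / sy2)
    sum((g - gs)^2 / (2 * sx2) + (o - th * gs)^2 / (2 * sy2))
  }
  repeat {
    thetas <- seq(lo, hi, length.out = n)
    nll <- vapply(thetas, nll_at, numeric(1))
    k <- which.min(nll)
    step <- thetas[2] - thetas[1]
    if (step < 1e-12) return(thetas[k])
    lo <- thetas[max(1, k - 1)]
    hi <- thetas[min(n, k + 1)]
  }
}
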