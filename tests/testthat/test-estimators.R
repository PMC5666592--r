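test_that("Wald ratios follow the delta-method arithmetic", {
  # null numerator
  inst <- bare_instrument(2.5, 0.1, 0, 0.02)
  expect_equal(wald_ratio(inst)$beta, 0)
  # hand-computed: outcome ln(0.95) on exposure 4.67 nmol/L per allele
  inst <- bare_instrument(4.67, 0.126, log(0.95), 0.02)
  wr <- wald_ratio(inst)
  expect_equal(wr$beta, log(0.95) / 4.67, tolerance = 1e-12)
  expect_equal(wr$beta, -0.010986, tolerance = 1e-3)
  expect_equal(exp(25 * wr$beta), 0.760, tolerance = 1e-3)
  expect_equal(wr$se, 0.02 / 4.67)
  # doubling the exposure effect halves the ratio and its SE exactly
  inst2 <- bare_instrument(2 * 4.67, 0.126, log(0.95), 0.02)
  wr2 <- wald_ratio(inst2)
  expect_equal(wr2$beta, wr$beta / 2)
  expect_equal(wr2$se, wr$se / 2)
  expect_error(wald_ratio(bare_instrument(0, 0.1, 0.1, 0.1)),
               "exposure_beta = 0")
})

test_that("IVW equals weighted least squares through the origin", {
  # J = 1 reduces to the Wald ratio
  inst1 <- bare_instrument(1.72, 0.09, 0.03, 0.018)
  expect_equal(mr_ivw(inst1)$beta, wald_ratio(inst1)$beta)
  expect_equal(mr_ivw(inst1)$se, wald_ratio(inst1)$se)

  # symmetry: equal gamma, equal sigma_y -> mean of the two ratios
  inst2 <- bare_instrument(c(2, 2), c(0.1, 0.1), c(0.04, 0.08), c(0.02, 0.02))
  r <- wald_ratio(inst2)$beta
  expect_equal(mr_ivw(inst2)$beta, mean(r))

  # independent normal-equations oracle on random instances, J <= 6
  set.seed(402)
  for (J in c(2, 3, 4, 6)) {
    g <- runif(J, 0.5, 5)
    sy <- runif(J, 0.01, 0.05)
    o <- rnorm(J, -0.004 * g, sy)
    inst <- bare_instrument(g, runif(J, 0.05, 0.2), o, sy)
    fit <- stats::lm(o ~ 0 + g, weights = 1 / sy^2)
    est <- mr_ivw(inst)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    # fixed-effect SE: strip the residual variance lm estimates
    se_wls <- sqrt(vcov(fit)[1, 1]) / summary(fit)$sigma
    expect_equal(est$se, unname(se_wls), tolerance = 1e-10)
  }
  expect_error(mr_ivw(bare_instrument(numeric(0), numeric(0),
                                      numeric(0), numeric(0))),
               "at least 1")
})

test_that("the profile-likelihood estimator matches its oracles", {
  inst <- make_fixture_instrument(
    outcome_beta = c(-0.052, -0.011, 0.010, -0.031))
  # dense grid-search oracle with the same profiled nuisance form
  ivw <- mr_ivw(inst)
  mle <- mr_likelihood(inst)
  oracle <- grid_search_theta(inst, ivw$beta - 6 * ivw$se,
                              ivw$beta + 6 * ivw$se)
  expect_equal(mle$beta, oracle, tolerance = 1e-6)

  # all outcome effects zero -> theta_hat = 0
  null_inst <- make_fixture_instrument()
  expect_equal(mr_likelihood(null_inst)$beta, 0, tolerance = 1e-8)

  # NOME limit: vanishing exposure uncertainty recovers IVW
  nome <- inst
  nome$exposure_se <- rep(1e-8, 4)
  mle_nome <- mr_likelihood(nome)
  expect_equal(mle_nome$beta, ivw$beta, tolerance = 1e-4)

  # monotone approach to IVW along a shrinking sigma_x grid
  gaps <- vapply(c(1, 0.3, 0.1, 0.03), function(f) {
    shrunk <- inst
    shrunk$exposure_se <- f * inst$exposure_se
    abs(mr_likelihood(shrunk)$beta - ivw$beta)
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-9))

  # profile CI option brackets the Wald CI closely at this strength
  prof <- mr_likelihood(inst, ci = "profile")
  expect_equal(prof$ci_low, mle$ci_low, tolerance = 0.02)
  expect_equal(prof$ci_high, mle$ci_high, tolerance = 0.02)
})

test_that("MR-Egger recovers an exact linear fit and rejects degenerate input", {
  g <- c(4.67, 1.72, 2.11, 0.98)
  inst <- bare_instrument(g, rep(0.1, 4), -0.004 * g, rep(0.02, 4))
  eg <- mr_egger(inst)
  expect_equal(eg$slope$beta, -0.004, tolerance = 1e-12)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$residual_se, 0, tolerance = 1e-8)
  # intercept shifts move only the intercept
  inst$outcome_beta <- inst$outcome_beta + 0.02
  eg2 <- mr_egger(inst)
  expect_equal(eg2$slope$beta, -0.004, tolerance = 1e-12)
  expect_equal(eg2$intercept, 0.02, tolerance = 1e-12)

  expect_error(mr_egger(bare_instrument(c(1, 2), c(.1, .1), c(0, 0),
                                        c(.02, .02))),
               "at least 3")
  expect_error(mr_egger(bare_instrument(rep(2, 4), rep(.1, 4), rnorm(4),
                                        rep(.02, 4))),
               "spread")
  # t-test option is wider than the normal test at J = 4
  inst3 <- bare_instrument(g, rep(0.1, 4),
                           -0.004 * g + c(0.01, -0.02, 0.015, -0.005),
                           rep(0.02, 4))
  p_norm <- mr_egger(inst3, intercept_test = "normal")$intercept_pvalue
  p_t <- mr_egger(inst3, intercept_test = "t")$intercept_pvalue
  expect_gt(p_t, p_norm)
})

test_that("weighted median interpolates cumulative weights like the scan oracle", {
  # equal weights, odd J: plain median
  inst <- bare_instrument(rep(1, 5), rep(0.1, 5),
                          c(0.1, 0.3, 0.2, 0.5, 0.4), rep(0.02, 5))
  wm <- mr_weighted_median(inst, bootstrap_reps = 200, seed = 7)
  expect_equal(wm$beta, 0.3)

  # degenerate spread: all ratios equal
  inst <- bare_instrument(c(1, 2, 4), rep(0.1, 3), 0.02 * c(1, 2, 4),
                          c(0.02, 0.04, 0.08))
  wm <- mr_weighted_median(inst, bootstrap_reps = 200, seed = 7)
  expect_equal(wm$beta, 0.02, tolerance = 1e-12)

  # frozen J = 4 case with unequal weights against the brute-force scan
  ratios <- c(0.1, 0.2, 0.4, 0.8)
  weights <- c(0.1, 0.2, 0.3, 0.4)
  # encode ratios/weights into an instrument: se = g / sqrt(w)
  g <- c(1, 1, 1, 1)
  sy <- g / sqrt(weights)
  inst <- bare_instrument(g, rep(0.01, 4), ratios * g, sy)
  wm <- mr_weighted_median(inst, bootstrap_reps = 200, seed = 11)
  expect_equal(wm$beta, scan_weighted_median(ratios, weights),
               tolerance = 1e-9)
  # the analytic interpolation at these breakpoints: s = (.05,.2,.45,.8)
  expect_equal(wm$beta, 0.4 + (0.8 - 0.4) * (0.5 - 0.45) / (0.8 - 0.45),
               tolerance = 1e-12)

  # randomised property: oracle agreement and range containment
  set.seed(31)
  for (i in 1:20) {
    J <- sample(3:7, 1)
    theta <- rnorm(J, 0, 0.05)
    w <- runif(J, 0.1, 2)
    g <- runif(J, 0.5, 4)
    inst <- bare_instrument(g, rep(0.01, J), theta * g, g / sqrt(w))
    wm <- mr_weighted_median(inst, bootstrap_reps = 100, seed = i)
    expect_equal(wm$beta, scan_weighted_median(theta, w), tolerance = 1e-9)
    expect_gte(wm$beta, min(theta))
    expect_lte(wm$beta, max(theta))
  }

  expect_warning(mr_weighted_median(inst, bootstrap_reps = 50, seed = 1),
                 "unstable")
  expect_error(mr_weighted_median(inst, bootstrap_reps = 200), "seed")
  # same seed, same bootstrap SE
  a <- mr_weighted_median(inst, bootstrap_reps = 300, seed = 42)
  b <- mr_weighted_median(inst, bootstrap_reps = 300, seed = 42)
  expect_identical(a$se, b$se)
})

test_that("allele-score subsets are IVW restricted to the pathway rsids", {
  inst <- make_fixture_instrument(
    outcome_beta = c(-0.052, -0.011, 0.010, -0.031))
  syn <- mr_score_subset(inst, "synthesis")
  expect_equal(syn$n_variants, 2)
  expect_equal(syn$score, "synthesis")
  by_hand <- mr_ivw(inst[inst$rsid %in% c("rs10741657", "rs12785878"), ])
  expect_equal(syn$beta, by_hand$beta)
  expect_equal(syn$se, by_hand$se)
  met <- mr_score_subset(inst, "metabolism")
  expect_equal(met$n_variants, 2)
  # the full instrument as a custom subset reduces to plain IVW
  full <- mr_score_subset(inst, inst$rsid)
  expect_equal(full$beta, mr_ivw(inst)$beta)
  expect_error(mr_score_subset(inst[1:2, ], "synthesis"),
               "rs12785878")
})

test_that("estimators are invariant to variant ordering", {
  inst <- make_fixture_instrument(
    outcome_beta = c(-0.052, -0.011, 0.010, -0.031))
  perm <- inst[c(3, 1, 4, 2), ]
  expect_equal(mr_ivw(perm)$beta, mr_ivw(inst)$beta)
  expect_equal(mr_likelihood(perm)$beta, mr_likelihood(inst)$beta,
               tolerance = 1e-9)
  expect_equal(mr_egger(perm)$slope$beta, mr_egger(inst)$slope$beta)
  expect_equal(mr_egger(perm)$intercept, mr_egger(inst)$intercept)
  expect_equal(
    mr_weighted_median(perm, bootstrap_reps = 100, seed = 5)$beta,
    mr_weighted_median(inst, bootstrap_reps = 100, seed = 5)$beta)
})

test_that("rescaling converts between reporting increments and directions", {
  # the published ovarian cross-check: 0.988 per 1 nmol/L increase is
  # 1.27 per 20 nmol/L decrease
  est <- new_mr_estimate_from_or(0.988, c(0.979, 0.997))
  dec20 <- rescale_estimate(est, 20, "decrease")
  expect_equal(round(odds_ratio(dec20)[["or"]], 2), 1.27)
  expect_equal(round(odds_ratio(dec20)[["ci_low"]], 2), 1.06)
  expect_lt(odds_ratio(dec20)[["ci_low"]], odds_ratio(dec20)[["ci_high"]])

  # null effect is fixed under any rescaling
  null_est <- new_mr_estimate_from_or(1, c(0.9, 1 / 0.9))
  expect_equal(odds_ratio(rescale_estimate(null_est, 25))[["or"]], 1)
  expect_equal(odds_ratio(rescale_estimate(null_est, 10, "decrease"))[["or"]], 1)

  # linearity on the log scale and p-value invariance
  b <- -0.0047
  est <- vitdmr:::new_mr_estimate("ivw", b, 0.003, 4)
  inc25 <- rescale_estimate(est, 25)
  expect_equal(inc25$beta, 25 * b)
  expect_equal(inc25$se, 25 * 0.003)
  expect_equal(inc25$pvalue, est$pvalue)
  expect_error(rescale_estimate(est, 0), "> 0")
  expect_error(rescale_estimate(est, -5), "> 0")
})
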