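# Synthetic two-sample GWAS summary statistics.
#
# Statistics are simulated directly at the estimate level — normal sampling
# of (gamma_hat_j, Gamma_hat_j) around their true values at the stated
# standard errors — which is exactly the measurement model the summary-data
# estimators assume. No individual-level genotypes, no LD, no sample
# overlap.

#' Published characteristics of the four 25(OH)D variants
#'
#' The four-variant instrument for circulating 25-hydroxyvitamin D: GC
#' (transport), CYP2R1 and DHCR7/NADSYN1 (synthesis pathway), CYP24A1
#' (degradation). `beta` is the published per-allele effect on 25(OH)D in
#' nmol/L on the printed allele coding; `pvalue` the published
#' association p-value (the GC variant's value is a printed bound, treated
#' as an equality when deriving standard errors).
#'
#' @format A tibble with columns `rsid`, `chr`, `locus`, `effect_allele`,
#'   `beta`, `pvalue`.
#' @export
vitd_variants <- tibble::tibble(
  rsid = c("rs2282679", "rs10741657", "rs12785878", "rs6013897"),
  chr = c("4", "11", "11", "20"),
  locus = c("GC", "CYP2R1", "DHCR7/NADSYN1", "CYP24A1"),
  effect_allele = c("G", "G", "G", "A"),
  beta = c(-4.67, -1.72, -2.11, -0.98),
  pvalue = c(3.4e-302, 6.5e-81, 6.4e-129, 3.4e-17)
)

# Outcome-side per-allele log-OR standard errors sized so the pooled IVW
# standard error on the per-25 nmol/L scale is ~0.075, comparable to the
# confidence intervals of large consortium case-control outcomes.
default_outcome_ses <- c(0.016, 0.018, 0.018, 0.022)

#' Configure the summary-statistics simulator
#'
#' Defaults encode the study conditions the estimators are validated under:
#' the four-variant 25(OH)D instrument at its published strengths (gamma =
#' 4.67, 1.72, 2.11, 0.98 nmol/L per allele in exposure-increasing
#' orientation, exposure SEs derived from the published p-values) and
#' outcome standard errors typical of large cancer consortium GWAS.
#'
#' @param theta Causal log odds ratio per 1 nmol/L of 25(OH)D (default 0).
#' @param gammas True per-allele exposure effects, nmol/L (> 0).
#' @param exposure_ses,outcome_ses Per-variant standard errors (> 0; zeros
#'   are allowed for noise-free checks).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects
#'   `~ N(0, sd^2)`), or `"directional"` (`~ N(mean, sd^2)`).
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution on the
#'   log-OR scale; forced to 0 when `pleiotropy_mode = "none"`.
#' @param flip_fraction Probability that a variant's outcome row is coded
#'   on the other allele (exercises harmonization; default 0).
#' @param palindromic_fraction Probability that a variant is assigned a
#'   palindromic (A/T or G/C) allele pair with strand-informative
#'   frequencies (default 0).
#' @param n_replicates Number of independent replicate pairs (default 1).
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @param rsids Variant identifiers.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(theta = 0,
                              gammas = abs(vitd_variants$beta),
                              exposure_ses = se_from_pvalue(
                                vitd_variants$beta, vitd_variants$pvalue),
                              outcome_ses = default_outcome_ses,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional"),
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              flip_fraction = 0,
                              palindromic_fraction = 0,
                              n_replicates = 1,
                              seed,
                              rsids = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) abort("simulation_config() requires an explicit seed")
  J <- length(gammas)
  if (length(exposure_ses) != J || length(outcome_ses) != J) {
    abort("gammas, exposure_ses and outcome_ses must have equal length")
  }
  if (any(gammas <= 0)) abort("gammas must be > 0 (exposure-increasing)")
  if (any(exposure_ses < 0) || any(outcome_ses < 0)) {
    abort("standard errors must be non-negative")
  }
  if (pleiotropy_mode == "none" && (pleiotropy_mean != 0 || pleiotropy_sd != 0)) {
    warn("pleiotropy_mode = 'none' forces pleiotropy_mean = pleiotropy_sd = 0")
    pleiotropy_mean <- 0
    pleiotropy_sd <- 0
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    abort("balanced pleiotropy has mean 0; use pleiotropy_mode = 'directional'")
  }
  rsids <- rsids %||% if (J == nrow(vitd_variants)) vitd_variants$rsid else
    sprintf("rs%05d", seq_len(J))
  structure(
    list(theta = theta, gammas = gammas, exposure_ses = exposure_ses,
         outcome_ses = outcome_ses, pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         flip_fraction = flip_fraction,
         palindromic_fraction = palindromic_fraction,
         n_replicates = n_replicates, seed = seed, rsids = rsids),
    class = "sim_config"
  )
}

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("G", "C"))

#' Simulate paired exposure/outcome summary tables
#'
#' Draws, per replicate and variant, `gamma_hat_j ~ N(gamma_j, sigma_xj^2)`
#' and `Gamma_hat_j ~ N(theta * gamma_j + alpha_j, sigma_yj^2)`, where
#' `alpha_j` is 0, `N(0, sd^2)` or `N(mean, sd^2)` depending on the
#' pleiotropy mode. The tables conform to the [read_associations()] schema
#' with consistent allele codings (optionally including flipped and
#' palindromic codings to exercise [harmonize()]), and the output is fully
#' reproducible from the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list: `exposure` and `outcome` tibbles in the exchange schema
#'   (with a `replicate` column when `n_replicates > 1`), and `truth`
#'   (per-replicate, per-variant `theta`, `gamma`, `alpha`).
#' @export
simulate_summary_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- length(config$gammas)
  R <- config$n_replicates
  with_seed(config$seed, {
    pair_idx <- ifelse(
      stats::runif(J) < config$palindromic_fraction,
      -sample.int(length(PALINDROMIC_PAIRS), J, replace = TRUE),
      sample.int(length(NONPALINDROMIC_PAIRS), J, replace = TRUE)
    )
    alleles <- purrr::map(pair_idx, function(i) {
      if (i < 0) PALINDROMIC_PAIRS[[-i]] else NONPALINDROMIC_PAIRS[[i]]
    })
    flip <- stats::runif(J) < config$flip_fraction
    eaf <- stats::runif(J, 0.2, 0.4)  # strand-informative by construction

    alpha <- switch(config$pleiotropy_mode,
      none = matrix(0, R, J),
      balanced = matrix(rnorm(R * J, 0, config$pleiotropy_sd), R, J),
      directional = matrix(rnorm(R * J, config$pleiotropy_mean,
                                 config$pleiotropy_sd), R, J)
    )
    gamma_hat <- matrix(rnorm(R * J, rep(config$gammas, each = R),
                              rep(config$exposure_ses, each = R)), R, J)
    mu_out <- config$theta * rep(config$gammas, each = R) + alpha
    Gamma_hat <- matrix(rnorm(R * J, mu_out,
                              rep(config$outcome_ses, each = R)), R, J)

    ea <- purrr::map_chr(alleles, 1)
    oa <- purrr::map_chr(alleles, 2)
    base <- tibble::tibble(
      replicate = rep(seq_len(R), times = J),
      rsid = rep(config$rsids, each = R)
    )
    exposure <- dplyr::mutate(base,
      chr = NA_character_, locus = NA_character_,
      effect_allele = rep(ea, each = R),
      other_allele = rep(oa, each = R),
      eaf = rep(eaf, each = R),
      beta = as.vector(gamma_hat),
      se = rep(config$exposure_ses, each = R),
      pvalue = NA_real_, n_cases = NA_real_, n_controls = NA_real_
    )
    outcome <- dplyr::mutate(base,
      chr = NA_character_, locus = NA_character_,
      effect_allele = rep(ifelse(flip, oa, ea), each = R),
      other_allele = rep(ifelse(flip, ea, oa), each = R),
      eaf = rep(ifelse(flip, 1 - eaf, eaf), each = R),
      beta = as.vector(Gamma_hat) * rep(ifelse(flip, -1, 1), each = R),
      se = rep(config$outcome_ses, each = R),
      pvalue = NA_real_, n_cases = NA_real_, n_controls = NA_real_
    )
    truth <- dplyr::mutate(base,
      theta = config$theta,
      gamma = rep(config$gammas, each = R),
      alpha = as.vector(alpha)
    )
    if (R == 1) {
      exposure$replicate <- NULL
      outcome$replicate <- NULL
      truth$replicate <- NULL
    }
    list(exposure = dplyr::arrange(exposure, !!!rlang::syms(
           intersect("replicate", names(exposure))), .data$rsid),
         outcome = dplyr::arrange(outcome, !!!rlang::syms(
           intersect("replicate", names(outcome))), .data$rsid),
         truth = dplyr::arrange(truth, !!!rlang::syms(
           intersect("replicate", names(truth))), .data$rsid))
  })
}

#' Harmonized instrument built from the published variant characteristics
#'
#' The four-variant 25(OH)D instrument in exposure-increasing orientation
#' (per-allele effects 4.67, 1.72, 2.11, 0.98 nmol/L) with exposure
#' standard errors derived from the published p-values via
#' [se_from_pvalue()]. Outcome effects default to the null with
#' consortium-scale standard errors; supply `outcome_beta`/`outcome_se`
#' to pair the instrument with real or simulated outcome associations.
#'
#' @param outcome_beta Per-allele outcome log odds ratios in the same
#'   (exposure-increasing) orientation (default all 0).
#' @param outcome_se Per-allele outcome standard errors (> 0).
#' @return An `mr_instrument`.
#' @examples
#' make_fixture_instrument()
#' @export
make_fixture_instrument <- function(outcome_beta = rep(0, 4),
                                    outcome_se = default_outcome_ses) {
  if (length(outcome_beta) != 4 || length(outcome_se) != 4) {
    abort("outcome_beta and outcome_se must have length 4")
  }
  if (any(outcome_se <= 0)) abort("outcome_se must be > 0")
  records <- tibble::tibble(
    rsid = vitd_variants$rsid,
    locus = vitd_variants$locus,
    # printed coding has the 25(OH)D-lowering allele as effect allele;
    # the increasing allele is its unstated partner
    effect_allele = NA_character_,
    other_allele = vitd_variants$effect_allele,
    exposure_beta = abs(vitd_variants$beta),
    exposure_se = se_from_pvalue(vitd_variants$beta, vitd_variants$pvalue),
    outcome_beta = outcome_beta,
    outcome_se = outcome_se
  )
  log <- tibble::tibble(
    rsid = vitd_variants$rsid,
    action = "oriented",
    detail = "published coding recoded to the 25(OH)D-increasing allele"
  )
  new_mr_instrument(records, log, "nmol/L")
}
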