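---
title: "Methods: two-sample Mendelian randomisation of circulating vitamin D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation of circulating vitamin D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The problem and the instrument

Observational associations between circulating 25-hydroxyvitamin D
(25(OH)D) and cancer risk are heavily confounded: vitamin D status tracks
adiposity, physical activity, time outdoors, and general health, and
reverse causation (preclinical disease lowering 25(OH)D) is plausible.
Mendelian randomisation (MR) sidesteps both by using genetic variants as
instruments: alleles are fixed at conception, so a variant that raises
25(OH)D by a known amount provides a small randomized "dose" of lifelong
exposure.

`vitdmr` is built around the standard four-variant instrument for
25(OH)D, one variant per gene with a known role in vitamin D physiology:
transport (*GC*, rs2282679), hydroxylation (*CYP2R1*, rs10741657),
precursor synthesis (*DHCR7/NADSYN1*, rs12785878), and degradation
(*CYP24A1*, rs6013897). Their per-allele effects on 25(OH)D (4.67, 1.72,
2.11 and 0.98 nmol/L in the exposure-increasing orientation) and
association p-values are shipped as `vitd_variants` and as the plain-text
fixture `extdata/vitd_exposure.tsv`. Published sources report these with a
beta and a p-value but no standard error; `se_from_pvalue()` recovers
se = |beta|/z with the normal quantile evaluated on the log scale, which is
stable down to p ≈ 1e-302. A p-value printed as a bound ("< 3.4e-302") is
treated as an equality: at that extreme the instrument weight is insensitive
to the difference, and only a lower bound on precision is needed.

## Data model and harmonization

Summary statistics travel as tab-delimited tables with a named header
(`rsid, chr, locus, effect_allele, other_allele, eaf, beta, se, pvalue,
n_cases, n_controls`); columns outside the schema are ignored. `beta` is
nmol/L per allele for the exposure and log odds ratio per allele for the
outcome; each row needs `se` or `pvalue`.

`harmonize()` pairs the two tables by rsid and brings them onto one allele
orientation:

1. If the outcome's effect allele equals the exposure's effect allele
   (directly or after strand complementation) signs are kept; if it equals
   the exposure's other allele (or its complement), the outcome beta is
   negated.
2. Every pair is then oriented so the exposure beta is positive. This
   exposure-increasing convention is required for MR-Egger (whose intercept
   is not identifiable under arbitrary sign flips) and harmless for the
   symmetric estimators.
3. Palindromic variants (A/T, G/C) cannot be aligned from letters. The
   default policy retains them only when the effect-allele frequency is
   informative on both sides (|eaf − 0.5| > 0.08); same side of 0.5
   confirms the coding, opposite sides imply a strand flip. Otherwise the
   variant is excluded with a warning. The 0.08 threshold is the
   conventional conservative band beyond which strand assignment from
   frequency is considered reliable in GWAS harmonization practice.
   `"drop"` and `"keep"` policies are available for sensitivity checks.
4. A variant whose alleles are irreconcilable (e.g. indel codings) is
   excluded with a warning rather than failing the run; zero survivors is
   fatal. Every action lands in the `orientation_log` attribute.

Harmonization is idempotent — re-harmonizing its own output is a no-op —
and this is enforced by test.

## Estimators

All estimators consume the harmonized records (γ̂ⱼ, σₓⱼ, Γ̂ⱼ, σᵧⱼ) and
return the causal log OR per 1 nmol/L; `rescale_estimate()` converts to a
reporting increment (25 nmol/L by default, the conventional "one SD"
increment for 25(OH)D) in either direction.

**Wald ratio.** θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ with first-order delta SE σᵧⱼ/|γ̂ⱼ|. The
exposure-side uncertainty is deliberately ignored here, matching the IVW
weighting convention; the likelihood estimator is the route that honours
it, which keeps the IVW/likelihood comparison meaningful as a check on
instrument strength.

**IVW.** Fixed-effect inverse-variance weighting of the Wald ratios,
algebraically weighted least squares of Γ̂ on γ̂ through the origin. No
residual-variance inflation is applied: with four strong instruments and
homogeneous ratios the fixed-effect model is the reference analysis, and
pairing it with a fixed-parameter likelihood keeps the two methods'
agreement a meaningful diagnostic rather than a modelling artefact.

**Profile likelihood.** The bivariate measurement model
γ̂ⱼ ~ N(γⱼ, σₓⱼ²), Γ̂ⱼ ~ N(θγⱼ, σᵧⱼ²) with independent samples; the
per-variant γⱼ maximize out in closed form,
γⱼ\*(θ) = (γ̂ⱼ/σₓⱼ² + θΓ̂ⱼ/σᵧⱼ²)/(1/σₓⱼ² + θ²/σᵧⱼ²), leaving a 1-D
optimisation solved by golden-section/parabolic search (`optimize`,
tolerance 1e-10) on an interval of ±(|θ̂_IVW| + 100·se_IVW) around the IVW
estimate, widened and retried if the optimum lands on a boundary (six
widenings before a convergence error). The SE comes from the numerical
curvature of the profile log-likelihood (central second difference, step
max(1e-5, 1e-4·|θ̂|)); the profile-likelihood interval (likelihood-ratio
inversion by root-finding) is available via `ci = "profile"` since the
sources using this model do not state which interval they report — at the
instrument strengths shipped here the two are nearly identical, so the
cheaper Wald form is the default. Correlation between γ̂ and Γ̂ within a
study is not modelled: the two-sample design makes the independent-samples
form the natural choice.

**MR-Egger.** Weighted regression of Γ̂ on γ̂ with intercept, weights
σᵧⱼ⁻². Coefficient SEs are fixed-effect ((X'WX)⁻¹ without the residual
variance multiplier) to match the IVW convention; `dispersion = "residual"`
gives the conventional weighted-regression SEs. The intercept test is
normal by default with a t(J−2) option — at J = 4 the choice matters
(df = 2), and the normal default mirrors the fixed-effect treatment of the
other estimators; the option exists precisely because this is a judgement
call.

**Weighted median.** Wald ratios ordered, inverse-variance weights
normalized, breakpoints at cumulative weight minus half the variant's own
weight, linear interpolation at the 50% crossing. The SE is a parametric
bootstrap (default 2000 resamples of γ̂ⱼ and Γ̂ⱼ at their SEs; a seed is
mandatory so results are reproducible; fewer than 100 resamples draws a
warning).

**Allele scores.** `mr_score_subset()` reruns IVW on the synthesis
(rs10741657, rs12785878) or metabolism (rs2282679, rs6013897) pathway
subset; materially different subset estimates point to pathway-specific
pleiotropy.

P-values are two-sided and unadjusted throughout — each outcome is a
separate hypothesis reported at nominal level, as is conventional for
consortium-by-consortium MR reports. Display rounding is 2 decimals for
ORs, CIs and P (`format_mr_estimate()`); machine-readable outputs keep full
precision.

## Diagnostics

`mr_cochran_q()` computes Q = Σwⱼ(θ̂ⱼ − θ̂_IVW)² with the IVW weights
wⱼ = γ̂ⱼ²/σᵧⱼ², df = J−1, chi-square upper tail. Q is identically the
weighted sum of squared residuals of the IVW fit (a tested identity) and is
invariant to rescaling the exposure units. `mr_overid()` is the same
statistic under its over-identification label: with J instruments and one
parameter the model is over-identified, and in the fixed-effect
summary-data setting the Sargan-style equality test reduces to Q up to
parameterization. Implementing one statistic with two labels is deliberate:
it makes silent divergence between "goodness of fit" and
"over-identification" impossible. `consistency_report()` lays method
estimates side by side on the OR scale and flags pairs differing by more
than 0.01 (display rounding).

## Power

For a case-control outcome sample the package uses the symmetric log-OR
non-centrality approximation: power = Φ(√(N·R²·K(1−K))·|ln OR| − z₁₋α/₂),
inverted in closed form for the minimum detectable OR at target power. The
two bounds are exact reciprocals pre-rounding. This formula reproduces the
published design table for the large consortium rows at both R² values
(PRACTICAL 0.86/1.16 and 0.89/1.12, DRIVE 0.84, GAME-ON prostate 0.82,
GAME-ON colorectal 0.72 protective side) and the protective side of nearly
all remaining rows; a few published risk-direction cells (e.g. colorectal
1.39, neuroblastoma 0.58/1.57) sit 0.01–0.03 away, indicating the original
calculator used an asymmetric variant whose exact form is not stated. The
package documents this rather than reverse-engineering it, and its own
checks are restricted to the cells the symmetric formula reproduces.
Quantiles are computed in full double precision; rounding happens only at
display.

## Synthetic data: what it emulates and what it does not

`simulation_config()`/`simulate_summary_pair()` draw summary statistics
directly at the estimate level: γ̂ⱼ ~ N(γⱼ, σₓⱼ²),
Γ̂ⱼ ~ N(θγⱼ + αⱼ, σᵧⱼ²), with αⱼ zero, balanced N(0, sd²) or directional
N(m, sd²). This is exactly the sampling model the summary-data estimators
assume, so simulation results validate the estimators under their own
assumptions at desk scale — they do not probe LD between instruments,
winner's curse in instrument selection, sample overlap between exposure
and outcome GWAS, or case-control ascertainment effects, none of which the
estimators model either.

Defaults encode the study conditions the package is validated under:
γ = (4.67, 1.72, 2.11, 0.98) nmol/L with σₓ derived from the published
p-values, and σᵧ = (0.016, 0.018, 0.018, 0.022) per-allele log-OR, chosen
once so the pooled IVW SE on the per-25 nmol/L scale is ≈ 0.075 — the
width implied by large consortium confidence intervals such as
0.89 (0.77 to 1.02). Optional `flip_fraction` and `palindromic_fraction`
make the generated tables exercise the harmonization paths. A seed is
mandatory; identical configs produce byte-identical tables.

## Validation problem sizes

The shipped test suite validates, among others: IVW against a
normal-equations least-squares oracle (tolerance 1e-10, J ≤ 6); the
likelihood estimator against an iteratively refined θ-grid search (1e-6)
and its NOME limit; the weighted median against a brute-force
cumulative-weight scan; Q against the two-study closed form (1e-10); IVW
95% CI coverage at θ = ln(0.89)/25 within [0.93, 0.97] and IVW/
over-identification type-I error within [0.03, 0.07] (2000 replicates
each); IVW-vs-likelihood display-rounding agreement in ≥ 99% of 200
replicates; and mean Egger-intercept recovery of an injected 0.02 log-OR
directional pleiotropy within three Monte-Carlo standard errors (2000
replicates). These replicate counts give Monte-Carlo error comfortably
inside each acceptance band while keeping the default suite fast enough to
run routinely.

## Limitations

- Per-variant outcome associations for specific cancer consortia are
  inputs, not package data: the published per-variant cancer tables live in
  supplementary material without a machine-readable accession, so
  consortium-specific results are reproducible only when the user supplies
  those tables in the exchange schema. The pipeline path is exercised with
  synthetic stand-ins, labelled as such.
- No LD-aware multi-variant modelling, no proxy-variant search, no
  multivariable MR, no mode-based estimators, no MR-PRESSO.
- The weighted-median SE is bootstrap-based and therefore seed-dependent at
  the third decimal for small resample counts.
- Instrument F-statistics from the source cohorts are treated as metadata
  and are not recomputed (the underlying cohort data are not summary-level
  inputs to this package).
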