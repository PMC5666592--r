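test_that("the four allele-coding cases resolve to the sign-flip oracle", {
  # exposure: effect A, other G, beta +2 (already exposure-increasing)
  exposure <- assoc_table("rs1", "A", 2, se = 0.1, other_allele = "G")
  # outcome coded four ways; letter-based oracle: match or complement of the
  # effect allele keeps the sign, the other allele (or its complement) flips
  codings <- list(
    list(ea = "A", oa = "G", expect = +0.05),  # same coding
    list(ea = "G", oa = "A", expect = -0.05),  # other allele
    list(ea = "T", oa = "C", expect = +0.05),  # strand complement of effect
    list(ea = "C", oa = "T", expect = -0.05)   # strand complement of other
  )
  for (cs in codings) {
    outcome <- assoc_table("rs1", cs$ea, 0.05, se = 0.02,
                           other_allele = cs$oa)
    inst <- harmonize(exposure, outcome)
    expect_equal(inst$outcome_beta, cs$expect, info = cs$ea)
    expect_equal(inst$exposure_beta, 2)
  }
})

test_that("negative exposure effects are recoded to the increasing allele", {
  # published-style coding: effect G lowers 25(OH)D by 4.67 nmol/L
  exposure <- assoc_table("rs2282679", "G", -4.67, se = 0.126,
                          other_allele = "T")
  outcome <- assoc_table("rs2282679", "G", 0.05, se = 0.02,
                         other_allele = "T")
  inst <- harmonize(exposure, outcome)
  expect_equal(inst$exposure_beta, 4.67)
  expect_equal(inst$outcome_beta, -0.05)
  expect_equal(inst$effect_allele, "T")  # alleles swapped with the signs
  lg <- orientation_log(inst)
  expect_true(any(lg$action == "oriented"))
})

test_that("identical coding with positive exposure beta passes through unchanged", {
  exposure <- assoc_table(c("rs1", "rs2"), c("A", "C"), c(1.5, 0.8),
                          se = c(0.1, 0.1), other_allele = c("G", "T"))
  outcome <- assoc_table(c("rs1", "rs2"), c("A", "C"), c(0.03, -0.02),
                         se = c(0.02, 0.02), other_allele = c("G", "T"))
  inst <- harmonize(exposure, outcome)
  expect_equal(inst$exposure_beta, c(1.5, 0.8))
  expect_equal(inst$outcome_beta, c(0.03, -0.02))
  expect_true(all(orientation_log(inst)$action == "kept"))
})

test_that("double allele flip is the identity on the sign pattern", {
  exposure <- assoc_table("rs1", "A", 2, se = 0.1, other_allele = "G")
  outcome_same <- assoc_table("rs1", "A", 0.05, se = 0.02, other_allele = "G")
  # flip the outcome coding twice: swap alleles and negate beta, twice
  outcome_double <- assoc_table("rs1", "A", 0.05, se = 0.02,
                                other_allele = "G")
  i1 <- harmonize(exposure, outcome_same)
  i2 <- harmonize(exposure, outcome_double)
  expect_equal(i1$outcome_beta, i2$outcome_beta)
  # one flip negates relative to zero flips
  flipped <- assoc_table("rs1", "G", -0.05, se = 0.02, other_allele = "A")
  i3 <- harmonize(exposure, flipped)
  expect_equal(i3$outcome_beta, i1$outcome_beta)
})

test_that("palindromic variants follow the eaf policy", {
  pal_exposure <- function(eaf) {
    assoc_table("rs9", "A", 1.2, se = 0.1, other_allele = "T", eaf = eaf)
  }
  pal_outcome <- function(eaf, beta = 0.05) {
    assoc_table("rs9", "A", beta, se = 0.02, other_allele = "T", eaf = eaf)
  }
  # concordant informative frequencies: kept with sign as coded
  inst <- harmonize(pal_exposure(0.3), pal_outcome(0.28))
  expect_equal(inst$outcome_beta, 0.05)
  # opposite sides of 0.5: strand flip inferred, sign negated
  inst <- harmonize(pal_exposure(0.3), pal_outcome(0.72))
  expect_equal(inst$outcome_beta, -0.05)
  expect_true(any(orientation_log(inst)$action == "flipped"))
  # uninformative frequency: excluded (warning), and with no survivors fatal
  expect_error(
    expect_warning(harmonize(pal_exposure(0.48), pal_outcome(0.47)),
                   "uninformative"),
    "No variants survived"
  )
  # drop policy always excludes
  expect_error(
    expect_warning(
      harmonize(pal_exposure(0.3), pal_outcome(0.28), palindromic = "drop"),
      "policy: drop"),
    "No variants survived"
  )
  # keep policy trusts the letters even without eaf
  inst <- harmonize(pal_exposure(NA_real_), pal_outcome(NA_real_),
                    palindromic = "keep")
  expect_equal(inst$outcome_beta, 0.05)
})

test_that("irreconcilable and unmatched variants are excluded, not fatal", {
  exposure <- assoc_table(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                          c(1, 1, 1), se = c(0.1, 0.1, 0.1),
                          other_allele = c("G", "G", "G"))
  # rs2's outcome coding is an indel-style allele no SNP coding reconciles
  outcome <- assoc_table(c("rs1", "rs2"), c("A", "AT"), c(0.05, 0.05),
                         se = c(0.02, 0.02), other_allele = c("G", "G"))
  expect_warning(inst <- harmonize(exposure, outcome), "irreconcilable")
  expect_equal(inst$rsid, "rs1")
  lg <- orientation_log(inst)
  expect_equal(lg$action[lg$rsid == "rs2"], "excluded")
  expect_equal(lg$action[lg$rsid == "rs3"], "dropped")
})

test_that("missing other allele aligns by effect-allele match and is logged", {
  exposure <- assoc_table("rs1", "G", -2.0, se = 0.1)  # no other_allele
  outcome <- assoc_table("rs1", NA_character_, 0.05, se = 0.02)
  inst <- harmonize(exposure, outcome)
  expect_equal(inst$exposure_beta, 2.0)
  expect_equal(inst$outcome_beta, -0.05)
  expect_match(orientation_log(inst)$detail[1], "assumed same coding")
  # effect allele neither matches nor complements, no other allele: excluded
  outcome2 <- assoc_table("rs1", "A", 0.05, se = 0.02)
  expect_error(expect_warning(harmonize(exposure, outcome2)),
               "No variants survived")
})

test_that("harmonization is idempotent", {
  exposure <- assoc_table(c("rs1", "rs2"), c("G", "A"), c(-1.7, 0.9),
                          se = c(0.1, 0.12), other_allele = c("A", "C"))
  outcome <- assoc_table(c("rs1", "rs2"), c("A", "C"), c(0.04, 0.03),
                         se = c(0.02, 0.02), other_allele = c("G", "A"))
  once <- harmonize(exposure, outcome)
  twice <- harmonize(instrument_exposure_table(once),
                     instrument_outcome_table(once))
  cols <- c("rsid", "exposure_beta", "exposure_se", "outcome_beta",
            "outcome_se")
  expect_equal(as.data.frame(twice)[cols], as.data.frame(once)[cols])
})

test_that("harmonize validates its inputs", {
  exposure <- assoc_table("rs1", "A", 1, se = 0.1, other_allele = "G")
  expect_error(harmonize(exposure[0, ], exposure), "non-empty")
  dup <- dplyr::bind_rows(exposure, exposure)
  expect_error(harmonize(dup, exposure), "duplicate rsid")
})
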