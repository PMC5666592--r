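# Allele harmonization: bring SNP-exposure and SNP-outcome association
# tables onto a common effect-allele orientation so that every downstream
# estimator sees matched (gamma_hat, Gamma_hat) pairs coded on the
# exposure-increasing allele.

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- unname(DNA_COMPLEMENT[toupper(a)])
  out[is.na(a)] <- NA_character_
  out
}

is_palindromic <- function(effect, other) {
  !is.na(effect) & !is.na(other) &
    toupper(other) == complement_allele(effect)
}

new_mr_instrument <- function(records, orientation_log, exposure_unit) {
  structure(
    records,
    orientation_log = orientation_log,
    exposure_unit = exposure_unit,
    class = c("mr_instrument", class(tibble::tibble()))
  )
}

#' Harmonize exposure and outcome association tables
#'
#' Pairs SNP-exposure and SNP-outcome associations by rsid and aligns them
#' onto a common allele orientation. For each shared variant: if the outcome
#' effect allele equals the exposure effect allele (directly or after strand
#' complementation) the signs are kept; if it equals the exposure's other
#' allele the outcome effect is negated. Every pair is then oriented so the
#' exposure effect is positive (the exposure-increasing allele), negating
#' both effects where needed — required for MR-Egger identifiability and
#' harmless for the symmetric estimators.
#'
#' Palindromic variants (A/T or G/C) cannot be aligned from allele letters
#' alone. Under the default `palindromic = "eaf"` policy they are retained
#' when the effect-allele frequency is informative on both sides
#' (`|eaf - 0.5| > eaf_threshold`); frequencies on the same side of 0.5
#' confirm the letter-based alignment, opposite sides imply a strand flip
#' and the outcome effect is negated. Otherwise the variant is excluded
#' with a warning. `"drop"` always excludes palindromic variants;
#' `"keep"` trusts the letter-based alignment.
#'
#' Variants whose alleles are irreconcilable are excluded with a warning
#' rather than failing the run; an empty result is an error. Every flip,
#' exclusion and assumption is recorded in the `orientation_log` attribute.
#'
#' @param exposure,outcome Association tibbles as returned by
#'   [read_associations()] (schema columns; `se` present or derivable).
#' @param palindromic Policy for A/T and G/C variants: `"eaf"` (default),
#'   `"drop"`, or `"keep"`.
#' @param eaf_threshold Minimum `|eaf - 0.5|` for a frequency to count as
#'   strand-informative (default 0.08).
#' @param exposure_unit Unit label for the exposure effect (default
#'   `"nmol/L"`).
#' @return An `mr_instrument`: a tibble with columns `rsid`, `locus`,
#'   `effect_allele`, `other_allele`, `exposure_beta`, `exposure_se`,
#'   `outcome_beta`, `outcome_se`, plus attributes `orientation_log`
#'   (a tibble of per-variant actions) and `exposure_unit`.
#' @examples
#' exposure <- make_fixture_instrument() |> instrument_exposure_table()
#' outcome <- tibble::tibble(
#'   rsid = exposure$rsid, effect_allele = exposure$effect_allele,
#'   beta = c(-0.01, 0.02, 0.00, 0.01), se = rep(0.02, 4)
#' )
#' harmonize(exposure, outcome)
#' @export
harmonize <- function(exposure, outcome,
                      palindromic = c("eaf", "drop", "keep"),
                      eaf_threshold = 0.08,
                      exposure_unit = "nmol/L") {
  palindromic <- match.arg(palindromic)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("harmonize() needs non-empty exposure and outcome tables")
  }
  exposure <- complete_schema(exposure)
  outcome <- complete_schema(outcome)
  validate_associations(exposure, "exposure")
  validate_associations(outcome, "outcome")
  exposure <- fill_se(exposure)
  outcome <- fill_se(outcome)

  log_rows <- list()
  note <- function(rsid, action, detail = "") {
    log_rows[[length(log_rows) + 1L]] <<-
      tibble::tibble(rsid = rsid, action = action, detail = detail)
  }

  for (r in setdiff(exposure$rsid, outcome$rsid)) {
    note(r, "dropped", "no outcome association")
  }
  for (r in setdiff(outcome$rsid, exposure$rsid)) {
    note(r, "dropped", "no exposure association")
  }

  shared <- intersect(exposure$rsid, outcome$rsid)
  records <- purrr::map(shared, function(r) {
    ex <- exposure[exposure$rsid == r, ]
    ou <- outcome[outcome$rsid == r, ]
    g <- ex$beta; g_se <- ex$se
    o <- ou$beta; o_se <- ou$se
    ex_ea <- toupper(ex$effect_allele %||% NA_character_)
    ex_oa <- toupper(ex$other_allele %||% NA_character_)
    ou_ea <- toupper(ou$effect_allele %||% NA_character_)
    ou_eaf <- ou$eaf

    pal <- is_palindromic(ex_ea, ex_oa)
    if (isTRUE(pal)) {
      if (palindromic == "drop") {
        note(r, "excluded", "palindromic variant (policy: drop)")
        return(NULL)
      }
      if (palindromic == "eaf") {
        informative <- !is.na(ex$eaf) && !is.na(ou_eaf) &&
          abs(ex$eaf - 0.5) > eaf_threshold && abs(ou_eaf - 0.5) > eaf_threshold
        if (!informative) {
          note(r, "excluded", "palindromic variant with uninformative eaf")
          return(NULL)
        }
        # Align outcome onto the exposure effect allele by frequency:
        # letters agree -> same eaf side means same strand coding.
        letters_match <- !is.na(ou_ea) && ou_ea %in% c(ex_ea, complement_allele(ex_ea))
        same_side <- (ex$eaf - 0.5) * (ou_eaf - 0.5) > 0
        if (!letters_match) {
          note(r, "excluded", "palindromic variant, alleles irreconcilable")
          return(NULL)
        }
        if (!same_side) {
          o <- -o
          note(r, "flipped", "palindromic strand flip inferred from eaf")
        } else {
          note(r, "kept", "palindromic, eaf concordant")
        }
      } else {
        note(r, "kept", "palindromic retained as coded (policy: keep)")
      }
    } else if (is.na(ou_ea)) {
      note(r, "kept", "outcome effect allele missing, assumed same coding")
    } else if (!is.na(ex_ea) && ou_ea == ex_ea) {
      note(r, "kept", "effect alleles match")
    } else if (!is.na(ex_oa) && ou_ea == ex_oa) {
      o <- -o
      note(r, "flipped", "outcome coded on the other allele")
    } else if (!is.na(ex_ea) && ou_ea == complement_allele(ex_ea)) {
      note(r, "kept", "effect alleles match after strand complement")
    } else if (!is.na(ex_oa) && ou_ea == complement_allele(ex_oa)) {
      o <- -o
      note(r, "flipped", "other-allele match after strand complement")
    } else if (is.na(ex_oa)) {
      note(r, "excluded", "exposure other allele missing and effect alleles differ")
      return(NULL)
    } else {
      note(r, "excluded", "alleles irreconcilable (neither match nor complement)")
      return(NULL)
    }

    ea <- ex_ea; oa <- ex_oa
    if (!is.na(g) && g < 0) {
      g <- -g
      o <- -o
      tmp <- ea; ea <- oa; oa <- tmp
      note(r, "oriented", "recoded to the exposure-increasing allele")
    }
    tibble::tibble(
      rsid = r,
      locus = ex$locus %||% NA_character_,
      effect_allele = ea,
      other_allele = oa,
      exposure_beta = g,
      exposure_se = g_se,
      outcome_beta = o,
      outcome_se = o_se
    )
  })
  records <- dplyr::bind_rows(purrr::compact(records))
  orientation_log <- dplyr::bind_rows(log_rows)

  excl <- orientation_log[orientation_log$action == "excluded", ]
  if (nrow(excl) > 0) {
    warn(paste0(
      "Excluded ", nrow(excl), " variant(s) during harmonization: ",
      paste(excl$rsid, excl$detail, sep = ": ", collapse = "; ")
    ))
  }
  if (nrow(records) == 0) {
    abort("No variants survived harmonization")
  }
  stopifnot(all(records$exposure_beta > 0),
            all(records$exposure_se > 0), all(records$outcome_se > 0))
  new_mr_instrument(records, orientation_log, exposure_unit)
}

complete_schema <- function(tbl) {
  for (col in setdiff(assoc_schema, names(tbl))) {
    tbl[[col]] <- if (col %in% c("rsid", "chr", "locus", "effect_allele",
                                 "other_allele")) NA_character_ else NA_real_
  }
  tbl[assoc_schema]
}

fill_se <- function(tbl) {
  dplyr::mutate(tbl, se = dplyr::if_else(
    is.na(.data$se) & !is.na(.data$pvalue) & !is.na(.data$beta),
    se_from_pvalue(.data$beta, .data$pvalue),
    .data$se
  ))
}

#' Per-variant harmonization actions
#'
#' @param instrument An `mr_instrument` from [harmonize()].
#' @return A tibble with columns `rsid`, `action`
#'   (`kept`/`flipped`/`oriented`/`excluded`/`dropped`) and `detail`.
#' @export
orientation_log <- function(instrument) {
  attr(instrument, "orientation_log")
}

#' Exposure half of a harmonized instrument as an association table
#'
#' Useful for re-harmonizing, serializing, or pairing the instrument with a
#' new outcome table.
#'
#' @param instrument An `mr_instrument`.
#' @return A tibble in the [read_associations()] exposure schema.
#' @export
instrument_exposure_table <- function(instrument) {
  tibble::tibble(
    rsid = instrument$rsid,
    chr = NA_character_,
    locus = instrument$locus,
    effect_allele = instrument$effect_allele,
    other_allele = instrument$other_allele,
    eaf = NA_real_,
    beta = instrument$exposure_beta,
    se = instrument$exposure_se,
    pvalue = pvalue_from_se(instrument$exposure_beta, instrument$exposure_se),
    n_cases = NA_real_,
    n_controls = NA_real_
  )
}

#' Outcome half of a harmonized instrument as an association table
#'
#' @inheritParams instrument_exposure_table
#' @return A tibble in the [read_associations()] outcome schema.
#' @export
instrument_outcome_table <- function(instrument) {
  tibble::tibble(
    rsid = instrument$rsid,
    chr = NA_character_,
    locus = instrument$locus,
    effect_allele = instrument$effect_allele,
    other_allele = instrument$other_allele,
    eaf = NA_real_,
    beta = instrument$outcome_beta,
    se = instrument$outcome_se,
    pvalue = pvalue_from_se(instrument$outcome_beta, instrument$outcome_se),
    n_cases = NA_real_,
    n_controls = NA_real_
  )
}

#' @export
print.mr_instrument <- function(x, ...) {
  cat("Harmonized instrument: ", nrow(x), " variant(s), exposure in ",
      attr(x, "exposure_unit"), "\n", sep = "")
  NextMethod()
  lg <- orientation_log(x)
  if (!is.null(lg) && nrow(lg) > 0) {
    acted <- lg[lg$action != "kept", ]
    if (nrow(acted) > 0) {
      cat("Harmonization actions: ",
          paste(acted$rsid, acted$action, sep = " ", collapse = "; "), "\n")
    }
  }
  invisible(x)
}
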