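# Summary-statistic data model and tab-delimited exchange format.
#
# A variant-association table holds one row per SNP: its identifier, allele
# coding, per-allele effect estimate and uncertainty. For the exposure the
# effect is in nmol/L of 25(OH)D per effect allele; for a case-control
# outcome it is the per-allele log odds ratio.

#' Recognised columns of the summary-statistics exchange format
#'
#' Tab-delimited, UTF-8, named header, decimal point. Columns beyond this
#' schema are ignored on read and dropped on write.
#'
#' @format A character vector of column names.
#' @keywords internal
assoc_schema <- c(
  "rsid", "chr", "locus", "effect_allele", "other_allele", "eaf",
  "beta", "se", "pvalue", "n_cases", "n_controls"
)

assoc_col_types <- readr::cols(
  rsid = readr::col_character(),
  chr = readr::col_character(),
  locus = readr::col_character(),
  effect_allele = readr::col_character(),
  other_allele = readr::col_character(),
  eaf = readr::col_double(),
  beta = readr::col_double(),
  se = readr::col_double(),
  pvalue = readr::col_double(),
  n_cases = readr::col_double(),
  n_controls = readr::col_double(),
  .default = readr::col_skip()
)

#' Read a table of per-variant associations
#'
#' Reads a tab-delimited summary-statistics file into a tibble with one row
#' per variant. The `role` declares the semantics of `beta`: nmol/L of
#' 25(OH)D per effect allele for an exposure table, per-allele log odds
#' ratio for an outcome table. Each row must carry at least one of `se`
#' (standard error, > 0) or `pvalue` (two-sided, in (0, 1]); a missing
#' standard error is filled in from `beta` and `pvalue` via
#' [se_from_pvalue()].
#'
#' @param path Path to a tab-delimited file whose header names a subset of
#'   the schema columns `rsid, chr, locus, effect_allele, other_allele, eaf,
#'   beta, se, pvalue, n_cases, n_controls`.
#' @param role `"exposure"` or `"outcome"`.
#' @return A tibble with the schema columns (missing optional columns are
#'   present but `NA`), a `role` attribute, and `se` filled from `pvalue`
#'   where it was absent.
#' @seealso [write_associations()], [harmonize()]
#' @examples
#' path <- system.file("extdata", "vitd_exposure.tsv", package = "vitdmr")
#' read_associations(path, role = "exposure")
#' @export
read_associations <- function(path, role = c("exposure", "outcome")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  probs_seen <- character()
  tbl <- withCallingHandlers(
    readr::read_tsv(path, col_types = assoc_col_types, progress = FALSE,
                    na = c("", "NA")),
    warning = function(w) {
      probs_seen <<- c(probs_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed row(s) in %s: first at line %d (%s)",
      path, probs$row[1], probs$expected[1]
    ))
  }
  if (!"rsid" %in% names(tbl)) {
    abort(paste0("Header of ", path, " lacks the mandatory 'rsid' column"))
  }
  for (col in setdiff(assoc_schema, names(tbl))) {
    tbl[[col]] <- if (col %in% c("rsid", "chr", "locus", "effect_allele",
                                 "other_allele")) NA_character_ else NA_real_
  }
  tbl <- tbl[assoc_schema]
  validate_associations(tbl, path = path)
  tbl <- dplyr::mutate(
    tbl,
    se = dplyr::if_else(
      is.na(.data$se) & !is.na(.data$pvalue) & !is.na(.data$beta),
      se_from_pvalue(.data$beta, .data$pvalue),
      .data$se
    )
  )
  attr(tbl, "role") <- role
  tbl
}

validate_associations <- function(tbl, path = "<data>") {
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (anyNA(tbl$rsid)) abort(paste0(path, ": missing rsid"))
  if (anyDuplicated(tbl$rsid)) {
    dup <- tbl$rsid[duplicated(tbl$rsid)]
    abort(paste0(path, ": duplicate rsid ", paste(unique(dup), collapse = ", ")))
  }
  bad_se <- !is.na(tbl$se) & tbl$se <= 0
  if (any(bad_se)) {
    abort(paste0(path, ": non-positive se for ", paste(tbl$rsid[bad_se], collapse = ", ")))
  }
  bad_p <- !is.na(tbl$pvalue) & (tbl$pvalue <= 0 | tbl$pvalue > 1)
  if (any(bad_p)) {
    abort(paste0(path, ": pvalue outside (0, 1] for ",
                 paste(tbl$rsid[bad_p], collapse = ", ")))
  }
  no_unc <- is.na(tbl$se) & is.na(tbl$pvalue)
  if (any(no_unc)) {
    abort(paste0(path, ": neither se nor pvalue for ",
                 paste(tbl$rsid[no_unc], collapse = ", ")))
  }
  same_allele <- !is.na(tbl$effect_allele) & !is.na(tbl$other_allele) &
    tbl$effect_allele == tbl$other_allele
  if (any(same_allele)) {
    abort(paste0(path, ": effect_allele equals other_allele for ",
                 paste(tbl$rsid[same_allele], collapse = ", ")))
  }
  bad_eaf <- !is.na(tbl$eaf) & (tbl$eaf <= 0 | tbl$eaf >= 1)
  if (any(bad_eaf)) {
    abort(paste0(path, ": eaf outside (0, 1) for ",
                 paste(tbl$rsid[bad_eaf], collapse = ", ")))
  }
  invisible(tbl)
}

#' Write a table of per-variant associations
#'
#' Inverse of [read_associations()]: writes the schema columns as
#' tab-delimited UTF-8 so that a read/write/read cycle round-trips the data
#' fields.
#'
#' @param tbl A tibble with (a subset of) the schema columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(tbl, path) {
  keep <- intersect(assoc_schema, names(tbl))
  readr::write_tsv(tbl[keep], path, progress = FALSE)
  invisible(path)
}

#' Standard error implied by an effect estimate and its p-value
#'
#' Recovers the standard error from a Wald z-test: `se = |beta| / z` where
#' `z` is the upper-tail standard-normal quantile at `pvalue / 2`. The
#' quantile is evaluated on the log scale, so p-values as extreme as
#' 1e-302 are handled without underflow. P-values printed as bounds
#' ("< 3.4e-302") should be passed as the bound itself; at that extreme the
#' implied weight is insensitive to the distinction.
#'
#' @param beta Effect estimate(s), non-zero.
#' @param pvalue Two-sided p-value(s) in (0, 1].
#' @return Standard error(s), same length as the inputs (recycled).
#' @examples
#' se_from_pvalue(-0.98, 3.4e-17) # ~0.1162
#' @export
se_from_pvalue <- function(beta, pvalue) {
  n <- max(length(beta), length(pvalue))
  beta <- rep_len(beta, n)
  pvalue <- rep_len(pvalue, n)
  if (any(!is.na(pvalue) & (pvalue <= 0 | pvalue > 1))) {
    abort("pvalue must lie in (0, 1]")
  }
  if (any(!is.na(beta) & beta == 0)) {
    abort("se_from_pvalue is undefined at beta = 0")
  }
  z <- qnorm(log(pvalue) - log(2), lower.tail = FALSE, log.p = TRUE)
  abs(beta) / z
}

#' Two-sided p-value implied by an effect estimate and its standard error
#'
#' The inverse of [se_from_pvalue()]: `p = 2 * Phi(-|beta| / se)`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @return Two-sided p-value(s).
#' @export
pvalue_from_se <- function(beta, se) {
  if (any(!is.na(se) & se <= 0)) abort("se must be > 0")
  2 * pnorm(-abs(beta) / se)
}
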