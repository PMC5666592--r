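# Full study workflow: harmonize each labeled outcome table against the
# exposure table, run every requested estimator, attach diagnostics,
# rescale to the reporting increment, and emit result-table rows plus
# per-variant scatter data.

#' Run the full Mendelian randomisation analysis
#'
#' For each labeled outcome table: harmonizes against the exposure table,
#' fits the requested estimators, rescales them to the reporting increment
#' (odds ratio per `scale_increment` nmol/L increase by default), and runs
#' the heterogeneity, over-identification and Egger-intercept diagnostics.
#' An outcome that fails harmonization is reported and skipped; the run
#' only fails if every outcome fails.
#'
#' @param exposure An exposure association tibble (schema of
#'   [read_associations()]), or a path to one.
#' @param outcomes A named list of outcome association tibbles (or paths);
#'   names label the cancer/subtype/study.
#' @param methods Estimators to run, a subset of `"ivw"`, `"likelihood"`,
#'   `"egger"`, `"weighted_median"`, `"score_subsets"`.
#' @param scale_increment Exposure units per reported odds ratio
#'   (default 25 nmol/L).
#' @param direction Reporting direction, `"increase"` (default) or
#'   `"decrease"`.
#' @param bootstrap_reps,seed Weighted-median bootstrap control; `seed` is
#'   required when `"weighted_median"` is requested.
#' @param digits Display rounding for the formatted column (default 2).
#' @return An `mr_analysis` list: `estimates` (tibble: one row per outcome
#'   x method with full-precision and formatted results), `diagnostics`
#'   (tibble of Q/over-identification/Egger-intercept rows per outcome),
#'   `scatter` (per-variant figure data via [export_scatter_data()]),
#'   `instruments` (the harmonized instruments), `failures` (labels and
#'   reasons), and `config` (the settings used, including the seed).
#' @export
run_mr_analysis <- function(exposure, outcomes,
                            methods = c("ivw", "likelihood", "egger",
                                        "weighted_median", "score_subsets"),
                            scale_increment = 25,
                            direction = c("increase", "decrease"),
                            bootstrap_reps = 2000, seed = NULL,
                            digits = 2) {
  direction <- match.arg(direction)
  methods <- match.arg(methods, several.ok = TRUE)
  if ("weighted_median" %in% methods && is.null(seed)) {
    abort("seed is required when weighted_median is requested")
  }
  if (is.character(exposure)) {
    exposure <- read_associations(exposure, role = "exposure")
  }
  if (is.data.frame(outcomes)) outcomes <- list(outcome = outcomes)
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- paste0("outcome_", seq_along(outcomes))
  }

  estimates <- list()
  diagnostics <- list()
  scatter <- list()
  instruments <- list()
  failures <- list()

  for (label in names(outcomes)) {
    ou <- outcomes[[label]]
    if (is.character(ou)) ou <- read_associations(ou, role = "outcome")
    instrument <- tryCatch(
      harmonize(exposure, ou),
      error = function(e) {
        failures[[label]] <<- conditionMessage(e)
        NULL
      }
    )
    if (is.null(instrument)) next
    instruments[[label]] <- instrument

    fits <- list()
    if ("ivw" %in% methods) fits$ivw <- mr_ivw(instrument)
    if ("likelihood" %in% methods) fits$likelihood <- mr_likelihood(instrument)
    if ("egger" %in% methods && nrow(instrument) >= 3) {
      egger <- mr_egger(instrument)
      fits$egger <- egger$slope
      diagnostics[[paste0(label, ":egger")]] <- dplyr::mutate(
        mr_egger_intercept(egger), outcome = label, .before = 1)
    }
    if ("weighted_median" %in% methods && nrow(instrument) >= 3) {
      fits$weighted_median <- mr_weighted_median(
        instrument, bootstrap_reps = bootstrap_reps, seed = seed)
    }
    if ("score_subsets" %in% methods &&
        all(unlist(allele_scores) %in% instrument$rsid)) {
      fits$synthesis <- mr_score_subset(instrument, "synthesis")
      fits$metabolism <- mr_score_subset(instrument, "metabolism")
    }

    if (nrow(instrument) >= 2) {
      pooled <- mr_ivw(instrument)
      diagnostics[[paste0(label, ":q")]] <- dplyr::mutate(
        mr_cochran_q(instrument, pooled), outcome = label, .before = 1)
      diagnostics[[paste0(label, ":overid")]] <- dplyr::mutate(
        mr_overid(instrument, pooled), outcome = label, .before = 1)
    }

    estimates[[label]] <- purrr::imap_dfr(fits, function(fit, name) {
      scaled <- rescale_estimate(fit, scale_increment, direction)
      dplyr::mutate(
        tidy(scaled, exponentiate = TRUE),
        outcome = label,
        fit_label = name,
        display = format_mr_estimate(scaled, digits = digits),
        .before = 1
      )
    })
    scatter[[label]] <- dplyr::mutate(export_scatter_data(instrument),
                                      outcome = label, .before = 1)
  }

  if (length(failures) > 0) {
    warn(paste0("Outcome(s) failed harmonization and were skipped: ",
                paste(names(failures), collapse = ", ")))
  }
  if (length(estimates) == 0) {
    abort("All outcomes failed harmonization; nothing to report")
  }

  structure(
    list(
      estimates = dplyr::bind_rows(estimates),
      diagnostics = dplyr::bind_rows(diagnostics),
      scatter = dplyr::bind_rows(scatter),
      instruments = instruments,
      failures = tibble::tibble(outcome = names(failures),
                                reason = unlist(failures, use.names = FALSE) %||%
                                  character()),
      config = list(methods = methods, scale_increment = scale_increment,
                    direction = direction, bootstrap_reps = bootstrap_reps,
                    seed = seed, digits = digits)
    ),
    class = "mr_analysis"
  )
}

#' Per-variant scatter data for association figures
#'
#' One row per variant with the per-allele exposure and outcome effects and
#' their 95% confidence half-widths (`1.96 * se`), plus the fitted IVW
#' slope and its confidence band endpoints — the data behind plots of
#' per-allele cancer risk against per-allele 25(OH)D effect.
#'
#' @inheritParams wald_ratio
#' @return A tibble with columns `rsid`, `exposure_beta`, `exposure_ci`,
#'   `outcome_beta`, `outcome_ci`, `slope`, `slope_low`, `slope_high`.
#' @export
export_scatter_data <- function(instrument) {
  check_instrument(instrument, 1, "export_scatter_data()")
  fit <- mr_ivw(instrument)
  tibble::tibble(
    rsid = instrument$rsid,
    exposure_beta = instrument$exposure_beta,
    exposure_ci = qnorm(0.975) * instrument$exposure_se,
    outcome_beta = instrument$outcome_beta,
    outcome_ci = qnorm(0.975) * instrument$outcome_se,
    slope = fit$beta,
    slope_low = fit$ci_low,
    slope_high = fit$ci_high
  )
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("MR analysis: ", length(x$instruments), " outcome(s), methods: ",
      paste(x$config$methods, collapse = ", "), "\n", sep = "")
  cat("Odds ratios per ", x$config$scale_increment, " nmol/L ",
      x$config$direction, "\n\n", sep = "")
  tbl <- dplyr::select(x$estimates, "outcome", "fit_label", "display")
  print(tidyr::pivot_wider(tbl, names_from = "fit_label",
                           values_from = "display"), n = Inf)
  if (nrow(x$failures) > 0) {
    cat("\nSkipped outcomes:\n")
    print(x$failures)
  }
  invisible(x)
}

#' Write an analysis bundle as tab-delimited reports
#'
#' Emits `estimates.tsv`, `diagnostics.tsv` and `scatter.tsv` (full
#' precision; the `display` column carries the rounded report form) plus a
#' plain-text `summary.txt` with a provenance header (methods, scale,
#' seed).
#'
#' @param analysis An `mr_analysis` from [run_mr_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "mr_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(analysis$estimates, file.path(dir, "estimates.tsv"),
                   progress = FALSE)
  readr::write_tsv(analysis$diagnostics, file.path(dir, "diagnostics.tsv"),
                   progress = FALSE)
  readr::write_tsv(analysis$scatter, file.path(dir, "scatter.tsv"),
                   progress = FALSE)
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  on.exit(close(con))
  writeLines(c(
    "vitdmr analysis summary",
    paste0("methods: ", paste(analysis$config$methods, collapse = ", ")),
    paste0("scale: per ", analysis$config$scale_increment, " nmol/L ",
           analysis$config$direction),
    paste0("seed: ", analysis$config$seed %||% "none"),
    ""
  ), con)
  for (label in unique(analysis$estimates$outcome)) {
    rows <- analysis$estimates[analysis$estimates$outcome == label, ]
    writeLines(paste0(label, ":"), con)
    writeLines(paste0("  ", format(rows$fit_label, width = 16), rows$display),
               con)
  }
  invisible(dir)
}
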