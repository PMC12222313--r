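#' Render human-readable report tables from pipeline outputs
#'
#' Reads the emitted CSVs in `out_dir` and writes three report tables plus a
#' Kaplan-Meier figure: a baseline-characteristics table (mean (SD) for age,
#' No. (%) for sex, median \[IQR\] otherwise), the matched-balance table
#' (median \[IQR\], SMD, Mann-Whitney p), and the longitudinal-results table
#' (per-outcome APCs with CIs and interaction p). Missing upstream files are
#' skipped with a warning.
#'
#' @param out_dir pipeline output directory.
#' @return invisibly, a list of the report data.frames.
#' @export
render_reports <- function(out_dir) {
  res <- list()
  p <- function(f) file.path(out_dir, f)
  if (file.exists(p("patients.csv"))) {
    pat <- utils::read.csv(p("patients.csv"), na.strings = "")
    res$baseline <- baseline_characteristics(pat)
    utils::write.csv(res$baseline, p("report_baseline.csv"),
                     row.names = FALSE, quote = TRUE, na = "")
  } else warning("patients.csv missing; baseline report skipped")
  if (file.exists(p("apc_results.csv"))) {
    apc <- utils::read.csv(p("apc_results.csv"), na.strings = "")
    prim <- apc[apc$variant %in% c("primary", "dti"), , drop = FALSE]
    prim$estimate <- ifelse(
      is.na(prim$apc), "not estimable",
      sprintf("%.2f (%.2f; %.2f)", prim$apc, prim$ci_low, prim$ci_high))
    res$longitudinal <- prim[, c("outcome", "group", "estimate",
                                 "interaction_p")]
    utils::write.csv(res$longitudinal, p("report_longitudinal.csv"),
                     row.names = FALSE, quote = TRUE, na = "")
  } else warning("apc_results.csv missing; longitudinal report skipped")
  if (file.exists(p("km_curves.csv"))) {
    km <- utils::read.csv(p("km_curves.csv"))
    class(km) <- c("km_curve", class(km))
    grDevices::pdf(p("km_figure.pdf"), width = 6, height = 5)
    plot(km, main = "Probability of PIRA-free survival")
    grDevices::dev.off()
  }
  invisible(res)
}

#' Baseline-characteristics table
#'
#' One row per matching covariate, following the conventions of
#' observational MS cohort reports: mean (SD) for age, No. (%) female for
#' sex, median \[IQR\] for the remaining covariates.
#'
#' @param patients patient table.
#' @return data.frame `characteristic, value`.
#' @export
baseline_characteristics <- function(patients) {
  med <- function(x) sprintf("%.1f [%.1f; %.1f]", stats::median(x),
                             stats::quantile(x, 0.25), stats::quantile(x, 0.75))
  rows <- list(
    c("n", as.character(nrow(patients))),
    c("Age, mean (SD), years",
      sprintf("%.1f (%.1f)", mean(patients$age), stats::sd(patients$age))),
    c("Females, No. (%)",
      sprintf("%d (%.1f)", sum(patients$sex == "F"),
              100 * mean(patients$sex == "F"))),
    c("Disease duration, median [IQR], years",
      med(patients$disease_duration_years)),
    c("EDSS, median [IQR]", med(patients$edss_baseline)),
    c("Number of previous DMTs, median [IQR]", med(patients$n_prior_dmts)),
    c("Time under current treatment, median [IQR], years",
      med(patients$time_under_treatment_years)),
    c("sNfL, median [IQR], pg/ml", med(patients$snfl_pg_ml)),
    c("sNfL Z-score, median [IQR]", med(patients$snfl_z)),
    c("T2LV, median [IQR], ml", med(patients$t2_volume_ml)),
    c("T2L count, median [IQR]", med(patients$t2_count)))
  data.frame(characteristic = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2), stringsAsFactors = FALSE)
}
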