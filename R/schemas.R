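#' Canonical table schemas
#'
#' Column layouts of the pipeline's CSV interfaces. Used by
#' [validate_table()] before any modelling stage runs.
#'
#' @return named list of character vectors (column names in order).
#' @export
table_schemas <- function() {
  list(
    patients = c("patient_id", "group", "age", "sex",
                 "disease_duration_years", "n_prior_dmts", "t2_count",
                 "t2_volume_ml", "snfl_pg_ml", "snfl_z", "edss_baseline",
                 "time_under_treatment_years", "discontinuation_day",
                 "last_visit_day"),
    visits = c("patient_id", "day", "edss"),
    relapses = c("patient_id", "day"),
    mri = c("patient_id", "day", "field_strength", "tiv_ml", "brain_ml",
            "cortex_ml", "thalamus_ml", "gm_ml",
            "fa_wml", "fa_nawm", "fa_cortex",
            "md_wml", "md_nawm", "md_cortex",
            "rd_wml", "rd_nawm", "rd_cortex",
            "ad_wml", "ad_nawm", "ad_cortex",
            "prl_count", "new_t2_flag"))
}

#' Validate a table against its canonical schema
#'
#' Checks column names/order and key value constraints (valid EDSS steps,
#' positive volumes, FA in \[0,1\], non-negative PRL counts, groups limited
#' to the two treatments), reporting offending row numbers.
#'
#' @param df data.frame.
#' @param what one of `"patients"`, `"visits"`, `"relapses"`, `"mri"`.
#' @param file optional file name for diagnostics.
#' @return invisibly `TRUE`; otherwise an error naming file/rows.
#' @export
validate_table <- function(df, what, file = what) {
  schema <- table_schemas()[[what]]
  if (is.null(schema)) stop("unknown table kind: ", what)
  if (!identical(names(df), schema))
    stop(file, ": columns must be exactly (", paste(schema, collapse = ","),
         "); got (", paste(names(df), collapse = ","), ")")
  complain <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      stop(file, ": ", msg, " at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (what == "patients") {
    complain(!df$group %in% c("teriflunomide", "ocrelizumab"),
             "unknown treatment group")
    complain(!is_valid_edss(df$edss_baseline), "invalid baseline EDSS")
    complain(df$age <= 0, "non-positive age")
    complain(duplicated(df$patient_id), "duplicate patient_id")
  } else if (what == "visits") {
    complain(!is_valid_edss(df$edss), "invalid EDSS step")
    complain(duplicated(df[c("patient_id", "day")]),
             "duplicate patient-day EDSS entry")
  } else if (what == "mri") {
    vols <- c("brain_ml", "cortex_ml", "thalamus_ml", "gm_ml")
    for (v in vols) complain(df[[v]] <= 0, paste("non-positive", v))
    complain(df$fa_wml < 0 | df$fa_wml > 1, "FA outside [0, 1]")
    complain(!is.na(df$prl_count) & df$prl_count < 0, "negative PRL count")
    complain(!df$new_t2_flag %in% c(0, 1), "new_t2_flag must be 0/1")
  }
  invisible(TRUE)
}
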