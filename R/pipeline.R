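#' Pipeline configuration
#'
#' Nests the simulator configuration with stage toggles, event-detection and
#' matching settings. Unknown keys are rejected up front.
#'
#' @param seed master seed; also seeds the simulator unless the nested
#'   simulation config overrides it.
#' @param out_dir output directory.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "events", "match", "survival", "mri", "report")`.
#' @param input_dir read cohort CSVs from here instead of simulating (the
#'   `simulate` stage is then skipped).
#' @param simulation list of overrides passed to [sim_config()].
#' @param confirmation_window,sustained,pre_window event-detection settings.
#' @param event_time event dating, `"onset"` or `"confirmation"`.
#' @param caliper_sd matching caliper in SDs of the logit propensity.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "smoldercmp_out",
                            stages = c("simulate", "events", "match",
                                       "survival", "mri", "report"),
                            input_dir = NULL,
                            simulation = list(),
                            confirmation_window = 180, sustained = TRUE,
                            pre_window = 90, event_time = "onset",
                            caliper_sd = 0.2) {
  known <- c("simulate", "events", "match", "survival", "mri", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.list(simulation)) stop("simulation overrides must be a list")
  badkeys <- setdiff(names(simulation), names(formals(sim_config)))
  if (length(badkeys))
    stop("unknown simulation key(s): ", paste(badkeys, collapse = ", "))
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 input_dir = input_dir, simulation = simulation,
                 confirmation_window = confirmation_window,
                 sustained = sustained, pre_window = pre_window,
                 event_time = event_time, caliper_sd = caliper_sd),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments; unknown keys are rejected.
#' @param seed,out_dir optional overrides (e.g. from the command line).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> event detection -> per-endpoint
#' propensity matching -> time-to-progression suite -> longitudinal MRI
#' models -> report rendering, writing the canonical CSV/JSON artifacts and
#' a run manifest to `config$out_dir`. Inputs (simulated or user-supplied)
#' are schema-validated before any modelling.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest (list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    r <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), s, units = "secs")), 3)
    r
  }

  # --- data: simulate or ingest ------------------------------------------
  if (!is.null(config$input_dir)) {
    cohort <- tick("ingest", read_cohort(config$input_dir))
  } else if ("simulate" %in% config$stages) {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- tick("simulate", simulate_cohort(scfg))
    write_cohort(cohort, out)
  } else stop("no input: enable the simulate stage or set input_dir")
  for (nm in c("patients", "visits", "relapses", "mri"))
    validate_table(cohort[[nm]], nm, paste0(nm, ".csv"))

  patients <- cohort$patients
  row_counts <- vapply(cohort[c("patients", "visits", "relapses", "mri")],
                       nrow, integer(1))

  # --- events -------------------------------------------------------------
  events <- NULL
  if ("events" %in% config$stages) {
    events <- tick("events", detect_events(
      cohort$visits, cohort$relapses,
      cohort$mri[, c("patient_id", "day", "new_t2_flag")],
      confirmation_window = config$confirmation_window,
      sustained = config$sustained, pre_window = config$pre_window))
    ev_out <- events[, c("patient_id", "onset_day", "confirmation_day",
                         "reference_edss", "onset_edss", "is_pira",
                         "is_pirma")]
    utils::write.csv(ev_out, file.path(out, "events.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
    row_counts["events"] <- nrow(events)
  }

  # --- matching: one matched set per endpoint cohort ----------------------
  pairs_all <- NULL
  if ("match" %in% config$stages) {
    eligible <- list(
      clinical = patients$patient_id,
      atrophy = unique(cohort$mri$patient_id[!is.na(cohort$mri$brain_ml)]),
      dti = unique(cohort$mri$patient_id[!is.na(cohort$mri$fa_wml)]),
      prl = unique(cohort$mri$patient_id[!is.na(cohort$mri$prl_count)]))
    pairs_all <- tick("match", {
      res <- lapply(names(eligible), function(ep) {
        sub <- patients[patients$patient_id %in% eligible[[ep]], ]
        if (min(table(factor(sub$group, c("ocrelizumab", "teriflunomide")))) < 10)
          return(NULL)
        tryCatch({
          pm <- fit_propensity(sub)
          pr <- match_1to1(pm, caliper_sd = config$caliper_sd,
                           seed = config$seed)
          if (nrow(pr)) cbind(endpoint = ep, pr) else NULL
        }, error = function(e) {
          warning("matching skipped for endpoint '", ep, "': ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      })
      do.call(rbind, res)
    })
    utils::write.csv(pairs_all, file.path(out, "pairs.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
    bal <- do.call(rbind, lapply(unique(pairs_all$endpoint), function(ep) {
      pp <- pairs_all[pairs_all$endpoint == ep, ]
      sub <- patients[patients$patient_id %in% c(pp$teri_id, pp$ocre_id), ]
      cbind(endpoint = ep, balance_table(sub))
    }))
    utils::write.csv(bal, file.path(out, "balance.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
    row_counts["pairs"] <- nrow(pairs_all)
  }

  # --- survival suite ------------------------------------------------------
  if ("survival" %in% config$stages && !is.null(events) && !is.null(pairs_all) &&
      any(pairs_all$endpoint == "clinical")) {
    cp <- pairs_all[pairs_all$endpoint == "clinical", ]
    suite <- tick("survival", run_endpoint_suite(
      patients, events, cp, event_time = config$event_time))
    cox_json <- lapply(suite, function(r) {
      if (inherits(r, "cox_result"))
        list(hazard_ratio = r$hazard_ratio, ci_low = r$ci_low,
             ci_high = r$ci_high, p_value = r$p_value,
             n_events = r$n_events, n_subjects = r$n_subjects)
      else list(error = conditionMessage(r))
    })
    jsonlite::write_json(cox_json, file.path(out, "cox_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    matched <- patients[patients$patient_id %in% c(cp$teri_id, cp$ocre_id), ]
    rec <- build_survival_records(matched, events, endpoint = "pira",
                                  event_time = config$event_time)
    utils::write.csv(rec, file.path(out, "survival.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
    km <- km_estimate(rec)
    utils::write.csv(as.data.frame(km), file.path(out, "km_curves.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
  }

  # --- longitudinal MRI models --------------------------------------------
  apc_rows <- NULL
  prl_res <- NULL
  if ("mri" %in% config$stages && !is.null(pairs_all)) {
    mri_g <- merge(cohort$mri,
                   patients[, c("patient_id", "group")], by = "patient_id")
    sub_for <- function(ep) {
      pp <- pairs_all[pairs_all$endpoint == ep, ]
      mri_g[mri_g$patient_id %in% c(pp$teri_id, pp$ocre_id), , drop = FALSE]
    }
    tick("mri", {
      bvl <- run_bvl_sensitivity_suite(sub_for("atrophy"), patients,
                                       cohort$relapses)
      dti <- fit_dti_suite(sub_for("dti"))
      prl_obs <- sub_for("prl")
      prl_res <- if (any(!is.na(prl_obs$prl_count)))
        analyze_prl(prl_obs) else NULL
      flat <- function(r, outcome) {
        if (!inherits(r, "apc_result"))
          return(data.frame(outcome = outcome, variant = "unestimable",
                            group = NA, apc = NA, ci_low = NA, ci_high = NA,
                            interaction_p = NA, n_subj = NA, n_obs = NA))
        data.frame(outcome = outcome, variant = r$variant,
                   group = r$apc$group, apc = r$apc$apc,
                   ci_low = r$apc$ci_low, ci_high = r$apc$ci_high,
                   interaction_p = r$p_interaction,
                   n_subj = r$n_subjects, n_obs = r$n_obs)
      }
      rows <- list()
      for (oc in names(bvl)) for (vt in names(bvl[[oc]]))
        rows[[length(rows) + 1]] <- flat(bvl[[oc]][[vt]], oc)
      for (oc in names(dti))
        rows[[length(rows) + 1]] <- flat(dti[[oc]], oc)
      apc_rows <- do.call(rbind, rows)
    })
    utils::write.csv(apc_rows, file.path(out, "apc_results.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
    if (!is.null(prl_res)) {
      jsonlite::write_json(
        list(counts = prl_res$counts, p_interaction = prl_res$p_interaction),
        file.path(out, "prl_results.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows", pretty = TRUE)
    }
  }

  # --- reports -------------------------------------------------------------
  if ("report" %in% config$stages) tick("report", render_reports(out))

  manifest <- list(
    package_version = as.character(utils::packageVersion("smoldercmp")),
    seed = config$seed,
    config_hash = config_hash(config),
    stage_timings_sec = timings,
    row_counts = as.list(row_counts),
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  tmp <- tempfile(tmpdir = out)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(out, "manifest.json"))
  invisible(manifest)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; identical config gives an
#' identical hash.
#'
#' @param config a `pipeline_config`.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
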