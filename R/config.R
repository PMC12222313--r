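#' Simulation configuration for synthetic RRMS cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and friends. Defaults emulate a two-arm observational
#' cohort of relapsing-remitting MS patients treated with teriflunomide or
#' ocrelizumab: confounded treatment assignment, annual clinical visits with
#' EDSS, sparse relapses, annual MRI with volumetric/DTI/PRL metrics, and
#' asymmetric follow-up (median 3.1 years ocrelizumab, 1.9 years
#' teriflunomide).
#'
#' @param n_per_group patients per treatment arm (>= 2).
#' @param seed integer RNG seed; identical config + seed give byte-identical
#'   output tables.
#' @param confounding_strength scale (log-odds) of the covariate effect on
#'   treatment assignment; 0 gives random assignment.
#' @param true_pira_hazard_ratio hazard ratio for PIRA, teriflunomide vs
#'   ocrelizumab.
#' @param baseline_pira_rate latent PIRA hazard in the ocrelizumab arm,
#'   events/person-year. The latent hazard exceeds the detected incidence
#'   because a confirmed event needs a qualifying visit plus a confirming
#'   visit at least six months later within follow-up.
#' @param relapse_rate relapse hazard, events/person-year (both arms).
#' @param true_apc named list `ocrelizumab`/`teriflunomide`, each a named
#'   vector of annualized percentage changes (%/year, negative = loss) for
#'   `brain`, `cortex`, `thalamus`, `gm`.
#' @param dti_drift named numeric vector of 12 linear drifts (%/year) for the
#'   DTI outcomes (`fa_wml`, ..., `ad_cortex`); default all zero.
#' @param prl_new_prob expected new paramagnetic rim lesions per person-year.
#' @param new_t2_rate baseline rate of new/enlarged T2 lesions per
#'   person-year (between-relapse); intervals containing a relapse use
#'   `new_t2_relapse_prob` instead.
#' @param new_t2_relapse_prob probability a scan interval containing a
#'   relapse shows new/enlarged T2 lesions.
#' @param visit_interval_days,visit_jitter_days clinical visit cadence: mean
#'   spacing and half-width of its uniform jitter.
#' @param mri_interval_days,mri_jitter_days MRI cadence, same convention.
#' @param dropout_rate treatment-discontinuation hazard, per person-year.
#' @param measurement_sd named vector: `volume` (SD of multiplicative
#'   log-scale noise on volumes), `dti` (same for DTI region means).
#' @param followup_median_years named vector of median follow-up per group,
#'   years.
#' @param followup_max_years hard cap on follow-up, years.
#' @param mri_cohort_sizes named vector `volumetric`, `dti`, `prl`: patients
#'   per group whose scans carry those metric blocks (capped at
#'   `n_per_group`).
#' @param relapse_residual_prob probability a relapse leaves a permanent
#'   +0.5 EDSS residual.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = 128,
                       seed = 1L,
                       confounding_strength = 0.5,
                       true_pira_hazard_ratio = 0.80,
                       baseline_pira_rate = 0.12,
                       relapse_rate = 0.10,
                       true_apc = list(
                         ocrelizumab  = c(brain = -1.06, cortex = -1.24,
                                          thalamus = -0.97, gm = -1.20),
                         teriflunomide = c(brain = -0.80, cortex = -0.97,
                                           thalamus = -1.04, gm = -0.92)),
                       dti_drift = NULL,
                       prl_new_prob = 0.02,
                       new_t2_rate = 0.05,
                       new_t2_relapse_prob = 0.6,
                       visit_interval_days = 182, visit_jitter_days = 45,
                       mri_interval_days = 365, mri_jitter_days = 90,
                       dropout_rate = 0.05,
                       measurement_sd = c(volume = 0.004, dti = 0.01),
                       followup_median_years = c(ocrelizumab = 3.1,
                                                 teriflunomide = 1.9),
                       followup_max_years = 6,
                       mri_cohort_sizes = c(volumetric = 72, dti = 33, prl = 31),
                       relapse_residual_prob = 0.3) {
  if (is.null(dti_drift)) {
    dti_drift <- stats::setNames(rep(0, 12), dti_outcomes())
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    confounding_strength = confounding_strength,
    true_pira_hazard_ratio = true_pira_hazard_ratio,
    baseline_pira_rate = baseline_pira_rate, relapse_rate = relapse_rate,
    true_apc = true_apc, dti_drift = dti_drift,
    prl_new_prob = prl_new_prob, new_t2_rate = new_t2_rate,
    new_t2_relapse_prob = new_t2_relapse_prob,
    visit_interval_days = visit_interval_days,
    visit_jitter_days = visit_jitter_days,
    mri_interval_days = mri_interval_days, mri_jitter_days = mri_jitter_days,
    dropout_rate = dropout_rate, measurement_sd = measurement_sd,
    followup_median_years = followup_median_years,
    followup_max_years = followup_max_years,
    mri_cohort_sizes = mri_cohort_sizes,
    relapse_residual_prob = relapse_residual_prob)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param config a candidate configuration list.
#' @export
validate_sim_config <- function(config) {
  if (config$n_per_group < 2) stop("invalid config: n_per_group must be >= 2")
  rates <- c(config$baseline_pira_rate, config$relapse_rate,
             config$dropout_rate, config$prl_new_prob, config$new_t2_rate)
  if (any(rates < 0)) stop("invalid config: rates must be non-negative")
  if (config$true_pira_hazard_ratio <= 0)
    stop("invalid config: hazard ratio must be positive")
  if (config$new_t2_relapse_prob < 0 || config$new_t2_relapse_prob > 1 ||
      config$relapse_residual_prob < 0 || config$relapse_residual_prob > 1)
    stop("invalid config: probabilities must lie in [0, 1]")
  if (!all(c("ocrelizumab", "teriflunomide") %in% names(config$true_apc)))
    stop("invalid config: true_apc needs both treatment groups")
  invisible(config)
}

#' Names of the twelve DTI outcomes
#'
#' Region means of FA, MD, RD and AD within white-matter lesions, NAWM and
#' cortex, in the column order of the MRI table.
#' @return character vector of length 12.
#' @export
dti_outcomes <- function() {
  as.vector(outer(c("fa", "md", "rd", "ad"), c("wml", "nawm", "cortex"),
                  function(m, r) paste(m, r, sep = "_")))
}

#' Names of the four volumetric outcomes
#' @return character vector.
#' @export
volumetric_outcomes <- function() c("brain", "cortex", "thalamus", "gm")

#' The ten propensity-matching covariates
#'
#' Baseline age, sex, disease duration, number of previous DMTs, T2-lesion
#' count and volume, raw and Z-scored serum neurofilament light chain, EDSS,
#' and time under current treatment.
#' @return character vector of column names in `patients.csv`.
#' @export
matching_covariates <- function() {
  c("age", "sex", "disease_duration_years", "n_prior_dmts", "t2_count",
    "t2_volume_ml", "snfl_pg_ml", "snfl_z", "edss_baseline",
    "time_under_treatment_years")
}
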