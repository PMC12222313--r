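#' Annualized percentage change via a linear mixed-effects model
#'
#' Fits `log(outcome) ~ group + time + group:time (+ field_strength + TIV)`
#' with a random intercept per participant (REML), where time is years since
#' treatment start. On this scale a constant relative change per year is a
#' linear trend, and the group-specific annualized percentage change is
#' `APC = 100 * (exp(beta_time [+ beta_interaction]) - 1)`, with Wald 95%
#' confidence intervals and a Wald test of the treatment-by-time
#' interaction. Field strength and standardized TIV enter as fixed
#' covariates for volumetric outcomes only.
#'
#' An alternative `time_transform = "log"` specification regresses the
#' log outcome on `log(1 + time)`; its APC is then the fitted percent change
#' over the first year. The default (`"linear"`) is the canonical APC
#' construction.
#'
#' @param observations long MRI table (needs `patient_id`, `day`, `group`,
#'   the outcome column, and `field_strength`/`tiv_ml` when
#'   `volumetric = TRUE`). Rows with a missing outcome are dropped.
#' @param outcome outcome column name (strictly positive values).
#' @param volumetric include field strength + TIV covariates.
#' @param extra_terms optional character vector of additional fixed-effect
#'   terms (e.g. `"age * time_years"`), used by the sensitivity suite.
#' @param time_transform `"linear"` (default) or `"log"`.
#' @param variant free-text label stored in the result.
#' @return object of class `apc_result`: list with `outcome`, `variant`,
#'   `apc` (data.frame `group, apc, ci_low, ci_high`), `p_interaction`,
#'   `n_subjects`, `n_obs`, and the `lme4` fit.
#' @export
fit_apc_model <- function(observations, outcome, volumetric = TRUE,
                          extra_terms = NULL,
                          time_transform = c("linear", "log"),
                          variant = "primary") {
  time_transform <- match.arg(time_transform)
  stopifnot(outcome %in% names(observations))
  df <- observations[!is.na(observations[[outcome]]), , drop = FALSE]
  if (!nrow(df)) stop("no observations with non-missing outcome ", outcome)
  bad <- df[[outcome]] <= 0
  if (any(bad))
    stop("non-positive outcome values under log transform (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  n_multi <- sum(table(df$patient_id) >= 2)
  if (n_multi == 0)
    stop("every subject has a single timepoint: slope is unidentifiable")
  df$.y <- log(df[[outcome]])
  df$time_years <- df$day / 365.25
  df$.t <- if (time_transform == "linear") df$time_years else log1p(df$time_years)
  df$group <- factor(df$group, levels = c("ocrelizumab", "teriflunomide"))
  terms <- c("group", ".t", "group:.t")
  if (volumetric) {
    df$.tiv_z <- as.vector(scale(df$tiv_ml))
    if (all(is.na(df$.tiv_z)) || stats::sd(df$tiv_ml) == 0) df$.tiv_z <- 0
    terms <- c(terms, "field_strength", ".tiv_z")
  }
  terms <- c(terms, extra_terms)
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + "),
                                 "+ (1 | patient_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  it <- ".t"
  ix <- "groupteriflunomide:.t"
  b_t <- fe[[it]]
  b_i <- fe[[ix]]
  v_t <- V[it, it]
  v_i <- V[ix, ix]
  cv <- V[it, ix]
  scale_t <- if (time_transform == "linear") 1 else log(2)  # % over year 1
  z975 <- stats::qnorm(0.975)
  apc_from <- function(b, v) {
    se <- sqrt(v)
    100 * (exp(scale_t * c(b, b - z975 * se, b + z975 * se)) - 1)
  }
  a_ocre <- apc_from(b_t, v_t)
  a_teri <- apc_from(b_t + b_i, v_t + v_i + 2 * cv)
  se_i <- sqrt(v_i)
  p_int <- if (!is.finite(se_i) || se_i < 1e-12) {
    if (abs(b_i) < 1e-8) 1 else 0
  } else 2 * stats::pnorm(-abs(b_i / se_i))
  structure(list(
    outcome = outcome, variant = variant,
    apc = data.frame(group = c("ocrelizumab", "teriflunomide"),
                     apc = c(a_ocre[1], a_teri[1]),
                     ci_low = c(a_ocre[2], a_teri[2]),
                     ci_high = c(a_ocre[3], a_teri[3]),
                     stringsAsFactors = FALSE),
    p_interaction = p_int,
    n_subjects = length(unique(df$patient_id)),
    n_obs = nrow(df),
    fit = fit), class = "apc_result")
}

#' @export
print.apc_result <- function(x, ...) {
  cat(sprintf("APC for %s [%s]: ocrelizumab %.2f (%.2f; %.2f), teriflunomide %.2f (%.2f; %.2f) %%/year; interaction p = %.3g\n",
              x$outcome, x$variant,
              x$apc$apc[1], x$apc$ci_low[1], x$apc$ci_high[1],
              x$apc$apc[2], x$apc$ci_low[2], x$apc$ci_high[2],
              x$p_interaction))
  invisible(x)
}

.vol_columns <- c(brain = "brain_ml", cortex = "cortex_ml",
                  thalamus = "thalamus_ml", gm = "gm_ml")

#' Brain-volume-loss sensitivity suite
#'
#' For each volumetric outcome, refits the APC model under four sensitivity
#' schemes: (1) adding baseline age, sex and disease duration with their
#' time interactions; (2) adding the annualized relapse rate during each
#' patient's MRI follow-up with its time interaction; (3) restricting to
#' patients with at least two scans; (4) restricting to scans at least 183
#' days (6 months) after treatment initiation. Unestimable variants are
#' returned as condition objects, flagged, without aborting the suite.
#'
#' @param observations MRI table merged with `group`.
#' @param patients baseline table (for age, sex, disease duration).
#' @param relapses relapse table (for the ARR covariate).
#' @param outcomes volumetric outcome names (default all four).
#' @return nested list: `result[[outcome]][[variant]]`, variants `primary`,
#'   `demographics`, `arr`, `min2scans`, `post6mo`.
#' @export
run_bvl_sensitivity_suite <- function(observations, patients, relapses,
                                      outcomes = volumetric_outcomes()) {
  obs <- merge(observations,
               patients[, c("patient_id", "age", "sex",
                            "disease_duration_years")],
               by = "patient_id")
  obs$sex_male <- as.integer(obs$sex == "M")
  obs$time_years <- obs$day / 365.25
  # ARR over each patient's MRI follow-up window
  arr <- vapply(split(obs, obs$patient_id), function(d) {
    span <- (max(d$day) - min(d$day)) / 365.25
    if (span <= 0) return(0)
    nrel <- sum(relapses$patient_id == d$patient_id[1] &
                  relapses$day >= min(d$day) & relapses$day <= max(d$day))
    nrel / span
  }, numeric(1))
  obs$arr <- arr[match(obs$patient_id, names(arr))]

  scans_per <- table(obs$patient_id[!is.na(obs[[.vol_columns[[1]]]])])
  multi_ids <- names(scans_per)[scans_per >= 2]

  lapply(stats::setNames(outcomes, outcomes), function(oc) {
    col <- .vol_columns[[oc]]
    safely <- function(expr) tryCatch(expr, error = function(e) e)
    list(
      primary = safely(fit_apc_model(obs, col, variant = "primary")),
      demographics = safely(fit_apc_model(
        obs, col, variant = "demographics",
        extra_terms = c("age * .t", "sex_male * .t",
                        "disease_duration_years * .t"))),
      arr = safely(fit_apc_model(obs, col, variant = "arr",
                                 extra_terms = "arr * .t")),
      min2scans = safely(fit_apc_model(
        obs[obs$patient_id %in% multi_ids, , drop = FALSE], col,
        variant = "min2scans")),
      post6mo = safely(fit_apc_model(
        obs[obs$day >= 183, , drop = FALSE], col, variant = "post6mo"))
    )
  })
}

#' DTI longitudinal suite
#'
#' One APC model per (metric, region) pair — 12 models, without
#' field-strength or TIV covariates and without multiplicity adjustment.
#'
#' @param observations MRI table with `group`.
#' @return named list of 12 `apc_result` (or condition objects).
#' @export
fit_dti_suite <- function(observations) {
  lapply(stats::setNames(dti_outcomes(), dti_outcomes()), function(oc) {
    tryCatch(fit_apc_model(observations, oc, volumetric = FALSE,
                           variant = "dti"),
             error = function(e) e)
  })
}

#' Longitudinal paramagnetic-rim-lesion analysis
#'
#' Counts, per treatment group, subjects whose PRL count ever increases
#' (new PRLs) or decreases (resolving PRLs), and tests the between-group
#' difference in longitudinal PRL-count change via a linear mixed model on
#' counts with a treatment-by-time interaction and random intercepts.
#'
#' @param observations MRI table with `group` and `prl_count`.
#' @return object of class `prl_result`: list with `counts` (data.frame
#'   `group, n, n_new, n_resolving`) and `p_interaction`.
#' @export
analyze_prl <- function(observations) {
  df <- observations[!is.na(observations$prl_count), , drop = FALSE]
  per <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$day), ]
    dd <- diff(d$prl_count)
    data.frame(patient_id = d$patient_id[1], group = d$group[1],
               new = any(dd > 0), resolving = any(dd < 0),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  counts <- do.call(rbind, lapply(split(per, per$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), n_new = sum(g$new),
               n_resolving = sum(g$resolving), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  p_int <- if (stats::var(df$prl_count) == 0) 1 else {
    d2 <- df
    d2$time_years <- d2$day / 365.25
    d2$group <- factor(d2$group, levels = c("ocrelizumab", "teriflunomide"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(prl_count ~ group * time_years + (1 | patient_id), data = d2,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ix <- "groupteriflunomide:time_years"
    se <- sqrt(V[ix, ix])
    if (!is.finite(se) || se < 1e-12) {
      if (abs(fe[[ix]]) < 1e-8) 1 else 0
    } else 2 * stats::pnorm(-abs(fe[[ix]] / se))
  }
  structure(list(counts = counts, p_interaction = p_int),
            class = "prl_result")
}

#' @export
print.prl_result <- function(x, ...) {
  print(x$counts)
  cat(sprintf("Group-by-time interaction p = %.3g\n", x$p_interaction))
  invisible(x)
}
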