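#' Simulate baseline covariates and confounded treatment assignment
#'
#' Draws per-patient baseline characteristics from marginal families matched
#' to a typical treated RRMS cohort (age ~ Normal(43.1, 12.5) truncated to
#' \[18, 80\]; 65.5% female; log-normal disease duration, sNfL and T2-lesion
#' volume with medians 9.2 y, 10.2 pg/ml and 7.4 ml; EDSS median 2.5).
#' Treatment is assigned by sampling exactly `n_per_group` ocrelizumab
#' patients without replacement with weights from a logistic model on
#' standardized covariates, whose slope scales with `confounding_strength`;
#' the latent logistic propensity is recorded as ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `patients` (data.frame) and `ground_truth` (data.frame
#'   with per-patient true propensity and, later, latent event times).
#' @export
simulate_baseline <- function(config) {
  validate_sim_config(config)
  n <- 2L * config$n_per_group
  withr::with_seed(config$seed, {
    age <- .rtruncnorm(n, .truncnorm_location(43.1, 12.5, 18, 80), 12.5, 18, 80)
    sex <- ifelse(stats::runif(n) < 0.655, "F", "M")
    disease_duration <- stats::rlnorm(n, log(9.2), 1.0)
    n_prior_dmts <- stats::rpois(n, 1.5)
    t2_volume <- stats::rlnorm(n, log(7.4), 1.0)
    t2_count <- pmax(1L, as.integer(round(stats::rlnorm(n, log(32), 0.45))))
    snfl <- stats::rlnorm(n, log(10.2), 0.5)
    snfl_z <- stats::rnorm(n, 0.8, 1.3)
    edss <- snap_edss(stats::rnorm(n, 2.5, 1.5))
    time_under <- stats::rexp(n, log(2) / 2.2)

    # confounded assignment: older, longer-duration, higher-EDSS patients
    # lean towards teriflunomide; high sNfL/T2 burden towards ocrelizumab
    lp <- config$confounding_strength *
      (0.5 * scale(age)[, 1] + 0.3 * scale(disease_duration)[, 1] +
         0.3 * scale(edss)[, 1] - 0.4 * scale(log(snfl))[, 1] -
         0.3 * scale(log(t2_volume))[, 1] + 0.2 * (sex == "M"))
    p_teri <- stats::plogis(lp)
    w <- if (config$confounding_strength == 0) rep(1, n) else p_teri
    teri_idx <- sample.int(n, config$n_per_group, prob = w)
    group <- rep("ocrelizumab", n)
    group[teri_idx] <- "teriflunomide"

    med <- config$followup_median_years[group]
    fup_years <- pmin(stats::runif(n, 0.5, pmax(2 * med - 0.5, 0.6)),
                      config$followup_max_years)
    last_visit_day <- round(fup_years * 365.25)
    disc <- if (config$dropout_rate > 0)
      stats::rexp(n, config$dropout_rate) else rep(Inf, n)
    discontinuation_day <- ifelse(disc * 365.25 < last_visit_day,
                                  round(disc * 365.25), NA_real_)

    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      group = group,
      age = round(age, 1),
      sex = sex,
      disease_duration_years = round(disease_duration, 2),
      n_prior_dmts = n_prior_dmts,
      t2_count = t2_count,
      t2_volume_ml = round(t2_volume, 2),
      snfl_pg_ml = round(snfl, 2),
      snfl_z = round(snfl_z, 2),
      edss_baseline = edss,
      time_under_treatment_years = round(time_under, 2),
      discontinuation_day = discontinuation_day,
      last_visit_day = last_visit_day,
      stringsAsFactors = FALSE)
    ground_truth <- data.frame(
      patient_id = patients$patient_id,
      group = group,
      true_propensity = p_teri,
      stringsAsFactors = FALSE)
    list(patients = patients, ground_truth = ground_truth)
  })
}

# location parameter giving a truncated-normal mean equal to `target`
.truncnorm_location <- function(target, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 c(target - 3 * sd, target + 3 * sd), tol = 1e-8)$root
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.jitter_grid <- function(end_day, interval, jitter) {
  days <- 0
  d <- 0
  repeat {
    d <- d + interval + stats::runif(1, -jitter, jitter)
    if (d > end_day) break
    days <- c(days, round(d))
  }
  unique(days)
}

#' Simulate the clinical stream: EDSS visits and relapses
#'
#' Visits fall on a jittered annual grid from day 0 to the end of
#' observation. Relapses follow a homogeneous Poisson process. The latent
#' EDSS trajectory is baseline EDSS plus transient relapse bumps (0.5-1.5
#' points decaying linearly over 90 days, leaving a permanent +0.5 residual
#' with probability `relapse_residual_prob`) plus a permanent
#' relapse-independent progression step at a latent onset time drawn from an
#' exponential distribution whose hazard is `baseline_pira_rate` in the
#' ocrelizumab arm times `true_pira_hazard_ratio` in the teriflunomide arm.
#' The progression step size equals the worsening threshold at the
#' pre-progression disability level. Observed EDSS is snapped to valid steps
#' and capped at 10.
#'
#' @param baseline output of [simulate_baseline()].
#' @param config a [sim_config()].
#' @return list with `visits`, `relapses` and the augmented `ground_truth`
#'   (adds `true_onset_day`, the latent PIRA onset, possibly beyond
#'   follow-up).
#' @export
simulate_clinical_stream <- function(baseline, config) {
  patients <- baseline$patients
  n <- nrow(patients)
  withr::with_seed(config$seed + 1L, {
    hr <- ifelse(patients$group == "teriflunomide",
                 config$true_pira_hazard_ratio, 1)
    rate <- config$baseline_pira_rate * hr
    onset_years <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
    onset_day <- ifelse(is.finite(onset_years), round(onset_years * 365.25), Inf)

    visits <- vector("list", n)
    relapses <- vector("list", n)
    for (i in seq_len(n)) {
      end_day <- min(patients$last_visit_day[i],
                     patients$discontinuation_day[i], na.rm = TRUE)
      vdays <- .jitter_grid(end_day, config$visit_interval_days,
                            config$visit_jitter_days)
      nrel <- stats::rpois(1, config$relapse_rate * end_day / 365.25)
      rdays <- sort(unique(round(stats::runif(nrel, 1, max(end_day, 1)))))
      bump <- if (length(rdays)) sample(c(0.5, 1, 1.5), length(rdays),
                                        replace = TRUE) else numeric(0)
      resid <- if (length(rdays))
        0.5 * (stats::runif(length(rdays)) < config$relapse_residual_prob)
      else numeric(0)

      base <- patients$edss_baseline[i]
      level_at <- function(d) {  # permanent components only
        base + sum(resid[rdays <= d])
      }
      step <- if (is.finite(onset_day[i]) && onset_day[i] <= end_day) {
        min_increase_for(snap_edss(level_at(onset_day[i])))
      } else 0
      edss_raw <- vapply(vdays, function(d) {
        tr <- 0
        if (length(rdays)) {
          act <- d >= rdays & d < rdays + 90
          tr <- sum(bump[act] * (1 - (d - rdays[act]) / 90))
        }
        lvl <- level_at(d) + tr
        if (is.finite(onset_day[i]) && d >= onset_day[i]) lvl <- lvl + step
        lvl
      }, numeric(1))
      visits[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                day = vdays, edss = snap_edss(edss_raw),
                                stringsAsFactors = FALSE)
      relapses[[i]] <- if (length(rdays))
        data.frame(patient_id = patients$patient_id[i], day = rdays,
                   stringsAsFactors = FALSE) else NULL
    }
    gt <- baseline$ground_truth
    gt$true_onset_day <- ifelse(is.finite(onset_day), onset_day, NA_real_)
    list(visits = do.call(rbind, visits),
         relapses = {
           r <- do.call(rbind, relapses)
           if (is.null(r)) data.frame(patient_id = character(0),
                                      day = numeric(0)) else r
         },
         ground_truth = gt)
  })
}

#' Simulate the MRI stream
#'
#' Scans fall on a jittered annual grid starting at day 0. Every scan carries
#' a new/enlarged-T2 flag (more likely when a relapse occurred since the
#' previous scan). Volumetric, DTI and PRL metric blocks are carried only by
#' seeded per-group sub-cohorts (`mri_cohort_sizes`), emulating
#' availability-driven endpoint cohorts. Volumes decay exponentially at the
#' group's true annualized percentage change with multiplicative log-normal
#' measurement noise; TIV and field strength are fixed per patient; DTI
#' region means drift linearly; PRL counts are non-decreasing integer paths.
#'
#' @param baseline output of [simulate_baseline()].
#' @param clinical output of [simulate_clinical_stream()] (relapse days drive
#'   the new-T2 flag).
#' @param config a [sim_config()].
#' @return data.frame in the `mri.csv` column layout.
#' @export
simulate_mri_stream <- function(baseline, clinical, config) {
  patients <- baseline$patients
  n <- nrow(patients)
  withr::with_seed(config$seed + 2L, {
    sub <- lapply(c(volumetric = "volumetric", dti = "dti", prl = "prl"),
                  function(k) {
                    sz <- min(config$mri_cohort_sizes[[k]], config$n_per_group)
                    unlist(lapply(split(patients$patient_id, patients$group),
                                  function(ids) sample(ids, sz)))
                  })
    rows <- vector("list", n)
    apc <- config$true_apc
    drift <- config$dti_drift
    dti_base <- c(fa_wml = 0.30, fa_nawm = 0.38, fa_cortex = 0.17,
                  md_wml = 0.00113, md_nawm = 0.00074, md_cortex = 0.00091,
                  rd_wml = 0.00095, rd_nawm = 0.00058, rd_cortex = 0.00083,
                  ad_wml = 0.00149, ad_nawm = 0.00106, ad_cortex = 0.00106)
    for (i in seq_len(n)) {
      pid <- patients$patient_id[i]
      grp <- patients$group[i]
      end_day <- min(patients$last_visit_day[i],
                     patients$discontinuation_day[i], na.rm = TRUE)
      sdays <- .jitter_grid(end_day, config$mri_interval_days,
                            config$mri_jitter_days)
      m <- length(sdays)
      t_years <- sdays / 365.25
      fs <- sample(c(3, 1.5), 1, prob = c(0.8, 0.2))
      tiv <- stats::rnorm(1, 1450, 120)

      rdays <- clinical$relapses$day[clinical$relapses$patient_id == pid]
      prev <- c(-Inf, sdays[-m])
      rel_in <- vapply(seq_len(m), function(k)
        any(rdays > prev[k] & rdays <= sdays[k]), logical(1))
      dt <- pmax(sdays - pmax(prev, 0), 0) / 365.25
      p_t2 <- ifelse(rel_in, config$new_t2_relapse_prob,
                     1 - exp(-config$new_t2_rate * dt))
      new_t2 <- as.integer(stats::runif(m) < p_t2)

      row <- data.frame(patient_id = pid, day = sdays, field_strength = fs,
                        tiv_ml = round(tiv, 1), stringsAsFactors = FALSE)
      volcols <- c(brain = "brain_ml", cortex = "cortex_ml",
                   thalamus = "thalamus_ml", gm = "gm_ml")
      if (pid %in% sub$volumetric) {
        frac0 <- c(brain = stats::rnorm(1, 0.69, 0.025),
                   cortex = stats::rnorm(1, 0.31, 0.015),
                   thalamus = stats::rnorm(1, 0.0105, 0.001),
                   gm = stats::rnorm(1, 0.405, 0.02))
        for (v in names(volcols)) {
          v0 <- frac0[[v]] * tiv
          noise <- stats::rnorm(m, 0, config$measurement_sd[["volume"]])
          row[[volcols[[v]]]] <-
            round(v0 * (1 + apc[[grp]][[v]] / 100)^t_years * exp(noise), 3)
        }
      } else {
        for (v in volcols) row[[v]] <- NA_real_
      }
      if (pid %in% sub$dti) {
        for (o in dti_outcomes()) {
          noise <- stats::rnorm(m, 0, config$measurement_sd[["dti"]])
          val <- dti_base[[o]] * stats::rlnorm(1, 0, 0.06) *
            (1 + drift[[o]] / 100 * t_years) * exp(noise)
          if (startsWith(o, "fa")) val <- pmin(val, 0.999)
          row[[o]] <- signif(val, 6)
        }
      } else {
        for (o in dti_outcomes()) row[[o]] <- NA_real_
      }
      if (pid %in% sub$prl) {
        new_prl <- stats::rpois(m, config$prl_new_prob * dt)
        row$prl_count <- stats::rpois(1, 1.2) + cumsum(new_prl)
      } else {
        row$prl_count <- NA_integer_
      }
      row$new_t2_flag <- new_t2
      rows[[i]] <- row
    }
    out <- do.call(rbind, rows)
    cols <- c("patient_id", "day", "field_strength", "tiv_ml", "brain_ml",
              "cortex_ml", "thalamus_ml", "gm_ml",
              paste0("fa_", c("wml", "nawm", "cortex")),
              paste0("md_", c("wml", "nawm", "cortex")),
              paste0("rd_", c("wml", "nawm", "cortex")),
              paste0("ad_", c("wml", "nawm", "cortex")),
              "prl_count", "new_t2_flag")
    rownames(out) <- NULL
    out[, cols]
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [simulate_baseline()],
#' [simulate_clinical_stream()] and [simulate_mri_stream()].
#'
#' @param config a [sim_config()].
#' @return list with `patients`, `visits`, `relapses`, `mri`,
#'   `ground_truth`, and the `config` used.
#' @export
simulate_cohort <- function(config = sim_config()) {
  bl <- simulate_baseline(config)
  cl <- simulate_clinical_stream(bl, config)
  mri <- simulate_mri_stream(bl, cl, config)
  list(patients = bl$patients, visits = cl$visits, relapses = cl$relapses,
       mri = mri, ground_truth = cl$ground_truth, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits `patients.csv`, `visits.csv`, `relapses.csv`, `mri.csv` and
#' `ground_truth.json` (config echo plus per-patient truths) in UTF-8 CSV
#' with header rows; missing values are empty strings. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort output of [simulate_cohort()].
#' @param out_dir directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             visits = file.path(out_dir, "visits.csv"),
             relapses = file.path(out_dir, "relapses.csv"),
             mri = file.path(out_dir, "mri.csv"))
  for (nm in names(paths)) {
    utils::write.csv(cohort[[nm]], paths[[nm]], row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  gt_path <- file.path(out_dir, "ground_truth.json")
  gt <- list(config = unclass(cohort$config),
             true_pira_hazard_ratio = cohort$config$true_pira_hazard_ratio,
             true_apc = lapply(cohort$config$true_apc, as.list),
             patients = cohort$ground_truth)
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(c(paths, ground_truth = gt_path))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the canonical CSV tables.
#' @return list with `patients`, `visits`, `relapses`, `mri` and (when
#'   present) `ground_truth` parsed from JSON.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), na.strings = "",
                                    stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  out <- list(patients = rd("patients.csv"), visits = rd("visits.csv"),
              relapses = rd("relapses.csv"), mri = rd("mri.csv"))
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$ground_truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  out
}
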