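#' Monte-Carlo recovery and calibration experiment for the Cox comparison
#'
#' Simulates exponentially distributed relapse-independent progression times
#' (ocrelizumab hazard `baseline_rate`, teriflunomide hazard scaled by
#' `hazard_ratio`) with uniform censoring, fits [fit_cox()] per replicate,
#' and summarizes estimation and inference quality: 95% CI coverage of the
#' true hazard ratio, the two-sided rejection rate at alpha = 0.05 (the
#' type-I error when `hazard_ratio = 1`), and the mean log hazard-ratio
#' estimate.
#'
#' @param n_per_group subjects per arm per replicate.
#' @param hazard_ratio true teriflunomide vs ocrelizumab hazard ratio.
#' @param reps number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param baseline_rate ocrelizumab hazard, events/person-year.
#' @param censor_range uniform censoring-time range, years.
#' @return list with `coverage`, `rejection_rate`, `mean_hr`, `reps`,
#'   `n_per_group`, `true_hr`.
#' @export
mc_cox_experiment <- function(n_per_group = 500, hazard_ratio = 0.8,
                              reps = 500, seed = 1L, baseline_rate = 0.06,
                              censor_range = c(0.5, 5.7)) {
  cover <- reject <- logical(reps)
  loghr <- numeric(reps)
  for (r in seq_len(reps)) {
    withr::with_seed(seed + r, {
      n <- 2L * n_per_group
      grp <- rep(c("ocrelizumab", "teriflunomide"), each = n_per_group)
      rate <- baseline_rate * ifelse(grp == "teriflunomide", hazard_ratio, 1)
      t_ev <- stats::rexp(n, rate)
      cen <- stats::runif(n, censor_range[1], censor_range[2])
      rec <- data.frame(patient_id = as.character(seq_len(n)), group = grp,
                        time_years = pmin(t_ev, cen),
                        event = as.integer(t_ev <= cen),
                        censor_reason = "", stringsAsFactors = FALSE)
      fit <- fit_cox(rec)
      cover[r] <- fit$ci_low <= hazard_ratio & hazard_ratio <= fit$ci_high
      reject[r] <- fit$p_value < 0.05
      loghr[r] <- log(fit$hazard_ratio)
    })
  }
  list(coverage = mean(cover), rejection_rate = mean(reject),
       mean_hr = exp(mean(loghr)), reps = reps, n_per_group = n_per_group,
       true_hr = hazard_ratio)
}

#' Monte-Carlo recovery experiment for annualized percentage change
#'
#' Repeatedly simulates the volumetric arm of the synthetic cohort at its
#' default truth (total-brain APC -1.06 %/year under ocrelizumab, -0.80
#' under teriflunomide) and refits the mixed-effects APC model, returning
#' per-group mean estimates, Monte-Carlo standard errors of those means, and
#' 95% CI coverage of the truth.
#'
#' @param n_per_group patients per arm (default 72, the atrophy cohort
#'   size).
#' @param reps replicates.
#' @param seed base seed; replicate r simulates with `seed + r`.
#' @param outcome volumetric outcome (`"brain"`, `"cortex"`, `"thalamus"`,
#'   `"gm"`).
#' @return list with `truth`, `mean_apc`, `mc_se`, `coverage` (all named by
#'   group), and `reps`.
#' @export
mc_apc_experiment <- function(n_per_group = 72, reps = 400, seed = 1L,
                              outcome = "brain") {
  col <- paste0(outcome, "_ml")
  est <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("ocrelizumab",
                                                           "teriflunomide")))
  cover <- matrix(NA, reps, 2, dimnames = dimnames(est))
  truth <- c(ocrelizumab = NA_real_, teriflunomide = NA_real_)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_per_group = n_per_group, seed = seed + r,
                      mri_cohort_sizes = c(volumetric = n_per_group,
                                           dti = 2, prl = 2))
    truth <- vapply(cfg$true_apc, `[[`, numeric(1), outcome)[colnames(est)]
    bl <- simulate_baseline(cfg)
    mri <- simulate_mri_stream(
      bl, list(relapses = data.frame(patient_id = character(0),
                                     day = numeric(0))), cfg)
    obs <- merge(mri, bl$patients[, c("patient_id", "group")],
                 by = "patient_id")
    fit <- fit_apc_model(obs, col)
    a <- fit$apc
    for (g in colnames(est)) {
      row <- a[a$group == g, ]
      est[r, g] <- row$apc
      cover[r, g] <- row$ci_low <= truth[[g]] & truth[[g]] <= row$ci_high
    }
  }
  list(truth = truth, mean_apc = colMeans(est),
       mc_se = apply(est, 2, stats::sd) / sqrt(reps),
       coverage = colMeans(cover), reps = reps)
}

#' Monte-Carlo balance-improvement experiment for propensity matching
#'
#' Under confounded treatment assignment, checks per replicate whether the
#' mean absolute standardized mean difference across the ten matching
#' covariates decreases from the full cohort to the 1:1 matched cohort.
#'
#' @param n_per_group patients per arm per replicate.
#' @param reps replicates.
#' @param seed base seed.
#' @param confounding_strength passed to [sim_config()]; must be positive
#'   for the experiment to be meaningful.
#' @return list with `improved_fraction`, `mean_pre`, `mean_post`, `reps`.
#' @export
mc_matching_experiment <- function(n_per_group = 500, reps = 100, seed = 1L,
                                   confounding_strength = 0.8) {
  pre <- post <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- simulate_baseline(sim_config(n_per_group = n_per_group,
                                       seed = seed + r,
                                       confounding_strength = confounding_strength))
    pre[r] <- mean_abs_smd(co$patients)
    pm <- fit_propensity(co$patients)
    pairs <- match_1to1(pm, seed = seed + r)
    matched <- co$patients[co$patients$patient_id %in%
                             c(pairs$teri_id, pairs$ocre_id), ]
    post[r] <- mean_abs_smd(matched)
  }
  list(improved_fraction = mean(post < pre), mean_pre = mean(pre),
       mean_post = mean(post), reps = reps)
}
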