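mkrec <- function(time, event, group, id = sprintf("P%02d", seq_along(time))) {
  data.frame(patient_id = id, group = group, time_years = time,
             event = as.integer(event), censor_reason = "", stringsAsFactors = FALSE)
}

test_that("identical record sets in both arms give HR exactly 1", {
  base <- mkrec(c(1, 2, 3, 4), c(1, 1, 0, 1), rep("ocrelizumab", 4))
  twin <- base
  twin$group <- "teriflunomide"
  twin$patient_id <- paste0(base$patient_id, "t")
  r <- fit_cox(rbind(base, twin))
  expect_equal(r$hazard_ratio, 1, tolerance = 1e-8)
  expect_equal(r$n_events, 6L)
})

test_that("Cox estimate equals brute-force partial-likelihood maximization", {
  rec <- mkrec(c(1, 2, 3, 4), c(1, 1, 1, 0),
               c("ocrelizumab", "teriflunomide", "ocrelizumab", "teriflunomide"))
  r <- fit_cox(rec)
  b_oracle <- oracle_cox_loghr(rec$time_years, rec$event,
                               as.integer(rec$group == "teriflunomide"))
  expect_equal(log(r$hazard_ratio), b_oracle, tolerance = 1e-6)
  # a second, larger tie-free fixture
  set.seed(4)
  rec2 <- mkrec(sort(runif(12, 0.1, 5)), rbinom(12, 1, 0.7),
                sample(c("ocrelizumab", "teriflunomide"), 12, replace = TRUE))
  rec2$event[c(1, 12)] <- 1L  # both arms need events
  r2 <- fit_cox(rec2)
  b2 <- oracle_cox_loghr(rec2$time_years, rec2$event,
                         as.integer(rec2$group == "teriflunomide"))
  expect_equal(log(r2$hazard_ratio), b2, tolerance = 1e-6)
})

test_that("label swap inverts the hazard ratio and preserves the p-value", {
  set.seed(5)
  rec <- mkrec(runif(40, 0.1, 5), rbinom(40, 1, 0.6),
               rep(c("ocrelizumab", "teriflunomide"), 20))
  sw <- rec
  sw$group <- ifelse(rec$group == "ocrelizumab", "teriflunomide", "ocrelizumab")
  a <- fit_cox(rec); b <- fit_cox(sw)
  expect_equal(a$hazard_ratio, 1 / b$hazard_ratio, tolerance = 1e-8)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
})

test_that("Cox estimate is invariant to rescaling time", {
  set.seed(6)
  rec <- mkrec(runif(40, 0.1, 5), rbinom(40, 1, 0.6),
               rep(c("ocrelizumab", "teriflunomide"), 20))
  sc <- rec
  sc$time_years <- sc$time_years * 7.3
  expect_equal(fit_cox(rec)$hazard_ratio, fit_cox(sc)$hazard_ratio,
               tolerance = 1e-8)
})

test_that("degenerate event patterns raise named errors", {
  expect_error(fit_cox(mkrec(1:4, 0, rep(c("ocrelizumab", "teriflunomide"), 2))),
               "no progression events")
  expect_error(fit_cox(mkrec(1:4, c(1, 1, 0, 0),
                             c("ocrelizumab", "ocrelizumab",
                               "teriflunomide", "teriflunomide"))),
               "one arm")
})

test_that("KM is the hand product-limit estimator and respects its invariants", {
  rec <- mkrec(c(1, 1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1, 0),
               rep("ocrelizumab", 7))
  km <- km_estimate(rec)
  want <- oracle_km(rec$time_years, rec$event)
  got <- km[km$n_event > 0, ]
  expect_equal(got$time_years, want$time)
  expect_equal(got$survival, want$surv, tolerance = 1e-12)
  expect_equal(km$survival[km$time_years == 0], 1)
  expect_true(all(diff(km$survival) <= 1e-12))
  # no events: survival stays at 1
  km0 <- km_estimate(mkrec(1:5, 0, rep("ocrelizumab", 5)))
  expect_true(all(km0$survival == 1))
  # distinct event times, no censoring: empirical survival function
  rec2 <- mkrec(1:6, 1, rep("teriflunomide", 6))
  km2 <- km_estimate(rec2)
  expect_equal(km2$survival[km2$n_event > 0], (5:0) / 6, tolerance = 1e-12)
})

test_that("pairwise censoring equalizes follow-up within pairs", {
  rec <- mkrec(c(3.1, 1.9, 2.5, 3.0), c(0, 0, 1, 0),
               c("teriflunomide", "ocrelizumab", "teriflunomide", "ocrelizumab"),
               id = c("T1", "O1", "T2", "O2"))
  pairs <- data.frame(teri_id = c("T1", "T2"), ocre_id = c("O1", "O2"))
  out <- pairwise_censor(rec, pairs)
  expect_equal(out$time_years, c(1.9, 1.9, 2.5, 2.5))
  expect_equal(out$event, c(0L, 0L, 1L, 0L))
  expect_equal(out$censor_reason[1], "pairwise")
  # event after the partner's censoring time becomes a censoring
  rec2 <- mkrec(c(2.5, 1.9), c(1, 0), c("teriflunomide", "ocrelizumab"),
                id = c("T1", "O1"))
  out2 <- pairwise_censor(rec2, data.frame(teri_id = "T1", ocre_id = "O1"))
  expect_equal(out2$time_years, c(1.9, 1.9))
  expect_equal(out2$event, c(0L, 0L))
  expect_error(pairwise_censor(rbind(rec2, mkrec(1, 0, "ocrelizumab", "X")),
                               data.frame(teri_id = "T1", ocre_id = "O1")),
               "paired")
})

test_that("the endpoint suite emits four labelled analyses with expected identities", {
  co <- simulate_cohort(sim_config(n_per_group = 60, seed = 31,
                                   new_t2_rate = 0, new_t2_relapse_prob = 0))
  ev <- detect_events(co$visits, co$relapses,
                      co$mri[, c("patient_id", "day", "new_t2_flag")])
  pm <- fit_propensity(co$patients)
  pairs <- match_1to1(pm, seed = 31)
  suite <- run_endpoint_suite(co$patients, ev, pairs)
  expect_named(suite, c("primary", "pairwise_censored", "onset_filtered", "pirma"))
  # simulation has no pre-baseline onsets: onset filter changes nothing
  expect_equal(suite$primary$hazard_ratio, suite$onset_filtered$hazard_ratio)
  # new_t2 never set: PIRA and PIRMA agree up to indeterminate windows
  expect_false(any(ev$is_pirma %in% FALSE))
  expect_lte(suite$pirma$n_events, suite$primary$n_events)
})

test_that("the detector-to-Cox chain recovers the true hazard ratio with symmetric follow-up", {
  # full chain: latent exponential onsets -> EDSS trajectories -> sequential
  # detection -> survival records -> Cox; equal follow-up keeps event
  # ascertainment symmetric across arms
  reps <- 60
  lhr <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_per_group = 250, seed = 3000 + r,
                      baseline_pira_rate = 0.08, relapse_rate = 0,
                      dropout_rate = 0,
                      followup_median_years = c(ocrelizumab = 3,
                                                teriflunomide = 3),
                      mri_cohort_sizes = c(volumetric = 2, dti = 2, prl = 2))
    bl <- simulate_baseline(cfg)
    cl <- simulate_clinical_stream(bl, cfg)
    ev <- detect_events(cl$visits, cl$relapses)
    rec <- build_survival_records(bl$patients, ev)
    lhr[r] <- log(fit_cox(rec)$hazard_ratio)
  }
  mc_se <- sd(lhr) / sqrt(reps)
  expect_lt(abs(mean(lhr) - log(0.8)), 3 * mc_se)
})
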