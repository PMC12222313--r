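tv <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(day = m[, 1], edss = m[, 2])
}

test_that("a sustained one-point increase confirmed at six months is detected", {
  ev <- detect_confirmed_worsening(tv(0, 2.0, 200, 3.0, 400, 3.0))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_day, 200)
  expect_equal(ev$confirmation_day, 400)
  expect_equal(ev$reference_edss, 2.0)
  expect_equal(ev$onset_edss, 3.0)
})

test_that("sub-threshold increases are not events", {
  expect_equal(nrow(detect_confirmed_worsening(tv(0, 2.0, 200, 2.5, 400, 2.5))), 0L)
  # from reference 0 a 1.0-point increase is below the 1.5 threshold
  expect_equal(nrow(detect_confirmed_worsening(tv(0, 0, 200, 1.0, 400, 1.0))), 0L)
  # from reference 6.0 half a point suffices
  ev <- detect_confirmed_worsening(tv(0, 6.0, 200, 6.5, 400, 6.5))
  expect_equal(nrow(ev), 1L)
})

test_that("a confirmed improvement re-baselines the roving reference", {
  ev <- detect_confirmed_worsening(
    tv(0, 3.0, 180, 2.0, 370, 2.0, 600, 3.0, 790, 3.0))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_day, 600)
  expect_equal(ev$confirmation_day, 790)
  expect_equal(ev$reference_edss, 2.0)
  expect_equal(ev$reference_day, 370)
})

test_that("worsening must be sustained at intervening visits by default", {
  # a dip below threshold before the 180-day confirming visit kills the
  # first candidate; the later sustained increase becomes the event instead
  v <- tv(0, 2.0, 200, 3.0, 300, 2.0, 400, 3.0, 600, 3.0)
  ev_s <- detect_confirmed_worsening(v)
  expect_equal(ev_s$onset_day, 400)
  ev <- detect_confirmed_worsening(v, sustained = FALSE)
  expect_equal(ev$onset_day, 200)
  # a dip that persists to the end leaves no event at all
  v2 <- tv(0, 2.0, 200, 3.0, 300, 2.0, 500, 2.0)
  expect_equal(nrow(detect_confirmed_worsening(v2)), 0L)
})

test_that("the reference moves to the confirmation visit after an event", {
  ev <- detect_confirmed_worsening(
    tv(0, 2.0, 200, 3.0, 400, 3.0, 600, 4.0, 800, 4.0))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$reference_edss, c(2.0, 3.0))
  expect_equal(ev$reference_day, c(0, 400))
})

test_that("unconfirmable or invalid streams are handled", {
  expect_equal(nrow(detect_confirmed_worsening(tv(0, 2.0, 100, 3.0))), 0L)
  expect_error(detect_confirmed_worsening(tv(0, 2.0, 0, 3.0)), "duplicate")
  expect_error(detect_confirmed_worsening(tv(200, 2.0, 0, 3.0)), "sorted")
  expect_error(detect_confirmed_worsening(tv(0, 2.3, 200, 3.3)), "invalid EDSS")
})

test_that("sequential detector matches the exhaustive oracle on random trajectories", {
  set.seed(7)
  for (rep in 1:2000) {
    tr <- random_trajectory()
    got <- detect_confirmed_worsening(data.frame(day = tr$day, edss = tr$edss))
    want <- oracle_detect(tr$day, tr$edss)
    expect_identical(unname(as.matrix(got)), unname(as.matrix(want)),
                     label = paste("trajectory", rep))
  }
})

test_that("threshold soundness holds for every emitted event", {
  set.seed(11)
  for (rep in 1:300) {
    tr <- random_trajectory()
    ev <- detect_confirmed_worsening(data.frame(day = tr$day, edss = tr$edss))
    if (!nrow(ev)) next
    expect_true(all(ev$onset_edss - ev$reference_edss >=
                      min_increase_for(ev$reference_edss)))
    expect_true(all(ev$confirmation_day - ev$onset_day >= 180))
  }
})

test_that("relapse windows exclude events from PIRA on both sides", {
  v <- tv(0, 2.0, 200, 3.0, 400, 3.0)
  ev <- detect_confirmed_worsening(v)
  # relapse between the pre-onset anchor and onset
  expect_false(classify_pira(ev, v, relapse_days = 150)$is_pira)
  # relapse between onset and confirmation
  expect_false(classify_pira(ev, v, relapse_days = 300)$is_pira)
  # no relapses at all
  expect_true(classify_pira(ev, v, relapse_days = numeric(0))$is_pira)
  # relapse outside the closed window
  expect_true(classify_pira(ev, v, relapse_days = 401)$is_pira)
  expect_false(classify_pira(ev, v, relapse_days = 400)$is_pira)  # boundary
})

test_that("anchor falls back to the earliest visit when none precedes onset by 90 days", {
  v <- tv(0, 2.0, 50, 3.0, 250, 3.0)
  ev <- detect_confirmed_worsening(v)
  cl <- classify_pira(ev, v, relapse_days = numeric(0))
  expect_true(cl$anchor_fallback)
  expect_equal(cl$anchor_day, 0)
})

test_that("PIRMA uses the half-open reference-to-confirmation MRI window", {
  v <- tv(0, 2.0, 200, 3.0, 400, 3.0)
  ev <- detect_confirmed_worsening(v)
  mri <- function(day, flag) data.frame(day = day, new_t2_flag = flag)
  expect_false(classify_pirma(ev, mri(300, 1)))
  expect_true(classify_pirma(ev, mri(300, 0)))
  expect_true(is.na(classify_pirma(ev, mri(500, 1))))      # after window
  expect_true(is.na(classify_pirma(ev, mri(0, 1))))        # ref day excluded
  expect_false(classify_pirma(ev, mri(400, 1)))            # confirmation incl.
  expect_error(classify_pirma(ev, mri(300, 0), is_pira = FALSE), "PIRA")
})

test_that("adding a relapse or flagged scan never rescues an exclusion", {
  set.seed(13)
  for (rep in 1:200) {
    tr <- random_trajectory()
    v <- data.frame(day = tr$day, edss = tr$edss)
    ev <- detect_confirmed_worsening(v)
    if (!nrow(ev)) next
    base_pira <- classify_pira(ev[1, ], v, tr$relapses)$is_pira
    more <- c(tr$relapses, sample.int(max(tr$day), 1))
    expect_true(classify_pira(ev[1, ], v, more)$is_pira <= base_pira)
    scans <- data.frame(day = sample.int(max(tr$day), 2), new_t2_flag = 0)
    base_pirma <- classify_pirma(ev[1, ], scans)
    scans2 <- rbind(scans, data.frame(day = ev$confirmation_day[1], new_t2_flag = 1))
    expect_false(isTRUE(classify_pirma(ev[1, ], scans2)) && isFALSE(base_pirma))
  }
})

test_that("cohort detection is independent of input row order", {
  set.seed(17)
  co <- simulate_cohort(sim_config(n_per_group = 30, seed = 5))
  mri <- co$mri[, c("patient_id", "day", "new_t2_flag")]
  a <- detect_events(co$visits, co$relapses, mri)
  perm <- sample(nrow(co$visits))
  b <- detect_events(co$visits[perm, ], co$relapses, mri)
  rownames(b) <- NULL
  expect_equal(a, b)
  expect_error(detect_events(rbind(co$visits, co$visits[1, ]), co$relapses),
               "duplicate")
})

test_that("survival records encode censoring, event timing and the onset filter", {
  pats <- data.frame(patient_id = c("A", "B", "C"),
                     group = c("teriflunomide", "ocrelizumab", "teriflunomide"),
                     discontinuation_day = c(NA, NA, 500),
                     last_visit_day = c(1132, 900, 900))
  ev <- data.frame(patient_id = c("B", "C"),
                   onset_day = c(365.25, -30), confirmation_day = c(550, 200),
                   reference_edss = 2, reference_day = c(0, -200),
                   onset_edss = 3, is_pira = TRUE, is_pirma = NA,
                   anchor_fallback = FALSE)
  rec <- build_survival_records(pats, ev, endpoint = "pira")
  expect_equal(rec$time_years[rec$patient_id == "A"], 1132 / 365.25)
  expect_equal(rec$event[rec$patient_id == "A"], 0L)
  expect_equal(rec$censor_reason[rec$patient_id == "A"], "last_visit")
  expect_equal(rec$time_years[rec$patient_id == "B"], 1.0)
  expect_equal(rec$event[rec$patient_id == "B"], 1L)
  # pre-treatment onset: clamped to 0 when the filter is off ...
  expect_equal(rec$time_years[rec$patient_id == "C"], 0)
  expect_equal(rec$event[rec$patient_id == "C"], 1L)
  # ... censored at discontinuation when the filter is on
  rec2 <- build_survival_records(pats, ev, endpoint = "pira", onset_filter = TRUE)
  expect_equal(rec2$event[rec2$patient_id == "C"], 0L)
  expect_equal(rec2$time_years[rec2$patient_id == "C"], 500 / 365.25)
  expect_equal(rec2$censor_reason[rec2$patient_id == "C"], "discontinuation")
})

test_that("indeterminate PIRMA events censor by default but can count as events", {
  pats <- data.frame(patient_id = "A", group = "teriflunomide",
                     discontinuation_day = NA, last_visit_day = 800)
  ev <- data.frame(patient_id = "A", onset_day = 400, confirmation_day = 600,
                   reference_edss = 2, reference_day = 0, onset_edss = 3,
                   is_pira = TRUE, is_pirma = NA, anchor_fallback = FALSE)
  rec <- build_survival_records(pats, ev, endpoint = "pirma")
  expect_equal(rec$event, 0L)
  rec2 <- build_survival_records(pats, ev, endpoint = "pirma",
                                 indeterminate_as_event = TRUE)
  expect_equal(rec2$event, 1L)
})
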