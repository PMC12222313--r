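#' Detect confirmed EDSS worsening with a roving baseline
#'
#' Scans a single patient's EDSS visit stream chronologically, maintaining a
#' roving reference. A visit is a candidate worsening onset when its EDSS
#' exceeds the reference by at least [min_increase_for()] of the reference; it
#' is confirmed at the first visit at least `confirmation_window` days later,
#' provided the increase is sustained (by default at every intervening visit
#' and the confirming visit, all judged against the same reference). After a
#' confirmed worsening the reference moves to the confirmation visit. A
#' confirmed improvement (a decrease of at least 0.5 sustained over the same
#' window) re-baselines the reference to its confirmation visit without
#' emitting an event. Events are therefore non-overlapping and chronological.
#'
#' @param visits data.frame with columns `day` (numeric, strictly increasing)
#'   and `edss` (valid EDSS steps); one patient.
#' @param confirmation_window days between onset and the earliest confirming
#'   visit (default 180, i.e. 6 months).
#' @param sustained logical; if `TRUE` (default) the threshold must hold at
#'   every visit between onset and confirmation, if `FALSE` only at the
#'   confirming visit.
#' @return data.frame with one row per confirmed worsening: `onset_day`,
#'   `confirmation_day`, `reference_edss`, `reference_day`, `onset_edss`.
#' @export
detect_confirmed_worsening <- function(visits, confirmation_window = 180,
                                       sustained = TRUE) {
  stopifnot(is.data.frame(visits), all(c("day", "edss") %in% names(visits)))
  day <- visits$day
  edss <- visits$edss
  if (is.unsorted(day, strictly = TRUE)) {
    if (anyDuplicated(day)) stop("duplicate EDSS entries on the same day")
    stop("visits must be sorted by day")
  }
  if (any(!is_valid_edss(edss))) stop("invalid EDSS step(s) in visit stream")
  n <- length(day)
  out <- list()
  if (n < 2) return(.empty_events())

  ref_i <- 1L
  i <- 2L
  while (i <= n) {
    ref <- edss[ref_i]
    thr <- min_increase_for(ref)
    if (edss[i] - ref >= thr) {
      j <- .first_confirming(day, i, confirmation_window)
      ok <- !is.na(j) && {
        idx <- if (sustained) seq.int(i + 1L, j) else j
        all(edss[idx] - ref >= thr)
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          onset_day = day[i], confirmation_day = day[j],
          reference_edss = ref, reference_day = day[ref_i],
          onset_edss = edss[i])
        ref_i <- j
        i <- j + 1L
        next
      }
    } else if (ref - edss[i] >= 0.5) {
      j <- .first_confirming(day, i, confirmation_window)
      ok <- !is.na(j) && {
        idx <- if (sustained) seq.int(i + 1L, j) else j
        all(ref - edss[idx] >= 0.5)
      }
      if (ok) {
        ref_i <- j
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(out)) return(.empty_events())
  do.call(rbind, out)
}

.first_confirming <- function(day, i, window) {
  j <- which(day - day[i] >= window & seq_along(day) > i)
  if (length(j)) j[1L] else NA_integer_
}

.empty_events <- function() {
  data.frame(onset_day = numeric(0), confirmation_day = numeric(0),
             reference_edss = numeric(0), reference_day = numeric(0),
             onset_edss = numeric(0))
}

#' Classify a confirmed worsening as PIRA
#'
#' An event is progression independent of relapse activity when no relapse
#' falls in the closed interval from the pre-onset anchor visit to the
#' confirmation visit. The anchor is the latest visit at least `pre_window`
#' days before onset; when no such visit exists the earliest visit is used and
#' the event is flagged (`anchor_fallback`).
#'
#' @param event one-row data.frame as returned by
#'   [detect_confirmed_worsening()].
#' @param visits the same patient's visit stream (`day` column used).
#' @param relapse_days numeric vector of relapse days for the patient.
#' @param pre_window days the anchor visit must precede onset by (default 90).
#' @return list with `is_pira` (logical), `anchor_day`, `anchor_fallback`.
#' @export
classify_pira <- function(event, visits, relapse_days, pre_window = 90) {
  stopifnot(nrow(event) == 1L)
  cand <- visits$day[visits$day <= event$onset_day - pre_window]
  fallback <- length(cand) == 0L
  anchor <- if (fallback) min(visits$day) else max(cand)
  hit <- any(relapse_days >= anchor & relapse_days <= event$confirmation_day)
  list(is_pira = !hit, anchor_day = anchor, anchor_fallback = fallback)
}

#' Classify a PIRA event as PIRMA
#'
#' PIRMA additionally requires freedom from new or enlarged T2-hyperintense
#' lesions on interval MRI. The MRI window is half-open:
#' `(reference_day, confirmation_day]`. Returns `FALSE` if any scan in the
#' window carries a new/enlarged-T2 flag, `TRUE` if at least one scan falls in
#' the window and none is flagged, and `NA` (indeterminate) when no scan
#' falls in the window.
#'
#' @param event one-row event (must be PIRA).
#' @param mri data.frame with `day` and `new_t2_flag` (0/1) for the patient.
#' @param is_pira logical; classification is only defined for PIRA events.
#' @return logical scalar, possibly `NA`.
#' @export
classify_pirma <- function(event, mri, is_pira = TRUE) {
  stopifnot(nrow(event) == 1L)
  if (!isTRUE(is_pira)) stop("PIRMA classification is defined only for PIRA events")
  inwin <- mri$day > event$reference_day & mri$day <= event$confirmation_day
  flags <- mri$new_t2_flag[inwin]
  flags <- flags[!is.na(flags)]
  if (!length(flags)) return(NA)
  if (any(flags == 1)) FALSE else TRUE
}

#' Detect and classify progression events for a cohort
#'
#' Runs [detect_confirmed_worsening()], [classify_pira()] and
#' [classify_pirma()] per patient over long-format visit, relapse and MRI
#' tables. Input rows may be unordered; they are sorted by patient and day.
#' Duplicate same-day EDSS entries are rejected (EDSS is ordinal and cannot
#' be averaged).
#'
#' @param visits data.frame `patient_id, day, edss`.
#' @param relapses data.frame `patient_id, day` (may be empty).
#' @param mri optional data.frame with `patient_id, day, new_t2_flag`; when
#'   `NULL` every PIRA event's PIRMA flag is indeterminate.
#' @param confirmation_window,sustained,pre_window see the per-patient
#'   functions.
#' @return data.frame `patient_id, onset_day, confirmation_day,
#'   reference_edss, reference_day, onset_edss, is_pira, is_pirma,
#'   anchor_fallback`; `is_pirma` is `NA` for non-PIRA events and for
#'   indeterminate windows.
#' @export
detect_events <- function(visits, relapses = NULL, mri = NULL,
                          confirmation_window = 180, sustained = TRUE,
                          pre_window = 90) {
  stopifnot(all(c("patient_id", "day", "edss") %in% names(visits)))
  if (anyDuplicated(visits[c("patient_id", "day")]))
    stop("duplicate EDSS entries on the same patient-day")
  visits <- visits[order(visits$patient_id, visits$day), , drop = FALSE]
  res <- lapply(split(visits, visits$patient_id), function(v) {
    ev <- detect_confirmed_worsening(v, confirmation_window, sustained)
    if (!nrow(ev)) return(NULL)
    pid <- v$patient_id[1L]
    rel <- if (is.null(relapses)) numeric(0) else
      relapses$day[relapses$patient_id == pid]
    scans <- if (is.null(mri)) NULL else
      mri[mri$patient_id == pid, c("day", "new_t2_flag"), drop = FALSE]
    ev$patient_id <- pid
    ev$is_pira <- NA
    ev$is_pirma <- NA
    ev$anchor_fallback <- NA
    for (k in seq_len(nrow(ev))) {
      cl <- classify_pira(ev[k, ], v, rel, pre_window)
      ev$is_pira[k] <- cl$is_pira
      ev$anchor_fallback[k] <- cl$anchor_fallback
      if (cl$is_pira && !is.null(scans) && nrow(scans))
        ev$is_pirma[k] <- classify_pirma(ev[k, ], scans)
    }
    ev
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- .empty_events()
    res$patient_id <- character(0)
    res$is_pira <- logical(0)
    res$is_pirma <- logical(0)
    res$anchor_fallback <- logical(0)
  }
  rownames(res) <- NULL
  cols <- c("patient_id", "onset_day", "confirmation_day", "reference_edss",
            "reference_day", "onset_edss", "is_pira", "is_pirma",
            "anchor_fallback")
  res[, cols, drop = FALSE]
}

#' Build per-patient survival records for a progression endpoint
#'
#' One record per patient: time to the first qualifying event in years
#' (onset-dated by default), or censoring at the earlier of the last visit and
#' treatment discontinuation.
#'
#' @param patients data.frame with `patient_id`, `group`,
#'   `discontinuation_day` (NA when still on treatment) and `last_visit_day`.
#' @param events output of [detect_events()].
#' @param endpoint `"pira"` or `"pirma"`. For the PIRMA endpoint,
#'   indeterminate events count as events only when
#'   `indeterminate_as_event = TRUE`; by default they are treated as
#'   censoring at the patient's censor day.
#' @param onset_filter logical; when `TRUE`, events whose initial EDSS
#'   increase predates treatment start (onset day < 0) are discarded. When
#'   `FALSE` such events are kept with time clamped to 0.
#' @param event_time date events at `"onset"` (default) or `"confirmation"`.
#' @param indeterminate_as_event see `endpoint`.
#' @return data.frame `patient_id, group, time_years, event, censor_reason`;
#'   patients absent from `patients` rows are never invented, patients with
#'   zero follow-up are kept with time 0.
#' @export
build_survival_records <- function(patients, events, endpoint = c("pira", "pirma"),
                                   onset_filter = FALSE,
                                   event_time = c("onset", "confirmation"),
                                   indeterminate_as_event = FALSE) {
  endpoint <- match.arg(endpoint)
  event_time <- match.arg(event_time)
  qual <- if (endpoint == "pira") {
    events[!is.na(events$is_pira) & events$is_pira, , drop = FALSE]
  } else {
    keep <- !is.na(events$is_pira) & events$is_pira &
      (ifelse(is.na(events$is_pirma), indeterminate_as_event, events$is_pirma))
    events[keep, , drop = FALSE]
  }
  if (onset_filter) qual <- qual[qual$onset_day >= 0, , drop = FALSE]

  censor_day <- pmin(patients$last_visit_day,
                     ifelse(is.na(patients$discontinuation_day), Inf,
                            patients$discontinuation_day))
  rec <- data.frame(
    patient_id = patients$patient_id,
    group = patients$group,
    time_years = censor_day / 365.25,
    event = 0L,
    censor_reason = ifelse(is.na(patients$discontinuation_day) |
                             patients$last_visit_day <= patients$discontinuation_day,
                           "last_visit", "discontinuation"),
    stringsAsFactors = FALSE)
  if (nrow(qual)) {
    dcol <- if (event_time == "onset") qual$onset_day else qual$confirmation_day
    first <- tapply(dcol, qual$patient_id, min)
    idx <- match(names(first), rec$patient_id)
    hit <- !is.na(idx)
    rec$time_years[idx[hit]] <- pmax(unname(first[hit]), 0) / 365.25
    rec$event[idx[hit]] <- 1L
    rec$censor_reason[idx[hit]] <- ""
  }
  rec
}
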