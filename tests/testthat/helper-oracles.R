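# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# Exhaustive-search event detector: precomputes, for every visit, its
# confirming visit, then replays the roving-reference process by scanning all
# candidate (reference, onset, confirmation) triples in chronological order.
oracle_detect <- function(day, edss, window = 180, sustained = TRUE) {
  n <- length(day)
  need <- function(rv) if (rv == 0) 1.5 else if (rv <= 5.5) 1.0 else 0.5
  conf_of <- vapply(seq_len(n), function(i) {
    js <- which(seq_len(n) > i & (day - day[i]) >= window)
    if (length(js)) min(js) else NA_integer_
  }, integer(1))
  span <- function(i, j) if (sustained) seq(i, j) else c(i, j)
  is_worsen <- function(rv, i) {
    j <- conf_of[i]
    !is.na(j) && all(edss[span(i, j)][-1] - rv >= need(rv)) &&
      (edss[i] - rv >= need(rv))
  }
  is_improve <- function(rv, i) {
    j <- conf_of[i]
    !is.na(j) && all(rv - edss[span(i, j)] >= 0.5)
  }
  ref <- 1L
  pos <- 2L
  ev <- NULL
  while (pos <= n) {
    hit <- NA
    for (i in pos:n) {
      if (edss[i] > edss[ref] && is_worsen(edss[ref], i)) { hit <- c(i, 1L); break }
      if (edss[i] < edss[ref] && is_improve(edss[ref], i)) { hit <- c(i, 2L); break }
    }
    if (anyNA(hit)) break
    i <- hit[1]
    j <- conf_of[i]
    if (hit[2] == 1L) {
      ev <- rbind(ev, data.frame(onset_day = day[i], confirmation_day = day[j],
                                 reference_edss = edss[ref],
                                 reference_day = day[ref],
                                 onset_edss = edss[i]))
    }
    ref <- j
    pos <- j + 1L
  }
  if (is.null(ev)) data.frame(onset_day = numeric(0),
                              confirmation_day = numeric(0),
                              reference_edss = numeric(0),
                              reference_day = numeric(0),
                              onset_edss = numeric(0)) else ev
}

# PIRA check written from the definition, independent of classify_pira()
oracle_pira <- function(onset_day, confirmation_day, visit_days, relapse_days,
                        pre_window = 90) {
  before <- visit_days[visit_days <= onset_day - pre_window]
  anchor <- if (length(before)) max(before) else min(visit_days)
  !any(relapse_days >= anchor & relapse_days <= confirmation_day)
}

# Random EDSS/relapse trajectory generator for the equivalence battery
random_trajectory <- function() {
  n <- sample(3:12, 1)
  day <- cumsum(c(0, sample(30:400, n - 1, replace = TRUE)))
  steps <- sample(c(-1.5, -1, -0.5, 0, 0, 0.5, 1, 1.5, 2), n - 1,
                  replace = TRUE)
  edss <- smoldercmp::snap_edss(cumsum(c(sample(c(0, 1, 1.5, 2, 2.5, 3, 4, 5.5, 6), 1),
                                         steps)))
  nrel <- stats::rpois(1, 1)
  rel <- if (nrel) sort(sample.int(max(day) + 100, nrel)) else numeric(0)
  list(day = day, edss = edss, relapses = rel)
}

# Hand-written Cox log partial likelihood (no ties), maximized by optimize()
oracle_cox_loghr <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  nlpl <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -ll
  }
  stats::optimize(nlpl, c(-10, 10), tol = 1e-10)$minimum
}

# Hand product-limit estimator at the distinct event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(xa, xb) sum(outer(xa, xb, ">"))
  u_obs <- ustat(a, b)
  u_all <- apply(idx, 2, function(k) ustat(pooled[k], pooled[-k]))
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Textbook SMD recomputation
oracle_smd <- function(a, b) {
  (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
}
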