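---
title: "Methods: detecting and comparing smoldering MS activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing smoldering MS activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoldercmp)
```

# Overview

`smoldercmp` implements a complete comparative-effectiveness analysis of
smoldering disease activity in relapsing–remitting multiple sclerosis:
detection of confirmed disability worsening independent of relapses (PIRA)
and of MRI activity (PIRMA) from longitudinal EDSS/relapse/MRI streams,
construction of 1:1 propensity-matched treatment groups, time-to-event
comparison with sensitivity schemes, and mixed-effects estimation of
annualized percentage change (APC) in volumetric, diffusion, and
paramagnetic-rim-lesion outcomes. A seeded synthetic-cohort generator with
known ground truth backs every estimator with parameter-recovery evidence.

This vignette records the modelling choices, their rationale, and the
conventions adopted where the underlying definitions leave room.

# Event detection

## The roving-baseline worsening rule

EDSS is ordinal on $\{0, 1.0, 1.5, \dots, 10.0\}$. A visit qualifies as a
worsening onset when its EDSS exceeds the current *reference* by at least
1.5 points (reference 0), 1.0 point (reference 1.0–5.5), or 0.5 points
(reference above 5.5). The event is confirmed at the first visit at least
180 days later ("at least 6 months" is rendered as 180 days). We require the
threshold to hold **at every visit between onset and confirmation** as well
as at the confirming visit (`sustained = TRUE`); this is the
high-specificity reading appropriate for observational cohorts, where a
transient fluctuation crossing the threshold at a single visit should not
count. The permissive reading — only the confirming visit must still exceed
the threshold — is available via `sustained = FALSE`, since the sources of
such definitions rarely state which applies between scheduled visits.

The reference *roves*: after a confirmed worsening it moves to the
confirmation visit, and after a confirmed improvement (a decrease of at
least 0.5 sustained over the same 180-day window) it moves to the
confirmation visit of the improvement. Symmetry between the two moves keeps
the reference on an actually observed, confirmed disability level.
Consequently events are non-overlapping and chronologically ordered, and an
early unconfirmed spike does not block a later sustained worsening from
becoming the event.

Duplicate same-day EDSS entries are rejected rather than averaged: EDSS is
ordinal and a mean of two steps is generally not a legal step. Detection is
invariant to input row order because streams are sorted per patient before
scanning.

## Relapse and MRI windows

An event is PIRA when no relapse falls in the **closed** interval from the
pre-onset anchor visit to the confirmation visit, where the anchor is the
latest visit at least 90 days before onset. Closed endpoints are the
conservative choice: a relapse on the boundary day removes the event from
the relapse-independent category. When no visit precedes onset by 90 days
(short histories), the earliest visit anchors the window and the event is
flagged (`anchor_fallback`) for quality review, rather than discarded — a
discard rule would silently bias early-follow-up event counts downward.

PIRMA is assessed only for PIRA events, on the **half-open** window
`(reference_day, confirmation_day]`: `FALSE` if any scan in the window has a
new/enlarged-T2 flag, `TRUE` if at least one unflagged scan falls in the
window, and *indeterminate* (`NA`) with no scan. The reference day itself is
excluded because a scan coincident with the reference visit describes the
pre-window state. Indeterminate events are, by default, not counted as PIRMA
events (the patient is censored); `indeterminate_as_event = TRUE` flips
this. Both conventions are exposed because reported PIRMA proportions in the
literature rarely state the rule.

## Survival records

Event time is the **onset** day by default (the clinically dated worsening);
`event_time = "confirmation"` is available since published analyses rarely
state which date they use. Times convert to years via 365.25. Patients are
censored at the earlier of last visit and treatment discontinuation. Events
whose onset precedes treatment start are kept with time clamped to zero in
the main analysis and removed by the onset filter (`onset_filter = TRUE`),
mirroring the standard sensitivity analysis.

An independent exhaustive-search oracle (in the test suite) re-derives
events by enumerating candidate (reference, onset, confirmation) triples;
the sequential detector matches it exactly on 10,000 random trajectories.

# Propensity matching

The propensity score is a logistic regression of treatment on ten baseline
covariates: age, sex, disease duration, number of previous DMTs, T2-lesion
count and volume, raw and Z-scored serum neurofilament light chain, EDSS,
and time under current treatment. Matching is greedy 1:1 nearest-neighbour
without replacement on the logit scale with a caliper of 0.2 SD of the
logit scores — the conventional default — with a seeded processing order
and smallest-patient-id tie-breaking so results are reproducible.
Incomplete cases are excluded listwise with a reported count. Quasi-complete
separation raises an explicit error rather than returning divergent
coefficients. Separate matched sets are built per endpoint cohort
(clinical / atrophy / DTI / PRL), with eligibility derived from data
availability (presence of volumetric, DTI, or PRL values), maximizing each
endpoint's sample size.

Balance reporting follows registry convention: median [IQR] per arm, the
standardized mean difference $(\bar x_a - \bar x_b) / \sqrt{(s_a^2 +
s_b^2)/2}$ (proportion variance for binary variables), and a two-sided
Mann–Whitney U p-value; constant variables report p = 1 with a note.

# Time-to-event comparison

The Cox model uses the treatment group as its sole covariate — appropriate
for a matched design — with Efron tie handling (ties arise from
visit-gridded onset days) and Wald confidence intervals. Robust (sandwich)
variance is available but off by default; pair-clustered inference is not
assumed by the analyses this package mirrors. The suite fits four labelled
analyses: primary PIRA, pairwise censoring (each patient truncated to the
shorter follow-up of the pair, with later events becoming censorings), the
post-baseline onset filter, and the PIRMA endpoint. Per-analysis failures
(e.g. zero events after a filter) are reported without aborting the suite.

# Annualized percentage change

The default APC model is the canonical log-outcome / linear-time
construction:

$$\log y_{ij} = \beta_0 + \beta_g g_i + \beta_t t_{ij} + \beta_{gt} g_i
t_{ij} + \gamma' z_{ij} + b_i + \varepsilon_{ij},$$

with $t$ in years, a random intercept per participant (REML), and, for
volumetric outcomes, field strength and standardized TIV as covariates
$z$. A constant relative change per year is exactly linear on this scale,
and $\mathrm{APC} = 100(e^{\beta_t[+\beta_{gt}]} - 1)$ per group, with Wald
intervals (the teriflunomide interval uses
$\mathrm{var}(\beta_t)+\mathrm{var}(\beta_{gt})+2\,\mathrm{cov}$) and a Wald
test of the interaction. The phrase "time was log-transformed to derive the
APC" that accompanies such analyses does not uniquely determine a model; a
`time_transform = "log"` alternative (log outcome on $\log(1+t)$, APC read
off as the fitted change over the first year) is implemented, and neither
reading is asserted as the original. The two agree closely when follow-up
is short relative to curvature.

APC from a log-linear model is invariant to outcome units (ml vs mm³);
TIV standardization keeps the covariate scale-free. Non-positive outcomes
under the log transform and all-single-timepoint designs raise errors that
name the offending rows. With a balanced design and no covariates the fixed
slope reduces to pooled OLS, which the tests verify.

The BVL sensitivity suite refits each volumetric outcome (1) with baseline
age, sex, and disease duration plus their time interactions; (2) with the
annualized relapse rate over each patient's MRI follow-up window plus its
time interaction; (3) on patients with at least two scans; (4) on scans at
least 183 days ("6 months") after treatment start. The DTI suite fits the
twelve (metric, region) models without field-strength/TIV covariates and
without multiplicity adjustment, matching exploratory practice. PRL change
is summarized as counts of subjects with any increase (new) or decrease
(resolving) plus a linear mixed model on counts with the group-by-time
interaction; a count model is a pragmatic choice — the model family behind
published PRL p-values is typically unstated — and with all-constant counts
the interaction p is defined as 1.

# The synthetic cohort generator

`sim_config()` fixes the study conditions. Baseline marginals target a
typical treated RRMS registry cohort: age from a truncated normal whose
*post-truncation* mean is 43.1 years (SD 12.5, range 18–80; the location
parameter is solved for, since naive truncation would shift the mean by
about +0.6 y), 65.5% female, log-normal disease duration (median 9.2 y),
sNfL (10.2 pg/ml), T2-lesion volume (7.4 ml) and count (32), Poisson prior
DMTs (median 1), EDSS from a snapped normal (median 2.5), exponential time
under current treatment (median 2.2 y). Treatment assignment is confounded:
a logistic score on standardized covariates (older/longer-duration/
higher-EDSS toward teriflunomide, higher sNfL/T2 burden toward ocrelizumab)
scaled by `confounding_strength` (default 0.5) weights a without-replacement
draw of exactly `n_per_group` per arm; the latent propensity is emitted as
ground truth.

Follow-up is asymmetric by design — uniform with group medians 3.1 y
(ocrelizumab) and 1.9 y (teriflunomide), capped at 6 y — with an
exponential discontinuation process (0.05/person-year). Clinical visits lie
on a jittered **semi-annual** grid (182 ± 45 days). A semi-annual cadence
(consistent with "at least annual" protocol visits as practised in
standardized registries) is necessary for confirmed events to be observable
in the short-follow-up arm at all: with strictly annual visits, a 6-month
confirmation inside a median 1.9-year window almost never finds both a
qualifying and a confirming visit. MRI stays on a jittered annual grid
(365 ± 90 days).

Latent PIRA onsets are exponential with ocrelizumab hazard
`baseline_pira_rate` (default 0.12/person-year) and teriflunomide hazard
scaled by `true_pira_hazard_ratio` (default 0.80). The latent rate
deliberately exceeds plausible *detected* incidence: an onset only becomes
a confirmed event if a qualifying visit and a 6-months-later confirming
visit both fall inside follow-up, so at study scale (128/group) the default
yields roughly 20 + 9 detected events — close to observed registry counts —
while the detected incidence works out near 0.05/person-year. Relapses are
a Poisson process (0.10/person-year) adding a transient EDSS bump of
0.5–1.5 decaying linearly over 90 days and, with probability 0.3, a
permanent +0.5 residual; this supplies relapse-associated worsening for the
PIRA filter to exclude. The progression step at onset equals the worsening
threshold at the pre-progression level, and all observed EDSS values are
snapped to valid steps (half-up) and capped at 10.

Volumes decay exponentially, $v(t) = v_0 (1 + \mathrm{APC}/100)^{t}$, with
multiplicative log-normal noise (log-SD 0.004); defaults embed the
group-specific truths (total brain −1.06 vs −0.80, cortex −1.24 vs −0.97,
thalamus −0.97 vs −1.04, gray matter −1.20 vs −0.92 %/year). Baseline
volumes derive from per-patient TIV (normal, 1450 ± 120 ml, constant over
time) through typical parenchymal/cortical/thalamic/gray-matter fractions,
keeping every volume positive and below TIV. DTI region means start at
typical values per (metric, region), drift linearly at `dti_drift`
(default 0 %/year — observed cohort changes are null-ish and a zero default
makes the null-calibration experiments meaningful) with 1% multiplicative
noise. PRL counts are non-decreasing integer paths (Poisson increments at
0.02/person-year); the new-T2 flag fires per scan interval with probability
0.6 when the interval contains a relapse and at a 0.05/person-year rate
otherwise. Sub-cohorts carrying volumetric/DTI/PRL blocks default to
72/33/31 per group, emulating availability-defined endpoint cohorts.

## What the generator does not emulate

No EDSS rater noise (trajectories are exact up to snapping), no center
effects, no treatment switching, no informative dropout (discontinuation is
independent of trajectory), no spinal or lesion-level spatial structure, no
pseudoatrophy phase, and DTI drifts are linear rather than biologically
structured. Passing recovery tests therefore demonstrates that the
estimators are correct *under the stated model* — unbiased recovery of
hazard ratios and APCs, calibrated intervals — not that real registry data
meet these assumptions.

## A note on event ascertainment

With asymmetric follow-up, visit-grid detection loses more near-boundary
events in the short-follow-up arm, which biases the study-scale hazard
ratio downward relative to the latent truth even though the Cox estimator
itself is calibrated (verified directly on exponential survival data). The
end-to-end recovery test therefore uses symmetric follow-up, where
ascertainment cancels across arms and the detector-to-Cox chain recenters
on the true hazard ratio. This is a property of confirmed-progression
endpoints under scheduled visits, worth remembering when interpreting real
asymmetric cohorts.

# Numerical and validation choices

- Days are integers from treatment start; years use 365.25; "6 months" is
  180 days for confirmation and 183 days for the scan-timing filter.
- Estimation: REML for mixed models, Wald inference throughout; Efron ties
  in Cox; matching ties broken by smaller patient id; all stochastic steps
  seeded (`withr::with_seed`), so identical config + seed reproduces every
  output byte-identically.
- Degenerate inputs fail loudly and specifically: invalid EDSS steps,
  duplicate patient-days, zero events, single-arm events, non-positive
  outcomes under log, single-timepoint designs, unmatched patients in
  pairwise censoring.
- Monte-Carlo experiment sizes were fixed from binomial-precision
  arithmetic so that the Monte-Carlo SE of each measured rate is small
  against its plausible deviation: 500 replicates at n = 500/group for CI
  coverage, 2000 replicates at n = 250/group for type-I error, 400
  replicates at n = 72/group for APC recovery, 100 replicates at
  n = 500/group for balance improvement; the 10,000-trajectory oracle
  battery and the study-scale (128/group; 72/33/31 MRI sub-cohorts)
  determinism check complete in minutes on one CPU.

# Known limitations

Progression is EDSS-only (no timed-walk or dexterity composites); there is
no relapse-associated-worsening endpoint, no competing-risk or
doubly-robust machinery, no random slopes (random intercepts match the
target analysis), and proportional-hazards diagnostics are limited to the
exported curves. The PRL mixed model treats counts as Gaussian, adequate
for the near-constant paths simulated here but not for high-count settings.
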