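#' Fit a propensity-score model for treatment assignment
#'
#' Logistic regression of treatment (teriflunomide vs ocrelizumab) on the
#' baseline matching covariates, complete cases only. Binary sex enters as an
#' indicator for male.
#'
#' @param patients data.frame with `patient_id`, `group` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names; defaults to
#'   the ten canonical matching covariates ([matching_covariates()]).
#' @return object of class `propensity_model`: list with `coefficients`,
#'   `scores` (named by patient_id, on the probability scale), `n_excluded`
#'   (incomplete cases dropped), and the `glm` fit.
#' @export
fit_propensity <- function(patients, covariates = matching_covariates()) {
  stopifnot(all(covariates %in% names(patients)))
  if (min(table(patients$group)) < 10)
    stop("need at least 10 patients per group to fit a propensity model")
  df <- patients[, c("patient_id", "group", covariates)]
  if ("sex" %in% covariates) df$sex <- as.integer(df$sex == "M")
  cc <- stats::complete.cases(df[covariates])
  n_excluded <- sum(!cc)
  if (n_excluded) message(n_excluded, " patient(s) excluded: incomplete matching covariates")
  df <- df[cc, , drop = FALSE]
  df$.treat <- as.integer(df$group == "teriflunomide")
  fml <- stats::reformulate(covariates, response = ".treat")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || separated)
    stop("propensity model shows (quasi-)separation; consider a penalized fit")
  scores <- stats::fitted(fit)
  names(scores) <- df$patient_id
  structure(list(coefficients = stats::coef(fit), scores = scores,
                 n_excluded = n_excluded, fit = fit,
                 groups = stats::setNames(df$group, df$patient_id)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic):", length(x$scores), "patients,",
      x$n_excluded, "excluded\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Greedy 1:1 propensity matching without replacement
#'
#' Matches each teriflunomide patient to the nearest unused ocrelizumab
#' patient on the logit propensity scale, within a caliper of `caliper_sd`
#' standard deviations of the logit scores. The processing order of treated
#' patients is randomized by `seed`; distance ties are broken by the smaller
#' control patient_id.
#'
#' @param model a `propensity_model` (or a list with `scores` and `groups`).
#' @param caliper_sd caliper width in SDs of the logit scores (default 0.2).
#' @param seed integer seed for the processing order.
#' @return data.frame `teri_id, ocre_id, logit_distance`, zero rows when no
#'   pair fits the caliper.
#' @export
match_1to1 <- function(model, caliper_sd = 0.2, seed = 1L) {
  scores <- model$scores
  groups <- model$groups
  lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd * stats::sd(lg)
  teri <- names(lg)[groups == "teriflunomide"]
  ocre <- names(lg)[groups == "ocrelizumab"]
  if (!length(teri) || !length(ocre)) stop("both treatment groups must be non-empty")
  ord <- withr::with_seed(seed, sample(teri))
  ocre <- sort(ocre)  # tie-break: smaller patient_id wins
  avail <- rep(TRUE, length(ocre))
  pairs <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    d <- abs(lg[ocre] - lg[ord[k]])
    d[!avail] <- Inf
    best <- which.min(d)  # first minimum = smallest id on ties
    if (is.finite(d[best]) && d[best] <= caliper) {
      avail[best] <- FALSE
      pairs[[k]] <- data.frame(teri_id = ord[k], ocre_id = ocre[best],
                               logit_distance = unname(d[best]),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(teri_id = character(0), ocre_id = character(0),
                      logit_distance = numeric(0))
  rownames(out) <- NULL
  out[order(out$teri_id), , drop = FALSE]
}

#' Standardized mean difference between two samples
#'
#' `(mean_a - mean_b) / sqrt((var_a + var_b) / 2)`. For binary (0/1)
#' variables the proportion variance `p(1-p)` replaces the sample variance.
#' Equal means give 0 even when the pooled SD is zero; unequal means with
#' zero pooled SD give signed infinity.
#'
#' @param x_a,x_b numeric vectors (length >= 2 each).
#' @param binary treat inputs as 0/1 indicators.
#' @return scalar SMD (sign: a minus b).
#' @export
standardized_mean_difference <- function(x_a, x_b, binary = FALSE) {
  stopifnot(length(x_a) >= 2, length(x_b) >= 2)
  ma <- mean(x_a); mb <- mean(x_b)
  if (binary) {
    va <- ma * (1 - ma); vb <- mb * (1 - mb)
  } else {
    va <- stats::var(x_a); vb <- stats::var(x_b)
  }
  pooled <- sqrt((va + vb) / 2)
  if (ma == mb) return(0)
  if (pooled == 0) return(sign(ma - mb) * Inf)
  (ma - mb) / pooled
}

#' Covariate balance table for a matched cohort
#'
#' Per variable: median \[IQR\] per group, standardized mean difference, and
#' a two-sided Mann-Whitney U p-value. Constant variables get p = 1 with a
#' note.
#'
#' @param patients patient table (must contain `group` and the variables).
#' @param variables character vector of numeric variable names, reported in
#'   the given order. `sex` is handled as a binary male indicator.
#' @return data.frame `variable, median_iqr_teri, median_iqr_ocre, smd,
#'   mwu_p, note`.
#' @export
balance_table <- function(patients, variables = matching_covariates()) {
  rows <- lapply(variables, function(v) {
    x <- patients[[v]]
    binary <- FALSE
    if (v == "sex" || is.character(x)) {
      x <- as.integer(x == "M")
      binary <- TRUE
    }
    a <- x[patients$group == "teriflunomide"]
    b <- x[patients$group == "ocrelizumab"]
    fmt <- function(z) sprintf("%.2f [%.2f; %.2f]", stats::median(z),
                               stats::quantile(z, 0.25), stats::quantile(z, 0.75))
    note <- ""
    if (stats::var(x) == 0) {
      p <- 1
      note <- "constant variable"
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(variable = v, median_iqr_teri = fmt(a), median_iqr_ocre = fmt(b),
               smd = standardized_mean_difference(a, b, binary = binary),
               mwu_p = p, note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean absolute SMD across covariates
#'
#' Balance summary used to compare pre- vs post-match cohorts.
#'
#' @param patients patient table.
#' @param variables covariate names.
#' @return scalar mean |SMD|.
#' @export
mean_abs_smd <- function(patients, variables = matching_covariates()) {
  s <- vapply(variables, function(v) {
    x <- patients[[v]]
    binary <- FALSE
    if (v == "sex" || is.character(x)) {
      x <- as.integer(x == "M")
      binary <- TRUE
    }
    standardized_mean_difference(x[patients$group == "teriflunomide"],
                                 x[patients$group == "ocrelizumab"],
                                 binary = binary)
  }, numeric(1))
  mean(abs(s))
}
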