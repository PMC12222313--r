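#' Valid EDSS steps
#'
#' The Expanded Disability Status Scale is ordinal with steps
#' \{0, 1.0, 1.5, ..., 10.0\}; note that 0.5 is not a valid step.
#'
#' @return Numeric vector of the 20 valid EDSS values.
#' @export
edss_levels <- function() c(0, seq(1, 10, by = 0.5))

#' Test whether values are valid EDSS steps
#'
#' @param x numeric vector.
#' @return Logical vector.
#' @export
is_valid_edss <- function(x) {
  !is.na(x) & (x == 0 | (x >= 1 & x <= 10 & (x * 2) == floor(x * 2 + 1e-9)))
}

#' Snap numeric values to the nearest valid EDSS step
#'
#' Rounds to the nearest half point (ties rounded up), then maps the invalid
#' 0.5 step to 0 or 1.0 depending on which side of 0.5 the raw value lies
#' (exactly 0.5 rounds up to 1.0). Values are capped to \[0, 10\].
#'
#' @param x numeric vector.
#' @return Numeric vector of valid EDSS steps.
#' @export
snap_edss <- function(x) {
  x <- pmin(pmax(x, 0), 10)
  s <- floor(x * 2 + 0.5) / 2
  half <- s == 0.5
  s[half] <- ifelse(x[half] >= 0.5, 1, 0)
  s
}

#' Minimum EDSS increase qualifying as worsening
#'
#' The increase required for a confirmed disability worsening depends on the
#' reference EDSS: 1.5 points from a reference of 0, 1.0 points from a
#' reference in 1.0-5.5, and 0.5 points above 5.5.
#'
#' @param reference_edss numeric vector of valid EDSS steps.
#' @return Numeric vector of required minimum increases.
#' @export
#' @examples
#' min_increase_for(c(0, 2.5, 5.5, 6.0))
min_increase_for <- function(reference_edss) {
  if (any(!is_valid_edss(reference_edss))) {
    stop("invalid EDSS step(s): ",
         paste(reference_edss[!is_valid_edss(reference_edss)], collapse = ", "))
  }
  ifelse(reference_edss == 0, 1.5, ifelse(reference_edss <= 5.5, 1.0, 0.5))
}
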